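## Group statistics for per-organoid measurements (one-way ANOVA with
## Bonferroni pairwise comparisons) and exact binomial prevalence
## summaries for surveillance counts.

checkMeasurementTable <- function(table, value, group) {
  stopifnot(is.data.frame(table), value %in% names(table),
            group %in% names(table))
  v <- table[[value]]
  g <- factor(table[[group]])
  if (any(!is.finite(v)))
    stop("'", value, "' contains non-finite values")
  n <- table(g)
  if (nlevels(g) < 2L)
    stop("at least 2 groups are required")
  if (any(n < 2L))
    stop("every group needs >= 2 observations; too few in: ",
         paste(names(n)[n < 2L], collapse = ", "))
  list(v = v, g = g)
}

#' One-way analysis of variance from sums of squares
#'
#' Classical between/within decomposition computed explicitly:
#' `SS_between = sum n_i (mean_i - grand)^2`,
#' `SS_within = sum (x - mean_group)^2`,
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)` and the
#' p-value from the F distribution. Zero within-group variance with
#' equal group means leaves F undefined and is flagged rather than
#' reported as a number.
#'
#' @param table data.frame of per-organoid measurements.
#' @param value,group column names holding the measurement and the
#'   grouping factor.
#' @return list with `F`, `dfBetween`, `dfWithin`, `p`, `groups`
#'   (data.frame of group means, SDs and sizes) and `undefined`.
#' @examples
#' t <- data.frame(arm = rep(c("a", "b"), each = 3),
#'                 value = c(1, 2, 3, 4, 5, 6))
#' oneWayAnova(t)$F   # 13.5
#' @export
oneWayAnova <- function(table, value = "value", group = "arm") {
  d <- checkMeasurementTable(table, value, group)
  v <- d$v; g <- d$g
  k <- nlevels(g); N <- length(v)
  mi <- tapply(v, g, mean)
  ni <- tabulate(g)
  grand <- mean(v)
  ssB <- sum(ni * (mi - grand)^2)
  ssW <- sum((v - mi[g])^2)
  dfB <- k - 1L; dfW <- N - k
  msB <- ssB / dfB; msW <- ssW / dfW
  undefined <- msW == 0 && msB == 0
  Fst <- if (undefined) NA_real_ else msB / msW
  p <- if (undefined) NA_real_ else pf(Fst, dfB, dfW, lower.tail = FALSE)
  list(F = Fst, dfBetween = dfB, dfWithin = dfW, p = p,
       groups = data.frame(group = levels(g), n = ni, mean = as.numeric(mi),
                           sd = as.numeric(tapply(v, g, sd))),
       undefined = undefined)
}

starsFor <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
         ifelse(p < 0.05, "*", "ns")))
}

#' Pairwise t tests with Bonferroni correction
#'
#' Two-sided t tests for every group pair (pooled-variance by default,
#' the classical post-hoc companion to one-way ANOVA; Welch optional),
#' with each raw p-value multiplied by the number of comparisons and
#' capped at 1. Significance stars mark adjusted p below 0.05, 0.001 and
#' 0.0001.
#'
#' @param table,value,group as in [oneWayAnova()].
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @param versusControl when set to a group label, only pairs involving
#'   that group are tested (and `m` shrinks accordingly).
#' @return data.frame with one row per pair: `group1`, `group2`, `t`,
#'   `df`, `pRaw`, `pAdjusted`, `stars`.
#' @export
bonferroniPairwise <- function(table, value = "value", group = "arm",
                               welch = FALSE, versusControl = NULL) {
  d <- checkMeasurementTable(table, value, group)
  v <- d$v; g <- d$g
  levs <- levels(g)
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  if (!is.null(versusControl)) {
    stopifnot(versusControl %in% levs)
    pairs <- Filter(function(p) versusControl %in% p, pairs)
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- v[g == pr[1L]]; y <- v[g == pr[2L]]
    n1 <- length(x); n2 <- length(y)
    if (welch) {
      se2 <- var(x) / n1 + var(y) / n2
      tt <- (mean(x) - mean(y)) / sqrt(se2)
      df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) +
                     (var(y) / n2)^2 / (n2 - 1))
    } else {
      sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
      tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    }
    pRaw <- 2 * pt(abs(tt), df, lower.tail = FALSE)
    data.frame(group1 = pr[1L], group2 = pr[2L], t = tt, df = df,
               pRaw = pRaw)
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- pmin(1, m * out$pRaw)
  out$stars <- starsFor(out$pAdjusted)
  out
}

#' Prevalence with an exact binomial confidence interval
#'
#' Point prevalence `100 * k / n` (reported to 2 decimal places, as
#' surveillance studies print it) with a Clopper-Pearson exact 95% CI.
#' The Tsepamo surveillance counts are the canonical worked example:
#' 4 neural-tube defects among 426 DTG-exposed deliveries is 0.94%,
#' 5/1683 is 0.30% and 10/9460 is 0.11%.
#'
#' @param k case count.
#' @param n denominator (> 0).
#' @param conf confidence level.
#' @return data.frame with `k`, `n`, `percent` (2 dp), `ciLowPercent`,
#'   `ciHighPercent` and `method`.
#' @examples
#' prevalence(4, 426)$percent    # 0.94
#' @export
prevalence <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == length(n))
  if (any(n <= 0)) stop("denominator must be positive")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  ci <- t(mapply(function(ki, ni)
    binom.test(ki, ni, conf.level = conf)$conf.int, k, n))
  data.frame(k = k, n = n, percent = round(100 * k / n, 2),
             ciLowPercent = 100 * ci[, 1L], ciHighPercent = 100 * ci[, 2L],
             method = "Clopper-Pearson")
}
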