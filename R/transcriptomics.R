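## Count-level expression summarisation: CPM / log2CPM, arm-wise fold
## changes, fold-change thresholded gene lists, Venn partitioning and
## PCA. Selection is deliberately threshold-based (no p-values): the
## pooled-organoid design has one library per pool, so fold change on
## the CPM scale is the unit of evidence.

#' Counts-per-million normalisation
#'
#' `CPM[g, s] = 1e6 * counts[g, s] / libsize[s]`, and
#' `log2CPM = log2(CPM + pseudocount)`. The pseudocount (default 1 CPM)
#' guards the log against zero counts and is recorded in the object
#' metadata.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment-class] with a
#'   `counts` assay.
#' @param pseudocount value added to CPM before the log2 transform.
#' @return the same object with `cpm` and `log2cpm` assays added and
#'   `pseudocount` recorded in `metadata()`.
#' @examples
#' se <- simulateCounts(nGenes = 100)
#' se <- cpmNormalize(se)
#' colSums(SummarizedExperiment::assay(se, "cpm"))   # all 1e6
#' @export
cpmNormalize <- function(se, pseudocount = 1) {
  counts <- SummarizedExperiment::assay(se, "counts")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  SummarizedExperiment::assay(se, "cpm") <- cpm
  SummarizedExperiment::assay(se, "log2cpm") <- log2(cpm + pseudocount)
  S4Vectors::metadata(se)$pseudocount <- pseudocount
  se
}

#' Arm-wise fold changes on the CPM scale
#'
#' For every gene and every non-reference arm:
#' `FC = (mean CPM in arm + pseudocount) / (mean CPM in reference +
#' pseudocount)`. Arm means pool replicates (and, by default, both
#' timepoints), matching a pooled-organoid design; per-replicate means
#' are available by stratifying on `splitBy`.
#'
#' @param se a normalised object from [cpmNormalize()].
#' @param referenceArm the reference arm (default `"control"`).
#' @param splitBy optional extra `colData` column (e.g. `"timepoint"`)
#'   to stratify comparisons by.
#' @return data.frame with columns `gene`, `arm` (plus `splitBy` when
#'   stratified), `meanCpm`, `meanCpmRef`, `fc`, `log2fc`, `direction`.
#' @export
foldChanges <- function(se, referenceArm = "control", splitBy = NULL) {
  if (!"cpm" %in% SummarizedExperiment::assayNames(se))
    stop("run cpmNormalize() first")
  cpm <- SummarizedExperiment::assay(se, "cpm")
  pc <- S4Vectors::metadata(se)$pseudocount
  arm <- as.character(SummarizedExperiment::colData(se)$arm)
  if (!referenceArm %in% arm)
    stop("reference arm '", referenceArm, "' has no samples")
  strata <- if (is.null(splitBy)) rep("all", ncol(cpm))
            else as.character(SummarizedExperiment::colData(se)[[splitBy]])
  out <- list()
  for (st in unique(strata)) {
    sel <- strata == st
    refMean <- rowMeans(cpm[, sel & arm == referenceArm, drop = FALSE])
    for (a in setdiff(unique(arm[sel]), referenceArm)) {
      cols <- sel & arm == a
      if (!any(cols))
        stop("arm '", a, "' has no samples in stratum '", st, "'")
      armMean <- rowMeans(cpm[, cols, drop = FALSE])
      fc <- (armMean + pc) / (refMean + pc)
      df <- data.frame(gene = rownames(cpm), arm = a,
                       meanCpm = armMean, meanCpmRef = refMean,
                       fc = fc, log2fc = log2(fc),
                       direction = sign(log2(fc)), row.names = NULL)
      if (!is.null(splitBy)) df[[splitBy]] <- st
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}

#' Fold-change thresholded gene lists
#'
#' Per arm, genes with `FC > thresholdFC` (up) and `FC < 1/thresholdFC`
#' (down), reported separately.
#'
#' @param de fold-change table from [foldChanges()].
#' @param thresholdFC fold-change cut-off (> 1); the headline comparisons
#'   use genes with a fold change higher than 15.
#' @return list with elements `up` and `down`, each a named list of gene
#'   character vectors per arm.
#' @export
thresholdGeneLists <- function(de, thresholdFC = 15) {
  stopifnot(thresholdFC > 1)
  arms <- unique(de$arm)
  up <- lapply(setNames(arms, arms), function(a)
    de$gene[de$arm == a & de$fc > thresholdFC])
  down <- lapply(setNames(arms, arms), function(a)
    de$gene[de$arm == a & de$fc < 1 / thresholdFC])
  list(up = up, down = down, thresholdFC = thresholdFC)
}

#' Venn partition of 2-4 gene lists
#'
#' Assigns every gene in the union to exactly one Venn region (its
#' membership bitmask) and counts genes per region, including the central
#' intersection.
#'
#' @param lists named list of 2-4 character vectors.
#' @return list with `regions` (data.frame: region label, bitmask,
#'   count), `membership` (gene -> region label), `central` (genes in
#'   all lists) and `unionSize`.
#' @examples
#' vennPartition(list(A = c("g1", "g2"), B = c("g2"), C = c("g3"),
#'                    D = c("g2", "g3")))
#' @export
vennPartition <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L, length(lists) <= 4L)
  if (is.null(names(lists)))
    names(lists) <- LETTERS[seq_along(lists)]
  genes <- sort(unique(unlist(lists)))
  member <- vapply(lists, function(l) genes %in% l, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL,
                                                            names(lists)))
  maskOf <- function(bits) paste(as.integer(bits), collapse = "")
  labelOf <- function(bits) paste(names(lists)[bits], collapse = "&")
  geneMask <- apply(member, 1L, maskOf)
  nL <- length(lists)
  allBits <- expand.grid(rep(list(c(FALSE, TRUE)), nL))[-1L, , drop = FALSE]
  regions <- data.frame(
    region = apply(allBits, 1L, function(b) labelOf(as.logical(b))),
    bitmask = apply(allBits, 1L, function(b) maskOf(as.logical(b))),
    count = NA_integer_, row.names = NULL)
  regions$count <- vapply(regions$bitmask,
                          function(m) sum(geneMask == m), integer(1))
  membership <- if (length(genes))
    setNames(regions$region[match(geneMask, regions$bitmask)], genes)
  else setNames(character(0), character(0))
  central <- genes[rowSums(member) == nL]
  list(regions = regions, membership = membership, central = central,
       unionSize = length(genes))
}

#' Principal component analysis of log2CPM expression
#'
#' PCA with samples as observations on gene-centred (not unit-scaled)
#' log2CPM, so high-variance genes dominate, which is the point when a
#' single transcript spans orders of magnitude. Components use a
#' deterministic sign convention: the largest-magnitude gene loading of
#' each PC is positive. Scores reconstruct the centred data exactly at
#' full rank.
#'
#' @param se a normalised object from [cpmNormalize()].
#' @param topN optionally restrict to the `topN` most variable genes.
#' @return list of class `ExpressionPCA`: `scores` (samples x PC),
#'   `loadings` (genes x PC), `varExplained`, `sdev` and the centring
#'   vector `center`.
#' @export
runExpressionPCA <- function(se, topN = NULL) {
  if (!"log2cpm" %in% SummarizedExperiment::assayNames(se))
    stop("run cpmNormalize() first")
  x <- SummarizedExperiment::assay(se, "log2cpm")
  if (ncol(x) < 2L)
    stop("PCA needs at least 2 samples")
  if (!is.null(topN) && topN < nrow(x)) {
    v <- apply(x, 1L, var)
    x <- x[order(v, decreasing = TRUE)[seq_len(topN)], , drop = FALSE]
  }
  center <- rowMeans(x)
  xc <- t(x - center)                       # samples x genes
  sv <- svd(xc)
  flip <- vapply(seq_along(sv$d), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2L, flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  rownames(scores) <- colnames(x)
  rownames(loadings) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(sv$d))
  sdev <- sv$d / sqrt(max(1, nrow(xc) - 1L))
  structure(list(scores = scores, loadings = loadings,
                 varExplained = sdev^2 / sum(sdev^2), sdev = sdev,
                 center = center),
            class = "ExpressionPCA")
}

#' @export
print.ExpressionPCA <- function(x, ...) {
  cat(sprintf("ExpressionPCA: %d samples, %d genes\n",
              nrow(x$scores), nrow(x$loadings)))
  ve <- 100 * x$varExplained[seq_len(min(3L, length(x$varExplained)))]
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), ve), collapse = ", "),
      "\n")
  invisible(x)
}
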