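## Minimal 3D array morphology (shift-based): Otsu thresholding, largest
## connected component, hole filling and erosion, used by the OCT
## segmentation. 6-connectivity throughout.

## shift a 3D array by one voxel along an axis; fill with `fill`, or
## replicate the edge plane when fill = "edge"
shiftArr <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx[[axis]] - by
  if (identical(fill, "edge")) {
    src <- pmin(pmax(src, 1L), d[axis])
    idx[[axis]] <- src
    return(do.call(`[`, c(list(a), idx)))
  }
  out <- array(fill, d)
  keep <- src >= 1L & src <= d[axis]
  dst <- idx
  dst[[axis]] <- idx[[axis]][keep]
  srcIdx <- idx
  srcIdx[[axis]] <- src[keep]
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <-
    a[srcIdx[[1L]], srcIdx[[2L]], srcIdx[[3L]]]
  out
}

## 3 x 3 x 3 box blur via separable running means, edge-replicated
boxBlur3 <- function(a, iterations = 1L) {
  for (i in seq_len(iterations)) {
    for (axis in 1:3) {
      a <- (shiftArr(a, axis, -1L, "edge") + a +
            shiftArr(a, axis, 1L, "edge")) / 3
    }
  }
  a
}

## Otsu's threshold on a 256-bin histogram; also reports the separability
## (between-class variance / total variance), near 1 for bimodal data and
## low for unimodal noise
otsuThreshold <- function(x, nBins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0)
    return(list(threshold = rng[1L], separability = 0))
  br <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nBins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nBins]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  total <- sum(p * (mids - muT)^2)
  list(threshold = mids[which.max(between)],
       separability = if (total > 0) max(between) / total else 0)
}

## minimum over the six face neighbours
neighbourMin <- function(a) {
  m <- pmin(shiftArr(a, 1L, -1L, Inf), shiftArr(a, 1L, 1L, Inf))
  m <- pmin(m, shiftArr(a, 2L, -1L, Inf), shiftArr(a, 2L, 1L, Inf))
  pmin(m, shiftArr(a, 3L, -1L, Inf), shiftArr(a, 3L, 1L, Inf))
}

neighbourAny <- function(a) {
  m <- shiftArr(a, 1L, -1L) | shiftArr(a, 1L, 1L)
  m <- m | shiftArr(a, 2L, -1L) | shiftArr(a, 2L, 1L)
  m | shiftArr(a, 3L, -1L) | shiftArr(a, 3L, 1L)
}

neighbourAll <- function(a) {
  m <- shiftArr(a, 1L, -1L) & shiftArr(a, 1L, 1L)
  m <- m & shiftArr(a, 2L, -1L) & shiftArr(a, 2L, 1L)
  m & shiftArr(a, 3L, -1L) & shiftArr(a, 3L, 1L)
}

## largest 6-connected foreground component, by min-label propagation
largestComponent <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- array(Inf, dim(mask))
  lab[mask] <- which(mask)
  repeat {
    nxt <- pmin(lab, neighbourMin(lab))
    nxt[!mask] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  tab <- table(lab[mask])
  keep <- as.numeric(names(tab)[which.max(tab)])
  mask & lab == keep
}

## fill internal cavities: background voxels unreachable from the border
fillHoles <- function(mask) {
  bg <- !mask
  reach <- array(FALSE, dim(mask))
  d <- dim(mask)
  reach[c(1L, d[1L]), , ] <- bg[c(1L, d[1L]), , ]
  reach[, c(1L, d[2L]), ] <- bg[, c(1L, d[2L]), ]
  reach[, , c(1L, d[3L])] <- bg[, , c(1L, d[3L])]
  repeat {
    nxt <- reach | (bg & neighbourAny(reach))
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mask | (bg & !reach)
}

erodeMask <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- mask & neighbourAll(mask)
  mask
}
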