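## Brillouin spectra, OCT intensity volumes and RNA-seq count matrices
## with known ground truth.

lorentzian <- function(x, fwhm) {
  hw <- fwhm / 2
  hw^2 / (x^2 + hw^2)
}

#' Simulate a Brillouin spectrometer trace
#'
#' Produces an intensity-versus-pixel trace containing a symmetric
#' Stokes / anti-Stokes Lorentzian pair at `+/- trueShift` GHz around the
#' elastic line, mapped onto the pixel axis through an affine pixel-to-GHz
#' calibration `GHz = slope * pixel + intercept`, plus Gaussian read
#' noise. The defaults emulate a VIPA spectrometer whose free spectral
#' range covers roughly -8 to +8 GHz over 512 pixels.
#'
#' @param trueShift Brillouin shift to plant (GHz); must sit inside the
#'   calibrated range with a 2-linewidth margin.
#' @param linewidth Lorentzian FWHM (GHz).
#' @param slope,intercept forward pixel-to-GHz map.
#' @param nPixels number of spectrometer pixels.
#' @param amplitude peak amplitude (counts).
#' @param baseline constant background (counts).
#' @param noiseSd Gaussian read-noise SD (counts).
#' @param seed RNG seed; fixed seed gives a reproducible trace.
#' @param exposureTime camera acquisition time (s).
#' @return a [BrillouinSpectrum-class].
#' @examples
#' s <- simulateBrillouinSpectrum(5.1, noiseSd = 0)
#' @export
simulateBrillouinSpectrum <- function(trueShift, linewidth = 0.3,
                                      slope = 16 / 512, intercept = -8,
                                      nPixels = 512L, amplitude = 1000,
                                      baseline = 20, noiseSd = 0, seed = 1L,
                                      exposureTime = 0.2) {
  stopifnot(trueShift > 0, linewidth > 0, slope != 0)
  nu <- slope * seq_len(nPixels) + intercept
  if (trueShift + 2 * linewidth > max(nu) ||
      -trueShift - 2 * linewidth < min(nu))
    stop(sprintf(
      "shift %g GHz lies outside the spectrometer range [%g, %g] GHz",
      trueShift, min(nu), max(nu)))
  set.seed(seed)
  intensity <- baseline + amplitude *
    (lorentzian(nu - trueShift, linewidth) +
     lorentzian(nu + trueShift, linewidth))
  if (noiseSd > 0)
    intensity <- pmax(intensity + rnorm(nPixels, sd = noiseSd), 0)
  BrillouinSpectrum(intensity, exposureTime = exposureTime)
}

#' Simulate an OCT structural intensity volume
#'
#' Renders the phantom sphere as a bright object (`objectLevel`) against a
#' dim background (`backgroundLevel`) on an isotropic voxel grid, with
#' speckle-like multiplicative noise drawn from a Gamma distribution of
#' unit mean and SD `1/sqrt(snr)`. The ground-truth object mask is stored
#' alongside the intensities for recovery tests.
#'
#' @param phantom an [OrganoidPhantom-class]; `NULL` gives a
#'   background-only volume.
#' @param voxelSize isotropic voxel size (mm); must resolve the shell
#'   thickness with at least 2 voxels.
#' @param snr speckle signal-to-noise ratio; `Inf` disables noise.
#' @param seed RNG seed.
#' @param margin background margin around the phantom (mm).
#' @param objectLevel,backgroundLevel mean intensities.
#' @param dims optional explicit volume dimensions (voxels).
#' @return an [OCTVolume-class].
#' @export
simulateOCTVolume <- function(phantom, voxelSize = 0.02, snr = 10,
                              seed = 1L, margin = 0.25, objectLevel = 1,
                              backgroundLevel = 0.1, dims = NULL) {
  if (!is.null(phantom)) {
    stopifnot(is(phantom, "OrganoidPhantom"))
    if ((phantom@shellRadius - phantom@coreRadius) / voxelSize < 2)
      stop("voxel size does not resolve the shell thickness with >= 2 voxels")
    if (is.null(dims)) {
      side <- 2 * (phantom@shellRadius + margin)
      dims <- rep(2L * ceiling(side / (2 * voxelSize)) + 1L, 3L)
    }
  } else if (is.null(dims)) {
    dims <- c(33L, 33L, 33L)
  }
  dims <- as.integer(dims)
  set.seed(seed)
  ax <- lapply(dims, function(d) (seq_len(d) - (d + 1) / 2) * voxelSize)
  if (!is.null(phantom)) {
    dx2 <- ax[[1L]]^2
    dy2 <- ax[[2L]]^2
    dz2 <- ax[[3L]]^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    truth <- r2 <= phantom@shellRadius^2
  } else {
    truth <- array(FALSE, dims)
  }
  intensity <- array(backgroundLevel, dims)
  intensity[truth] <- objectLevel
  if (is.finite(snr))
    intensity <- intensity * rgamma(length(intensity), shape = snr,
                                    rate = snr)
  new("OCTVolume", intensity = intensity, voxelSize = voxelSize,
      truthMask = truth)
}

## ---------------------------------------------------------------------------
## RNA-seq counts
## ---------------------------------------------------------------------------

exposureArms <- c("DTG10", "DTG20", "DTG10_FA10", "DTG20_FA20")

#' Neurodevelopment gene panel tracked by the simulator
#'
#' Genes involved in head, brain, neuron and neural tube development whose
#' expression is perturbed by dolutegravir exposure, alongside the folate
#' receptor gene FOLR1.
#'
#' @return character vector of gene symbols.
#' @export
neuroDevGenes <- function() {
  c("DVL3", "GATA2", "KIF22", "LHX2", "NEUROG1", "NKX2-2", "NTF3",
    "SEMA6B", "WNT8B")
}

#' Five-arm, two-timepoint exposure design
#'
#' Builds the sample sheet for the dolutegravir exposure experiment:
#' control, DTG 10 uM, DTG 20 uM, DTG 10 uM + folic acid 10 uM and
#' DTG 20 uM + folic acid 20 uM, each at organoid days 20 and 24.
#'
#' @param nRep replicates per arm and timepoint.
#' @param timepoints timepoint labels.
#' @return data.frame with columns `sample`, `arm`, `timepoint`,
#'   `replicate`; `arm` and `timepoint` are factors with control /
#'   day20 as first levels.
#' @examples
#' nrow(organoidDesign())   # 5 arms x 2 days x 3 replicates = 30
#' @export
organoidDesign <- function(nRep = 3L, timepoints = c("day20", "day24")) {
  arms <- c("control", exposureArms)
  d <- expand.grid(replicate = seq_len(nRep), timepoint = timepoints,
                   arm = arms, stringsAsFactors = FALSE)
  d <- d[, c("arm", "timepoint", "replicate")]
  d$sample <- sprintf("%s_%s_r%d", d$arm, d$timepoint, d$replicate)
  d$arm <- factor(d$arm, levels = arms)
  d$timepoint <- factor(d$timepoint, levels = timepoints)
  rownames(d) <- d$sample
  d[, c("sample", "arm", "timepoint", "replicate")]
}

#' Default planted expression effects
#'
#' FOLR1 receives a large induction (default log2 fold change 8, i.e. a
#' 256-fold increase spanning several orders of magnitude on the CPM
#' scale) in every exposure arm; the neurodevelopment panel receives
#' mixed moderate perturbations.
#'
#' @param folr1Log2FC planted FOLR1 effect (log2 fold change vs control).
#' @return data.frame with columns `gene`, `arm`, `log2fc`.
#' @export
defaultExpressionEffects <- function(folr1Log2FC = 8) {
  neuro <- neuroDevGenes()
  neuroFC <- c(-1.5, 2, -1, 1.5, -2, 1, -1.2, 1.8, -1.6)
  eff <- rbind(
    data.frame(gene = "FOLR1", arm = exposureArms, log2fc = folr1Log2FC),
    do.call(rbind, lapply(exposureArms, function(a)
      data.frame(gene = neuro, arm = a, log2fc = neuroFC))))
  rownames(eff) <- NULL
  eff
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Draws gene x sample counts from a negative binomial with mean
#' `mu * 2^effect * sizeFactor` and variance `mu + dispersion * mu^2`
#' (Poisson when `dispersion = 0`). Library sizes vary by up to
#' `libFactor` between samples. The planted effect table, baseline means
#' and size factors are stored in the object metadata as ground truth.
#'
#' @param design sample sheet from [organoidDesign()].
#' @param nGenes total number of genes (the FOLR1 + neurodevelopment
#'   panel is always included and counted within `nGenes`).
#' @param baselineMu per-gene baseline means; default log-normal draws.
#' @param dispersion NB dispersion (scalar or per-gene).
#' @param effects planted log2 fold changes, as from
#'   [defaultExpressionEffects()]; genes must exist in the matrix.
#' @param libFactor maximal ratio between sample library-size factors.
#' @param seed RNG seed.
#' @return a [SummarizedExperiment::SummarizedExperiment-class] with a
#'   `counts` assay, the design as `colData` and ground truth in
#'   `metadata()`.
#' @examples
#' se <- simulateCounts(nGenes = 200, seed = 7)
#' @export
simulateCounts <- function(design = organoidDesign(), nGenes = 2000L,
                           baselineMu = NULL, dispersion = 0.1,
                           effects = defaultExpressionEffects(),
                           libFactor = 2, seed = 1L) {
  stopifnot(all(c("sample", "arm", "timepoint") %in% colnames(design)),
            nGenes >= 10L, libFactor >= 1, all(dispersion >= 0))
  set.seed(seed)
  panel <- c("FOLR1", neuroDevGenes())
  genes <- c(panel, sprintf("G%04d", seq_len(nGenes - length(panel))))
  if (is.null(baselineMu)) {
    baselineMu <- rlnorm(length(genes), meanlog = log(50), sdlog = 1.5)
    names(baselineMu) <- genes
    baselineMu["FOLR1"] <- 20      # modest baseline; induction does the work
  }
  stopifnot(length(baselineMu) == length(genes))
  names(baselineMu) <- genes
  missing <- setdiff(unique(effects$gene), genes)
  if (length(missing))
    stop("effect table references absent gene(s): ",
         paste(missing, collapse = ", "))

  nS <- nrow(design)
  log2fc <- matrix(0, nrow = length(genes), ncol = nS,
                   dimnames = list(genes, design$sample))
  for (i in seq_len(nrow(effects))) {
    sel <- design$arm == effects$arm[i]
    log2fc[effects$gene[i], sel] <- effects$log2fc[i]
  }
  sizeFactors <- exp(runif(nS, -log(libFactor) / 2, log(libFactor) / 2))
  names(sizeFactors) <- design$sample
  mu <- baselineMu * 2^log2fc
  mu <- sweep(mu, 2L, sizeFactors, "*")
  disp <- rep_len(dispersion, length(genes))
  counts <- matrix(0L, nrow = length(genes), ncol = nS,
                   dimnames = dimnames(mu))
  for (g in seq_along(genes)) {
    counts[g, ] <- if (disp[g] < 1e-12) rpois(nS, mu[g, ])
                   else rnbinom(nS, mu = mu[g, ], size = 1 / disp[g])
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(design, row.names = design$sample),
    metadata = list(effects = effects, baselineMu = baselineMu,
                    sizeFactors = sizeFactors, dispersion = disp,
                    seed = seed))
}
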