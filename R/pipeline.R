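## End-to-end orchestration: validated run configuration, staged
## execution (counts -> elastography/Brillouin per organoid -> group
## statistics) and a checksummed run manifest.

defaultRunConfig <- function() {
  list(
    experiment = "demo",
    seed = 1L,
    outputDir = "organoidKit-run",
    phantom = list(shellRadius = 0.6, coreFraction = 0.7,
                   vsShell = 2.5, vsCore = 2.0, vsBackground = 3.0,
                   shiftShell = 5.25, shiftCore = 5.1),
    acquisition = list(lambda0 = 840e-9, nRefractive = 1.34,
                       alineRate = 25000, excitationFreq = 3000,
                       nTimepoints = 500L, gridPoints = c(101L, 101L),
                       scanExtent = c(2, 2), windowSize = 0.5),
    simulation = list(nPlaneWaves = 1000L, fieldRms = 5e-4, noiseSd = 0,
                      amplitudeModel = "constant"),
    thresholds = list(fc = 15, r2 = 0.6, shellFraction = 0.2),
    counts = list(nGenes = 2000L, dispersion = 0.1, libFactor = 2,
                  nRep = 3L, folr1Log2FC = 8),
    brillouin = list(linewidth = 0.3, noiseSd = 5, nPoints = 60L,
                     voxelSize = 0.02, snr = 10),
    prevalence = list(cases = c(4L, 5L, 10L),
                      denominators = c(426L, 1683L, 9460L))
  )
}

## recursive merge of user values over defaults, collecting unknown keys
mergeConfig <- function(defaults, user, path = "") {
  errors <- character()
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors <- c(errors, paste0("unknown key '", full, "'"))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors <- c(errors, paste0("'", full, "' must be a mapping"))
        next
      }
      sub <- mergeConfig(defaults[[key]], user[[key]], full)
      defaults[[key]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(config = defaults, errors = errors)
}

#' Validate and resolve a run configuration
#'
#' Merges a raw configuration (e.g. from a YAML file) over the defaults,
#' rejects unknown keys, type- and constraint-checks every section by
#' constructing the corresponding objects, and resolves derived values
#' (the inter-A-line interval `deltaT = 1 / alineRate`). All problems
#' are reported together in a single error, not one at a time. An empty
#' input yields the complete default demo configuration.
#'
#' @param raw named list of overrides (possibly nested), or `NULL` /
#'   empty for the defaults; or a path to a YAML file.
#' @return a resolved configuration list of class `RunConfig`, carrying
#'   ready-built `acq` ([AcquisitionConfig-class]) and `sim`
#'   ([SimSpec-class]) objects and `deltaT`.
#' @examples
#' cfg <- validateRunConfig(list(acquisition = list(alineRate = 25000)))
#' cfg$deltaT   # 4e-05 s
#' @export
validateRunConfig <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1L)
    raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  merged <- mergeConfig(defaultRunConfig(), raw)
  cfg <- merged$config
  errors <- merged$errors

  tryOr <- function(expr, label) {
    obj <- tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(label, ": ", conditionMessage(e)))
      NULL
    })
    obj
  }
  a <- cfg$acquisition
  cfg$acq <- tryOr(AcquisitionConfig(
    lambda0 = a$lambda0, nRefractive = a$nRefractive,
    alineRate = a$alineRate, excitationFreq = a$excitationFreq,
    nTimepoints = a$nTimepoints, gridPoints = a$gridPoints,
    scanExtent = a$scanExtent, windowSize = a$windowSize), "acquisition")
  s <- cfg$simulation
  cfg$sim <- tryOr(SimSpec(nPlaneWaves = s$nPlaneWaves, seed = cfg$seed,
                           fieldRms = s$fieldRms, noiseSd = s$noiseSd,
                           amplitudeModel = s$amplitudeModel), "simulation")
  p <- cfg$phantom
  if (is.null(p$shellRadius) || is.null(p$coreFraction)) {
    errors <- c(errors, "phantom: 'shellRadius' and 'coreFraction' required")
  } else {
    tryOr(OrganoidPhantom(shellRadius = p$shellRadius,
                          coreRadius = p$shellRadius * p$coreFraction,
                          vsShell = p$vsShell, vsCore = p$vsCore,
                          vsBackground = p$vsBackground,
                          shiftShell = p$shiftShell,
                          shiftCore = p$shiftCore), "phantom")
  }
  th <- cfg$thresholds
  if (!is.null(th$fc) && th$fc <= 1)
    errors <- c(errors, "thresholds: 'fc' must exceed 1")
  if (!is.null(th$r2) && (th$r2 < 0 || th$r2 > 1))
    errors <- c(errors, "thresholds: 'r2' must lie in [0, 1]")
  if (length(errors))
    stop("invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  cfg$deltaT <- 1 / cfg$acquisition$alineRate
  class(cfg) <- c("RunConfig", "list")
  cfg
}

## study-condition phantom for one organoid: DTG slows growth (smaller
## day-24 radius), stiffens the surface (higher shell speed and shift,
## further escalated by folate) and softens the core
armPhantom <- function(cfg, arm, timepoint, replicate, seed) {
  p <- cfg$phantom
  growth <- if (timepoint == "day24" && arm == "control") 1.15
            else if (timepoint == "day24") 0.9 else 1
  vsShell <- p$vsShell * switch(arm, control = 1, DTG10 = 1.15,
                                DTG20 = 1.2, DTG10_FA10 = 1.25,
                                DTG20_FA20 = 1.3)
  vsCore <- p$vsCore * switch(arm, control = 1, 0.75)
  dShift <- switch(arm, control = 0, DTG10 = 0.06, DTG20 = 0.08,
                   DTG10_FA10 = 0.12, DTG20_FA20 = 0.15)
  set.seed(seed)
  jitter <- exp(rnorm(3, sd = 0.03))
  OrganoidPhantom(shellRadius = p$shellRadius * growth * jitter[1L],
                  coreRadius = p$shellRadius * growth * jitter[1L] *
                    p$coreFraction,
                  vsShell = vsShell * jitter[2L],
                  vsCore = vsCore * jitter[3L],
                  vsBackground = p$vsBackground,
                  shiftShell = p$shiftShell + dShift,
                  shiftCore = p$shiftCore)
}

writeStage <- function(manifest, stage, path, t0) {
  manifest[[length(manifest) + 1L]] <- data.frame(
    stage = stage, path = path,
    md5 = unname(tools::md5sum(path)),
    seconds = round(as.numeric(Sys.time()) - t0, 2))
  manifest
}

#' Run the full multimodal pipeline
#'
#' Executes the stages in dependency order: (1) RNA-seq simulation and
#' summarisation (CPM, fold changes, thresholded lists, Venn partition,
#' PCA); (2) one organoid per arm x timepoint x replicate: reverberant
#' field simulation, phase encoding and decoding, harmonic extraction,
#' bandpass, wavenumber and speed maps with region-wise summaries, OCT
#' simulation, segmentation, volumetry, Brillouin calibration and
#' surface-wise shift; (3) group statistics (ANOVA + Bonferroni) over
#' the per-organoid summaries and the prevalence worked examples. Each
#' stage writes its tables under `outputDir` and a failing stage aborts
#' the run naming itself. A manifest listing every output with its MD5
#' checksum is written last; identical configurations and seeds give
#' identical checksums for all deterministic outputs.
#'
#' @param cfg a `RunConfig` from [validateRunConfig()] (or a raw list /
#'   YAML path, which is validated first).
#' @param outputDir overrides the configured output directory.
#' @return (invisibly) the manifest data.frame.
#' @export
runPipeline <- function(cfg = validateRunConfig(), outputDir = NULL) {
  if (!inherits(cfg, "RunConfig")) cfg <- validateRunConfig(cfg)
  out <- if (is.null(outputDir)) cfg$outputDir else outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- stage rnaseq ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  rnaseq <- runStage("rnaseq", function() {
    design <- organoidDesign(nRep = cfg$counts$nRep)
    se <- simulateCounts(design = design, nGenes = cfg$counts$nGenes,
                         dispersion = cfg$counts$dispersion,
                         effects = defaultExpressionEffects(
                           cfg$counts$folr1Log2FC),
                         libFactor = cfg$counts$libFactor,
                         seed = cfg$seed)
    se <- cpmNormalize(se)
    de <- foldChanges(se)
    lists <- thresholdGeneLists(de, cfg$thresholds$fc)
    venn <- vennPartition(lists$up)
    pca <- runExpressionPCA(se)
    dePath <- file.path(out, "de_results.tsv")
    write.table(de, dePath, sep = "\t", quote = FALSE, row.names = FALSE)
    vennPath <- file.path(out, "venn_regions.tsv")
    write.table(venn$regions, vennPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    pcaPath <- file.path(out, "pca_scores.tsv")
    scores <- data.frame(sample = rownames(pca$scores),
                         design[rownames(pca$scores),
                                c("arm", "timepoint")],
                         pca$scores[, seq_len(min(5L, ncol(pca$scores)))])
    write.table(scores, pcaPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(paths = c(dePath, vennPath, pcaPath), se = se, venn = venn)
  })
  for (p in rnaseq$paths) manifest <- writeStage(manifest, "rnaseq", p, t0)

  ## -- stage organoids ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  summaryPath <- file.path(out, "organoid_summary.csv")
  runStage("organoids", function() {
    shifts <- brillouinReferenceShifts()
    refSpecs <- lapply(shifts, simulateBrillouinSpectrum,
                       noiseSd = cfg$brillouin$noiseSd, seed = cfg$seed)
    calib <- calibrateSpectrometer(refSpecs, shifts)
    design <- organoidDesign(nRep = cfg$counts$nRep)
    rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      d <- design[i, ]
      seed <- cfg$seed * 1000L + i
      ph <- armPhantom(cfg, as.character(d$arm), as.character(d$timepoint),
                       d$replicate, seed)
      sim <- SimSpec(nPlaneWaves = cfg$simulation$nPlaneWaves, seed = seed,
                     fieldRms = cfg$simulation$fieldRms,
                     noiseSd = cfg$simulation$noiseSd,
                     amplitudeModel = cfg$simulation$amplitudeModel)
      vf <- simulateReverberantField(ph, cfg$acq, sim)
      vf2 <- phaseToVelocity(fieldToPhaseVolume(vf))
      h <- extractHarmonic(vf2)
      kNom <- 2 * pi * h@freq / mean(c(ph@vsShell, ph@vsCore))
      h <- spatialBandpass(h, 0.25 * kNom,
                           min(4 * kNom,
                               0.95 * pi / (max(gridSpacing(cfg$acq)) *
                                            1e-3)))
      km <- estimateWavenumberMap(h, r2Threshold = cfg$thresholds$r2)
      sm <- wavenumberToSpeed(km)
      reg <- regionSpeedSummary(sm, phantom = ph,
                                shellFraction = cfg$thresholds$shellFraction)
      oct <- simulateOCTVolume(ph, voxelSize = cfg$brillouin$voxelSize,
                               snr = cfg$brillouin$snr, seed = seed)
      mask <- segmentOrganoid(oct)
      morph <- organoidMorphometry(mask = mask)
      shiftMap <- simulateShiftMap(ph, mask, calib,
                                   nPoints = cfg$brillouin$nPoints,
                                   noiseSd = cfg$brillouin$noiseSd,
                                   linewidth = cfg$brillouin$linewidth,
                                   seed = seed)
      surf <- surfaceMeanShift(shiftMap, mask)
      rows[[i]] <- data.frame(
        organoid_id = d$sample, arm = as.character(d$arm),
        day = as.character(d$timepoint),
        surface_mean_vs = reg$mean[reg$region == "surface"],
        core_mean_vs = reg$mean[reg$region == "core"],
        d_mean_mm = morph@dMean, volume_mm3 = morph@volume,
        surface_mean_shift_GHz = surf$meanShift)
    }
    write.csv(do.call(rbind, rows), summaryPath, row.names = FALSE)
  })
  manifest <- writeStage(manifest, "organoids", summaryPath, t0)

  ## -- stage stats ----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  statsPath <- file.path(out, "stats_report.tsv")
  prevPath <- file.path(out, "prevalence.tsv")
  runStage("stats", function() {
    tab <- read.csv(summaryPath)
    rows <- list()
    for (measure in c("surface_mean_shift_GHz", "surface_mean_vs",
                      "core_mean_vs", "volume_mm3")) {
      av <- oneWayAnova(tab, value = measure, group = "arm")
      rows[[length(rows) + 1L]] <- data.frame(
        test = "one-way ANOVA", measure = measure, group1 = "all",
        group2 = "", statistic = av$F, pRaw = av$p, pAdjusted = av$p,
        stars = if (is.na(av$p)) "" else starsFor(av$p))
      pw <- bonferroniPairwise(tab, value = measure, group = "arm")
      rows[[length(rows) + 1L]] <- data.frame(
        test = "Bonferroni pairwise t", measure = measure,
        group1 = pw$group1, group2 = pw$group2, statistic = pw$t,
        pRaw = pw$pRaw, pAdjusted = pw$pAdjusted, stars = pw$stars)
    }
    write.table(do.call(rbind, rows), statsPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
    prev <- prevalence(cfg$prevalence$cases, cfg$prevalence$denominators)
    write.table(prev, prevPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  manifest <- writeStage(manifest, "stats", statsPath, t0)
  manifest <- writeStage(manifest, "stats", prevPath, t0)

  manifestDf <- do.call(rbind, manifest)
  jsonlite::write_json(manifestDf, file.path(out, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifestDf)
}
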