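makeSe <- function(counts, arms, timepoints = NULL) {
  n <- ncol(counts)
  if (is.null(timepoints)) timepoints <- rep("day20", n)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(n))
  if (is.null(rownames(counts)) || any(rownames(counts) == ""))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      sample = colnames(counts), arm = arms, timepoint = timepoints,
      replicate = seq_len(n), row.names = colnames(counts)))
}

test_that("CPM normalisation follows the library-size identity", {
  counts <- cbind(a = c(1L, 1L, 2L), b = c(10L, 0L, 30L))
  se <- cpmNormalize(makeSe(counts, arms = c("control", "DTG10")))
  cpm <- assay(se, "cpm")
  expect_equal(unname(cpm[, "a"]), c(250000, 250000, 500000))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-6)
  ## all-zero gene: CPM 0, log2CPM = log2(pseudocount)
  counts2 <- rbind(counts, zero = c(0L, 0L))
  se2 <- cpmNormalize(makeSe(counts2, arms = c("control", "DTG10")))
  expect_equal(unname(assay(se2, "cpm")[4L, ]), c(0, 0))
  expect_equal(unname(assay(se2, "log2cpm")[4L, ]), c(0, 0))  # log2(1)

  bad <- makeSe(cbind(a = c(1L, 1L), b = c(0L, 0L)),
                arms = c("control", "DTG10"))
  expect_error(cpmNormalize(bad), "b")
})

test_that("CPM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  se <- cpmNormalize(simulateCounts(nGenes = 120L, seed = 5L))
  ref <- edgeR::cpm(assay(se, "counts"))
  expect_equal(unname(assay(se, "cpm")), unname(ref), tolerance = 1e-12)
})

test_that("fold changes use pseudocounted arm means symmetrically", {
  ## equal libraries of 1e6 so counts are CPM directly
  counts <- cbind(ctrl = c(1L, 500L), arm = c(256L, 500L))
  counts <- rbind(counts, filler = c(999499L, 999244L))
  se <- cpmNormalize(makeSe(counts, arms = c("control", "DTG10")))
  de <- foldChanges(se)
  expect_equal(de$fc[de$gene == "g1"], 257 / 2)      # (256+1)/(1+1)
  expect_gt(de$fc[de$gene == "g1"], 15)

  ## identical arms: FC = 1, log2FC = 0
  counts2 <- cbind(a = c(10L, 20L), b = c(10L, 20L))
  se2 <- cpmNormalize(makeSe(counts2, arms = c("control", "DTG10")))
  de2 <- foldChanges(se2)
  expect_equal(de2$fc, c(1, 1))
  expect_equal(de2$log2fc, c(0, 0))

  ## swapping arm and reference inverts FC
  deFwd <- foldChanges(se)
  deRev <- foldChanges(se, referenceArm = "DTG10")
  expect_equal(deFwd$fc, 1 / deRev$fc, tolerance = 1e-12)

  expect_error(foldChanges(se, referenceArm = "missing"), "missing")
})

test_that("threshold lists shrink with the cut-off and split directions", {
  se <- cpmNormalize(simulateCounts(nGenes = 300L, seed = 11L))
  de <- foldChanges(se)
  sizes <- vapply(c(2, 5, 15, 50), function(thr)
    length(unlist(thresholdGeneLists(de, thr)$up)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  lists <- thresholdGeneLists(de, 15)
  expect_true(all(vapply(lists$up, function(l) "FOLR1" %in% l, logical(1))))
  expect_error(thresholdGeneLists(de, 0.5))
})

test_that("Venn partitions match brute-force enumeration", {
  ## trivial cases
  same <- vennPartition(list(A = "g", B = "g", C = "g", D = "g"))
  expect_equal(same$regions$count[same$regions$region == "A&B&C&D"], 1L)
  expect_equal(sum(same$regions$count), 1L)

  disj <- vennPartition(list(A = "a", B = "b", C = "c", D = "d"))
  singles <- disj$regions$count[disj$regions$region %in% LETTERS[1:4]]
  expect_equal(singles, rep(1L, 4L))
  expect_equal(disj$unionSize, 4L)

  ## random lists versus per-gene brute force
  for (seed in 1:5) {
    set.seed(seed)
    genes <- sprintf("g%03d", 1:100)
    lists <- list(A = sample(genes, 20), B = sample(genes, 30),
                  C = sample(genes, 25), D = sample(genes, 15))
    vp <- vennPartition(lists)
    union <- sort(unique(unlist(lists)))
    bruteCounts <- table(vapply(union, function(g) {
      paste(vapply(lists, function(l) as.integer(g %in% l), integer(1)),
            collapse = "")
    }, character(1)))
    for (i in seq_len(nrow(vp$regions))) {
      expected <- bruteCounts[vp$regions$bitmask[i]]
      expect_equal(vp$regions$count[i],
                   if (is.na(expected)) 0L else unname(as.integer(expected)))
    }
    expect_equal(sum(vp$regions$count), length(union))
    ## each gene sits in exactly one region
    expect_equal(length(vp$membership), length(union))
  }
})

test_that("expression PCA is orthonormal, reconstructive and signed", {
  se <- cpmNormalize(simulateCounts(nGenes = 150L, seed = 13L))
  pca <- runExpressionPCA(se)
  L <- pca$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$varExplained) <= 1e-12))
  ## full-rank reconstruction of the centred data
  xc <- t(assay(se, "log2cpm") - pca$center)
  expect_equal(pca$scores %*% t(L), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## deterministic sign: the largest-magnitude loading is positive
  for (j in seq_len(ncol(L)))
    expect_gte(L[which.max(abs(L[, j])), j], 0)
  ## agreement with prcomp up to the sign convention
  pr <- stats::prcomp(xc, center = FALSE)
  expect_equal(abs(unname(pca$scores[, 1:3])), abs(unname(pr$x[, 1:3])),
               tolerance = 1e-6)

  ## two identical samples: no variance at all
  counts <- cbind(a = c(5L, 9L, 2L), b = c(5L, 9L, 2L))
  seId <- cpmNormalize(makeSe(counts, arms = c("control", "DTG10")))
  expect_lt(runExpressionPCA(seId)$sdev[1L], 1e-8)

  one <- makeSe(cbind(a = c(1L, 2L)), arms = "control")
  expect_error(runExpressionPCA(cpmNormalize(one)), "2 samples")
})

test_that("planted exposure effects dominate the expression summaries", {
  skip_if_not_installed("cluster")
  se <- cpmNormalize(simulateCounts(nGenes = 400L, seed = 17L))
  de <- foldChanges(se)
  ## FOLR1 carries the largest |log2FC| in every exposure arm
  top <- vapply(split(de, de$arm), function(d)
    d$gene[which.max(abs(d$log2fc))], character(1))
  expect_true(all(top == "FOLR1"))
  ## and sits in the central Venn intersection of the up-lists
  vp <- vennPartition(thresholdGeneLists(de, 15)$up)
  expect_true("FOLR1" %in% vp$central)
  ## PC1 separates exposed samples from control
  pca <- runExpressionPCA(se)
  grp <- ifelse(colData(se)$arm == "control", 1L, 2L)
  sil <- cluster::silhouette(grp, dist(pca$scores[, 1L]))
  expect_gt(mean(sil[, 3L]), 0)
})
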