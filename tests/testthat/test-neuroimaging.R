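geomSmall <- toyLabelMap(32L)

makePair <- function(t2w, t1w, mask, id = "s") {
  new("VolumePair", t1w = t1w, t2w = t2w, mask = mask, subjectId = id)
}

test_that("ratio maps divide T2w by T1w and drop undefined voxels", {
  d <- c(8, 8, 8)
  mask <- array(TRUE, d)
  a <- array(3, d); b <- array(2, d)
  r <- ratioMap(makePair(a, b, mask))
  expect_equal(unique(r$ratio[r$mask]), 1.5)
  ## coil-loading invariance: scaling both images leaves the ratio alone
  r2 <- ratioMap(makePair(a * 1.37, b * 1.37, mask))
  expect_equal(r2$ratio, r$ratio, tolerance = 1e-12)
  ## t1w = 0 voxels are excluded from the mask
  b0 <- b; b0[1, 1, 1] <- 0
  r3 <- ratioMap(makePair(a, b0, mask))
  expect_false(r3$mask[1, 1, 1])
  expect_true(is.na(r3$ratio[1, 1, 1]))
  ## shape mismatch rejected at construction
  expect_error(makePair(array(1, c(8, 8, 7)), b, mask), "dimensions")
})

test_that("voxelwise Welch t matches stats::t.test voxel by voxel", {
  set.seed(21)
  d <- c(6, 6, 6); mask <- array(TRUE, d)
  ga <- lapply(1:4, function(i) array(rnorm(prod(d), 1), d))
  gb <- lapply(1:5, function(i) array(rnorm(prod(d), 1.2), d))
  vc <- voxelwiseContrast(ga, gb, mask)
  for (v in sample(prod(d), 8)) {
    av <- vapply(ga, function(x) x[v], numeric(1))
    bv <- vapply(gb, function(x) x[v], numeric(1))
    tt <- t.test(av, bv)
    expect_equal(vc$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(vc$p[v], tt$p.value, tolerance = 1e-10)
  }
  ## BH adjustment over in-mask voxels only
  expect_equal(vc$q[mask], p.adjust(vc$p[mask], method = "BH"))
})

test_that("contrasts are antisymmetric and null contrasts are empty", {
  set.seed(22)
  d <- c(6, 6, 6); mask <- array(TRUE, d)
  ga <- lapply(1:4, function(i) array(rnorm(prod(d)), d))
  gb <- lapply(1:4, function(i) array(rnorm(prod(d)), d))
  ab <- voxelwiseContrast(ga, gb, mask)
  ba <- voxelwiseContrast(gb, ga, mask)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$sig, -ba$sig)
  ## identical groups: empty significance mask
  same <- voxelwiseContrast(ga, ga, mask)
  expect_true(all(same$sig == 0))
  expect_error(voxelwiseContrast(ga[1], gb, mask), "at least 2")
})

test_that("ROI summaries average within labels and reject empty ROIs", {
  lm_ <- geomSmall$labels
  const <- array(0.7, dim(lm_@labels))
  rs <- roiSummary(list(s1 = const), lm_)
  expect_equal(as.numeric(rs[1, names(lm_@dictionary)]),
               rep(0.7, length(lm_@dictionary)))
  ## checkerboard 0/1 in an even-sized ROI -> mean 0.5
  labs8 <- array(0L, c(4, 4, 4)); labs8[1:8] <- 2L
  even <- new("RoiLabelMap", labels = labs8, dictionary = c(box = 2L))
  vol <- array(0, c(4, 4, 4)); vol[seq(1, 8, by = 2)] <- 1
  expect_equal(roiSummary(list(s1 = vol), even)$box, 0.5)
  ## hand-sized 3-voxel ROI
  labs <- array(0L, c(4, 4, 4)); labs[1:3] <- 9L
  tiny <- new("RoiLabelMap", labels = labs, dictionary = c(tiny = 9L))
  v <- array(0, c(4, 4, 4)); v[1:3] <- c(1, 2, 6)
  expect_equal(roiSummary(list(s = v), tiny)$tiny, 3)
  ## empty ROI errors, naming the label
  empty <- new("RoiLabelMap", labels = labs,
               dictionary = c(tiny = 9L, gone = 5L))
  expect_error(roiSummary(list(s = v), empty), "gone")
  ## subject order permutation leaves per-subject values unchanged
  vols <- list(a = v, b = v * 2, c = v * 3)
  r1 <- roiSummary(vols, tiny)
  r2 <- roiSummary(vols[c(3, 1, 2)], tiny)
  expect_equal(r1[match(r2$subject, r1$subject), "tiny"], r2$tiny)
})

test_that("Dunnett reduces to the pooled t-test for one comparison", {
  set.seed(23)
  y <- c(rnorm(10), rnorm(12, 0.8))
  g <- rep(c("CC", "TT"), c(10, 12))
  d <- anovaDunnett(y, g, control = "CC")
  tt <- t.test(y[g == "TT"], y[g == "CC"], var.equal = TRUE)
  expect_equal(d$comparisons$p_adjusted, tt$p.value, tolerance = 1e-10)
  expect_equal(d$comparisons$p_unadjusted, tt$p.value, tolerance = 1e-10)
})

test_that("Dunnett adjusted p is monotone and matches multcomp", {
  skip_if_not_installed("multcomp")
  set.seed(24)
  y <- c(rnorm(15, 0), rnorm(15, 0.5), rnorm(15, 0.9))
  g <- factor(rep(c("CC", "CT", "TT"), each = 15))
  d <- anovaDunnett(y, g, control = "CC", nsim = 4e5, seed = 3)
  expect_true(all(d$comparisons$p_adjusted >=
                    d$comparisons$p_unadjusted - 1e-12))
  fit <- stats::aov(y ~ g)
  mc <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  pm <- summary(mc)$test$pvalues
  expect_equal(d$comparisons$p_adjusted, as.numeric(pm), tolerance = 0.01)
  ## ANOVA part matches the closed-form oracle
  o <- oracleAnovaF(y, g)
  expect_equal(d$anova$F, o$F, tolerance = 1e-10)
  expect_equal(d$anova$p, o$p, tolerance = 1e-10)
  expect_error(anovaDunnett(y, g, control = "ZZ"), "absent")
})

test_that("Dunnett critical value matches the equicoordinate reference", {
  ## reference values computed independently with mvtnorm::qmvt
  ## (balanced correlation 0.5) and confirmed by raw-data simulation:
  ## k = 2, df = 20 -> 2.379; k = 3, df = 30 -> 2.472
  cv <- dunnettCritical(k = 2, df = 20, nsim = 4e5, seed = 5)
  expect_equal(cv, 2.379, tolerance = 0.01)
  cv3 <- dunnettCritical(k = 3, df = 30, nsim = 4e5, seed = 5)
  expect_equal(cv3, 2.472, tolerance = 0.01)
})

test_that("LDA separates, calibrates, and matches oracles", {
  set.seed(25)
  ## perfectly separated classes -> AUC 1
  xs <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 5, 0.1), 20))
  lab <- rep(c("CC", "TT"), each = 20)
  expect_equal(ldaClassify(xs, lab)$auc, 1.0)
  ## AUC equals brute-force pair counting
  x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 0.8), 30))
  l2 <- ldaClassify(x, rep(c("CC", "TT"), each = 30))
  expect_equal(l2$auc, oracleAuc(l2$scores, rep(c(FALSE, TRUE), each = 30)))
  ## permuted labels -> mean leave-one-out AUC ~ 0.5 (the resubstitution
  ## AUC is optimistically biased above 0.5 by construction)
  aucs <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    ldaClassify(x, sample(rep(c("CC", "TT"), each = 30)), loo = TRUE)$auc
  }, numeric(1))
  ## LOO scores are mildly pessimistic under the null (the held-out point
  ## repels its own class mean), so allow a symmetric band around 0.5
  expect_gt(mean(aucs), 0.42)
  expect_lt(mean(aucs), 0.58)
  ## ROC endpoints
  expect_equal(range(l2$roc$tpr), c(0, 1))
  expect_equal(range(l2$roc$fpr), c(0, 1))
  expect_error(ldaClassify(x[, 1, drop = FALSE],
                           rep(c("CC", "TT"), each = 30)), "2 features")
})

test_that("LDA direction matches MASS::lda and AUC matches pROC", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("pROC")
  set.seed(26)
  x <- rbind(matrix(rnorm(90), 30), matrix(rnorm(90, 0.7), 30))
  colnames(x) <- c("GPi", "SN", "LPut")
  lab <- rep(c("CC", "TT"), each = 30)
  mine <- ldaClassify(x, lab)
  ref <- MASS::lda(x, grouping = lab)
  ## directions proportional (standardization changes the basis)
  wref <- as.numeric(ref$scaling)
  wmine <- mine$weights / apply(x, 2, sd)  # undo standardization
  expect_equal(abs(cor(wmine, wref)), 1, tolerance = 1e-6)
  pauc <- as.numeric(pROC::auc(pROC::roc(lab, mine$scores, levels = c("CC", "TT"),
                                         direction = "<", quiet = TRUE)))
  expect_equal(mine$auc, pauc, tolerance = 1e-10)
})

test_that("leave-one-out scoring is honest for small samples", {
  set.seed(27)
  x <- matrix(rnorm(40), 20)  # pure noise
  lab <- rep(c("CC", "TT"), each = 10)
  full <- ldaClassify(x, lab)$auc
  loo <- ldaClassify(x, lab, loo = TRUE)$auc
  expect_lte(loo, full)  # resubstitution optimism on noise
})

test_that("a configured GPi decrease produces an overlapping negative cluster", {
  ## strong, low-noise effect: the significant voxels should tile the ROI
  co <- generateCohort(c(CC = 12, CT = 2, TT = 12), seed = 30)
  eff <- defaultMriEffects()
  eff$roi_offsets <- list(CC = c(GPi = 0), CT = c(GPi = 0),
                          TT = c(GPi = -0.04))
  eff$subject_sd <- c(GPi = 0.01)
  eff$voxel_noise_sd <- 0.015
  geom <- geomSmall
  pairs <- generateVolumePairs(co, geom, eff, seed = 31)
  g <- co$genotype
  ratios <- lapply(pairs, function(p) ratioMap(p)$ratio)
  vc <- voxelwiseContrast(ratios[g == "TT"], ratios[g == "CC"], geom$mask)
  gpi <- geom$labels@labels == geom$labels@dictionary[["GPi"]]
  inter <- sum(vc$sig == -1 & gpi)
  dice <- 2 * inter / (sum(gpi) + sum(vc$sig != 0))
  expect_gt(dice, 0.5)
  ## detected voxels are negative (TT below CC)
  expect_gte(sum(vc$sig == -1 & gpi), sum(vc$sig == 1 & gpi))
})

test_that("volume NIfTI I/O round-trips", {
  v <- array(runif(8 * 8 * 8), c(8, 8, 8))
  tmp <- tempfile(fileext = ".nii.gz")
  writeVolume(v, tmp)
  v2 <- readVolume(tmp)
  expect_equal(v2, v, tolerance = 1e-6)
})
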