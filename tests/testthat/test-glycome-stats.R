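panel <- buildDefaultPanel()

test_that("category aggregation sums member species", {
  ## all mass on one bi-antennary species
  prof <- setNames(rep(0, length(panel)), panelNames(panel))
  prof["A2G2S2"] <- 100
  agg <- aggregateByCategory(prof, panel)
  expect_equal(agg[["bi-antennary"]], 100)
  expect_equal(agg[["tri-antennary"]], 0)
  ## partition categories cover any profile
  prof2 <- randomProfile(panel, seed = 2)
  agg2 <- aggregateByCategory(prof2, panel)
  part <- c("mono-antennary", "bi-antennary", "tri-antennary",
            "tetra-antennary", "high-mannose", "hybrid")
  expect_equal(sum(agg2[part]), 100, tolerance = 1e-9)
  ## hand-built 3-species profile vs manual addition
  prof3 <- setNames(rep(0, length(panel)), panelNames(panel))
  prof3[c("A2G2S1", "A2G2S2", "A3G3S3")] <- c(25, 35, 40)
  agg3 <- aggregateByCategory(prof3, panel)
  expect_equal(agg3[["bi-antennary"]], 25 + 35)
  expect_equal(agg3[["tri-antennary"]], 40)
  ## unknown species rejected
  bad <- c(prof3, NOPE = 1)
  expect_error(aggregateByCategory(bad, panel), "unknown")
})

test_that("aggregation is linear: mean of sums equals sum of means", {
  co <- generateCohort(5, seed = 1)
  gl <- generateGlycomeProfiles(co, panel, seed = 3)
  m <- glycomePercent(gl)
  catm <- aggregateByCategory(gl)
  expect_equal(rowMeans(catm),
               aggregateByCategory(rowMeans(m), panel),
               tolerance = 1e-10)
})

test_that("monosaccharide contribution is an abundance-weighted average", {
  prof <- setNames(rep(0, length(panel)), panelNames(panel))
  prof["M5"] <- 100  # HexNAc2 Hex5
  mc <- monosaccharideContribution(prof, panel, splitHex = FALSE)
  expect_equal(mc[["GlcNAc"]], 100 * 2 / 7, tolerance = 1e-9)
  expect_equal(mc[["Hex"]], 100 * 5 / 7, tolerance = 1e-9)
  ## contributions always sum to 100
  mc2 <- monosaccharideContribution(randomProfile(panel, seed = 4), panel)
  expect_equal(sum(mc2), 100, tolerance = 1e-9)
  ## 50/50 two-glycan mixture: weighted average of per-glycan fractions
  prof3 <- setNames(rep(0, length(panel)), panelNames(panel))
  prof3[c("M5", "A2G1S1")] <- 50
  mc3 <- monosaccharideContribution(prof3, panel, splitHex = FALSE)
  # A2G1S1 = HexNAc4 Hex4 NeuAc1 (9 residues)
  expect_equal(mc3[["GlcNAc"]], 50 * 2 / 7 + 50 * 4 / 9, tolerance = 1e-9)
  expect_equal(mc3[["NeuAc"]], 50 * 1 / 9, tolerance = 1e-9)
  ## mass weighting changes the numbers but not the total
  mcm <- monosaccharideContribution(prof3, panel, weight = "mass")
  expect_equal(sum(mcm), 100, tolerance = 1e-9)
})

test_that("group comparison matches hand-computed Welch and ANOVA", {
  a <- c(88.1, 87.4, 89.0)
  b <- c(90.3, 90.9, 89.8)
  c_ <- c(90.0, 91.2, 90.4)
  y <- matrix(c(a, b, c_), nrow = 1,
              dimnames = list("bi", NULL))
  g <- rep(c("CC", "CT", "TT"), each = 3)
  res <- groupCompare(y, g, reference = "CC")
  expect_equal(res$anova_df, 2)  # three genotypes
  expect_equal(res$anova_F, oracleAnovaF(as.numeric(y), g)$F,
               tolerance = 1e-10)
  expect_equal(res$anova_p, oracleAnovaF(as.numeric(y), g)$p,
               tolerance = 1e-10)
  expect_equal(res$p_CC_vs_CT, oracleWelch(a, b)$p, tolerance = 1e-10)
  expect_equal(res$p_CC_vs_TT, oracleWelch(a, c_)$p, tolerance = 1e-10)
  expect_equal(res$p_CT_vs_TT, oracleWelch(b, c_)$p, tolerance = 1e-10)
  expect_equal(res$mean_CC, mean(a))
  expect_equal(res$sem_CC, sd(a) / sqrt(3), tolerance = 1e-12)
  expect_equal(res$relchange_CT, 100 * (mean(b) - mean(a)) / mean(a),
               tolerance = 1e-10)
  expect_equal(res$relchange_CC, 0)
})

test_that("identical groups give F = 0 and p = 1", {
  y <- matrix(rep(c(1, 2, 3), 3), nrow = 1)
  g <- rep(c("CC", "CT", "TT"), each = 3)
  res <- groupCompare(y, g)
  expect_equal(res$anova_F, 0, tolerance = 1e-20)
  expect_equal(res$p_CC_vs_CT, 1)
  ## degenerate: all values identical
  res0 <- groupCompare(matrix(rep(5, 9), nrow = 1), g)
  expect_equal(res0$anova_F, 0)
  expect_equal(res0$p_CC_vs_TT, 1)
})

test_that("p-values are invariant to relabeling non-reference groups", {
  set.seed(8)
  y <- matrix(rnorm(30), nrow = 1)
  g <- rep(c("CC", "CT", "TT"), each = 10)
  r1 <- groupCompare(y, g, reference = "CC")
  g2 <- g; g2[g == "CT"] <- "TT"; g2[g == "TT"] <- "CT"
  r2 <- groupCompare(y, g2, reference = "CC")
  expect_equal(r1$anova_p, r2$anova_p)
  expect_equal(r1$p_CC_vs_CT, r2$p_CC_vs_TT)
})

test_that("groups with fewer than 2 samples are rejected", {
  expect_error(groupCompare(matrix(1:4, nrow = 1),
                            c("CC", "CC", "CC", "TT")), "at least 2")
})

test_that("relative-change matrix clips for display but keeps data", {
  y <- matrix(c(1, 1, 1, 3, 3, 3), nrow = 1,
              dimnames = list("f", NULL))
  res <- groupCompare(y, rep(c("CC", "TT"), each = 3), reference = "CC")
  rc <- relativeChangeMatrix(res, "CC")
  expect_equal(unname(rc$change[, "CC"]), 0)
  expect_equal(unname(rc$change[, "TT"]), 200)   # data retained
  expect_equal(unname(rc$display[, "TT"]), 50)   # clipped at +50
  expect_equal(rc$clip, 50)
  ## absolute-abundance variant clips at +/-5
  rc5 <- relativeChangeMatrix(res, "CC", clip = 5)
  expect_equal(unname(rc5$display[, "TT"]), 5)
  ## zero reference mean flags undefined change
  y0 <- matrix(c(0, 0, 0, 1, 2, 3), nrow = 1, dimnames = list("z", NULL))
  res0 <- groupCompare(y0, rep(c("CC", "TT"), each = 3), reference = "CC")
  expect_warning(rc0 <- relativeChangeMatrix(res0, "CC"), "undefined")
  expect_true(is.na(rc0$change[1, "TT"]))
})

test_that("paired change tables report pre/post/comparator structure", {
  pre <- panelBaseline(panel)
  expect_equal(pairedChangeTable(pre, pre)$abs_change,
               rep(0, length(pre)))
  ## comparator column echoes the supplied group mean exactly
  tab <- pairedChangeTable(pre, pre, comparator = pre)
  expect_equal(tab$comparator, as.numeric(pre))
  expect_error(pairedChangeTable(pre, pre[-1]), "different features")
  ## injected CDG-like pattern: A2G1S1 elevated pre, reversed post;
  ## large glycans suppressed pre, restored post
  post <- pre
  pre2 <- pre
  pre2["A2G1S1"] <- pre["A2G1S1"] * 4
  pre2[c("A3G3S3", "A3FG3S3")] <- pre[c("A3G3S3", "A3FG3S3")] * 0.5
  pre2 <- 100 * pre2 / sum(pre2)
  tab2 <- pairedChangeTable(pre2, post)
  expect_lt(tab2$abs_change[tab2$feature == "A2G1S1"], 0)
  expect_gt(tab2$abs_change[tab2$feature == "A3G3S3"], 0)
  expect_gt(tab2$abs_change[tab2$feature == "A3FG3S3"], 0)
  ## category-level version shows the branching recovery signature
  cat_pre <- aggregateByCategory(pre2, panel)
  cat_post <- aggregateByCategory(post, panel)
  ctab <- pairedChangeTable(cat_pre, cat_post)
  expect_gt(ctab$abs_change[ctab$feature == "tri-antennary"], 0)
})

test_that("type-I error is calibrated under the null generator", {
  ## no genotype effect, 30/30/30, per-glycan ANOVA across 200 seeded reps
  co <- generateCohort(30, seed = 1)
  g <- co$genotype
  fr <- vapply(1:200, function(r) {
    gl <- generateGlycomeProfiles(co, panel,
                                  effects = list(category_means = NULL),
                                  seed = 1000 + r)
    res <- groupCompare(glycomePercent(gl), g)
    mean(res$anova_p < 0.05)
  }, numeric(1))
  ## no inflation beyond the nominal level (upper binomial-style bound);
  ## mild conservatism is expected for skewed low-abundance features
  expect_lt(mean(fr), 0.05 + 2.58 * sd(fr) / sqrt(length(fr)))
  expect_gt(mean(fr), 0.03)
})

test_that("branching effect signs are recovered at study scale", {
  ## bi up, tri down in carriers: sign recovered in >= 95% of seeded reps
  co <- generateCohort(30, seed = 2)
  g <- co$genotype
  hits <- vapply(1:100, function(r) {
    gl <- generateGlycomeProfiles(co, panel, seed = 2000 + r)
    catm <- aggregateByCategory(gl)
    res <- groupCompare(catm[c("bi-antennary", "tri-antennary"), ], g,
                        reference = "CC")
    bi <- res[res$feature == "bi-antennary", ]
    tri <- res[res$feature == "tri-antennary", ]
    bi$relchange_CT > 0 && bi$relchange_TT > 0 &&
      tri$relchange_CT < 0 && tri$relchange_TT < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stratified comparison facets over a metadata column", {
  co <- generateCohort(10, seed = 3)
  gl <- generateGlycomeProfiles(co, panel, seed = 4)
  catm <- aggregateByCategory(gl)
  by_sex <- groupCompareBy(catm, co$genotype, co$sex, reference = "CC")
  expect_setequal(names(by_sex), c("M", "F"))
  expect_equal(nrow(by_sex$M), nrow(catm))
})
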