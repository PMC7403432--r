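test_that("MDL is the one-sided 99% t quantile times the replicate SD", {
  ## seven identical values -> MDL 0
  qc <- matrix(rep(1, 7), nrow = 1, dimnames = list("Mn", NULL))
  expect_equal(unname(computeMdl(qc)), 0)
  ## replicate SD 0.01 -> t(0.99, 6) * 0.01, from the t-quantile oracle
  set.seed(5)
  x <- rnorm(7)
  x <- (x - mean(x)) / sd(x) * 0.01 + 1  # exact SD 0.01
  mdl <- computeMdl(matrix(x, nrow = 1, dimnames = list("Mn", NULL)))
  expect_equal(unname(mdl), qt(0.99, df = 6) * 0.01, tolerance = 1e-12)
  expect_equal(unname(mdl), 0.0314, tolerance = 1e-3)
  ## linearity: scaling replicates scales the MDL
  mdl_k <- computeMdl(matrix(3.7 * x, nrow = 1))
  expect_equal(unname(mdl_k), 3.7 * unname(mdl), tolerance = 1e-12)
  ## 3sd alternative
  expect_equal(unname(computeMdl(matrix(x, nrow = 1), method = "3sd")),
               0.03, tolerance = 1e-12)
  expect_error(computeMdl(matrix(1, nrow = 1, ncol = 1)), "at least 2")
})

test_that("mean-above-MDL filter reproduces the 16/7 detectability split", {
  co <- generateCohort(c(CC = 46, CT = 46, TT = 25), seed = 1)
  panel <- generateElementPanel(co, seed = 2)
  f <- filterElements(panel)
  expect_equal(length(f$included), 16L)
  expect_equal(length(f$excluded), 7L)
  ## the excluded set is the designated sub-MDL class
  expect_setequal(f$excluded, c("Be", "Cd", "Ni", "Pt", "Te", "Tl", "W"))
  ## partition is exhaustive and disjoint
  expect_equal(length(f$included) + length(f$excluded), 23L)
  expect_length(intersect(f$included, f$excluded), 0L)
  expect_equal(nrow(f$audit), 23L)
})

test_that("filter uses a strict inequality against the MDL", {
  co <- generateCohort(3, seed = 3)
  conc <- matrix(1, nrow = 23, ncol = 9,
                 dimnames = list(elementSymbols(),
                                 sprintf("s%d", 1:9)))
  mdl <- setNames(rep(0.5, 23), elementSymbols())
  ep <- ElementExperiment(conc, mdl, colData = co)
  expect_equal(length(filterElements(ep)$included), 23L)
  ## mean exactly equal to the MDL -> excluded
  mdl2 <- setNames(rep(1, 23), elementSymbols())
  ep2 <- ElementExperiment(conc, mdl2, colData = co)
  expect_equal(length(filterElements(ep2)$included), 0L)
})

test_that("genotype statistics ignore excluded elements entirely", {
  co <- generateCohort(c(CC = 20, CT = 20, TT = 20), seed = 4)
  panel <- generateElementPanel(co, seed = 5)
  st <- elementGenotypeStats(panel)
  f <- filterElements(panel)
  expect_setequal(st$feature, f$included)
  ## re-including an excluded element changes no originally included
  ## element's own statistics (the cross-feature BH column aside, which by
  ## definition spans whatever feature set is included)
  conc <- elementConc(panel)
  conc["Cd", ] <- conc["Cd", ] * 1000
  panel2 <- ElementExperiment(conc, elementMdl(panel), colData = co)
  st2 <- elementGenotypeStats(panel2)
  keep_cols <- setdiff(colnames(st), "fdr_q")
  a <- st2[match(f$included, st2$feature), keep_cols]
  b <- st[match(f$included, st$feature), keep_cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("percent reductions match the printed group means", {
  expect_equal(percentReduction(0.814, 0.732), 10)
  expect_equal(percentReduction(0.814, 0.669), 18)
  expect_equal(percentReduction(0.814, 0.732, digits = NA), 10.07,
               tolerance = 1e-2)
  expect_equal(percentReduction(0.814, 0.669, digits = NA), 17.81,
               tolerance = 1e-2)
  expect_equal(percentReduction(0.5, 0.5), 0)
  expect_error(percentReduction(0, 1), "positive")
})

test_that("covariate regression matches the closed-form OLS oracle", {
  co <- generateCohort(4, seed = 6)
  conc <- matrix(1, nrow = 23, ncol = nrow(co),
                 dimnames = list(elementSymbols(), co$sample_id))
  ## exact linear relation y = 2x
  conc["Mn", ] <- 2 * co$age
  ep <- ElementExperiment(conc, setNames(rep(0.1, 23), elementSymbols()),
                          colData = co)
  r <- suppressWarnings(covariateRegression(ep, "Mn", "age"))
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_lt(r$p, 1e-10)
  ## hand-computed 4-point fit
  x <- c(1, 2, 3, 5); y <- c(2.1, 3.9, 6.2, 9.7)
  co4 <- co[1:4, ]; co4$age <- x
  conc4 <- conc[, 1:4]; conc4["Mn", ] <- y
  ep4 <- ElementExperiment(conc4, setNames(rep(0.1, 23), elementSymbols()),
                           colData = co4)
  r4 <- covariateRegression(ep4, "Mn", "age")
  o <- oracleOls(x, y)
  expect_equal(r4$slope, o$slope, tolerance = 1e-10)
  expect_equal(r4$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(r4$p, o$p, tolerance = 1e-10)
  ## constant covariate rejected
  co4$bmi <- 25
  ep5 <- ElementExperiment(conc4, setNames(rep(0.1, 23), elementSymbols()),
                           colData = co4)
  expect_error(covariateRegression(ep5, "Mn", "bmi"), "constant")
})

test_that("Mn p-values are uniform under the null configuration", {
  co <- generateCohort(c(CC = 30, CT = 30, TT = 30), seed = 7)
  ps <- vapply(1:60, function(r) {
    ep <- generateElementPanel(co, effects = list(mn_genotype_means = NULL),
                               seed = 3000 + r)
    y <- elementConc(ep)["Mn", ]
    oracleAnovaF(y, co$genotype)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("configured genotype means are recovered within sampling error", {
  ## estimated group means within 2 SEM of 0.814/0.732/0.669 in >= 95%
  ## of seeded reps
  co <- generateCohort(c(CC = 46, CT = 46, TT = 25), seed = 8)
  target <- c(CC = 0.814, CT = 0.732, TT = 0.669)
  hits <- vapply(1:50, function(r) {
    ep <- generateElementPanel(co, seed = 4000 + r)
    y <- elementConc(ep)["Mn", ]
    ok <- vapply(names(target), function(g) {
      v <- y[co$genotype == g]
      abs(mean(v) - target[[g]]) < 2 * sd(v) / sqrt(length(v))
    }, logical(1))
    all(ok)
  }, logical(1))
  ## a single 2-SEM interval covers ~95%; three simultaneous checks are
  ## expected to all hold in ~87% of reps
  expect_gte(mean(hits), 0.75)
})

test_that("large-sample Mn means converge to the configured values", {
  co <- generateCohort(500, seed = 9)
  ep <- generateElementPanel(co, seed = 10)
  y <- elementConc(ep)["Mn", ]
  mu <- tapply(y, co$genotype, mean)
  expect_equal(as.numeric(mu[c("CC", "CT", "TT")]),
               c(0.814, 0.732, 0.669), tolerance = 0.02)
})
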