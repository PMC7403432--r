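## Seeded synthetic-cohort generation.  The generators emulate the
## statistical structure of the reference cohort design: genotype groups matched on
## age, sex and BMI; a genotype-graded serum Mn reduction against an
## otherwise null 23-element panel with a fixed detectability split; a
## compositional plasma N-glycome with genotype-graded branching shifts;
## and T2w/T1w volumes with genotype-dependent regional ratio offsets.
## Every generator is bit-reproducible given (config, seed) and returns
## its ground truth alongside the data.

#' Generate a matched synthetic cohort table
#'
#' Draws one base set of age/sex/BMI covariates and shares it across
#' genotypes (perfect matching), then adds a small jitter, emulating a
#' genotype-matched biobank selection.
#'
#' @param n_per_genotype Samples per genotype: a scalar or a named vector
#'   over \code{c("CC","CT","TT")} (e.g. \code{c(CC=46, CT=46, TT=25)}).
#' @param seed RNG seed.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate distribution
#'   parameters (years; kg/m2).
#' @param jitter_sd Matching jitter on age/BMI.
#' @return \code{data.frame}: sample_id, genotype, sex, age, bmi.
#' @examples
#' head(generateCohort(5, seed = 1))
#' @export
generateCohort <- function(n_per_genotype, seed = 1L, age_mean = 55,
                           age_sd = 8, bmi_mean = 27, bmi_sd = 4,
                           jitter_sd = 1) {
  genos <- c("CC", "CT", "TT")
  n <- if (length(n_per_genotype) == 1L)
    stats::setNames(rep(as.integer(n_per_genotype), 3L), genos)
  else n_per_genotype[genos]
  if (any(n < 2L)) stop("need at least 2 samples per genotype")
  nmax <- max(n)
  withSeed(seed, {
    base_age <- stats::rnorm(nmax, age_mean, age_sd)
    base_bmi <- stats::rnorm(nmax, bmi_mean, bmi_sd)
    base_sex <- sample(rep(c("M", "F"), length.out = nmax))
    rows <- lapply(genos, function(g) {
      i <- seq_len(n[[g]])
      data.frame(sample_id = sprintf("%s_%03d", g, i), genotype = g,
                 sex = base_sex[i],
                 age = pmax(base_age[i] + stats::rnorm(n[[g]], 0, jitter_sd), 18),
                 bmi = pmax(base_bmi[i] + stats::rnorm(n[[g]], 0, jitter_sd), 15))
    })
    do.call(rbind, rows)
  })
}

#' Default glycome effect configuration
#'
#' Genotype-specific target category means (percent): the reference (CC)
#' branching profile with a shift of abundance from tri-/tetra-antennary
#' toward bi-antennary species in carriers, and the Dirichlet
#' concentration controlling between-sample compositional noise.
#' Unlisted partition categories keep their baseline values; the target
#' vector is renormalized to 100 after assembly (printed rounded targets
#' need not sum exactly).
#'
#' @return List with \code{category_means} (genotype -> named percent
#'   vector over the partition categories) and \code{concentration}.
#' @export
defaultGlycomeEffects <- function() {
  list(category_means = list(
    CC = c(`bi-antennary` = 88.0, `tri-antennary` = 6.77,
           `tetra-antennary` = 0.574),
    CT = c(`bi-antennary` = 90.2, `tri-antennary` = 4.99,
           `tetra-antennary` = 0.420),
    TT = c(`bi-antennary` = 90.1, `tri-antennary` = 4.91,
           `tetra-antennary` = 0.457)),
    concentration = 150)
}

## assemble a genotype mean profile: scale species within each targeted
## category to hit its target total, keep others at baseline, renormalize
.genotypeMeanProfile <- function(panel, targets) {
  sp <- panelSpecies(panel)
  prof <- panelBaseline(panel)
  cats <- defaultCategories()[.partitionCategories]
  current <- vapply(cats, function(pred) sum(prof[pred(sp)]), numeric(1))
  full <- current
  full[names(targets)] <- targets
  if (abs(sum(full) - 100) > 0.5)
    stop("configured category means sum to ", round(sum(full), 2),
         "; must sum to 100 (within rounding)")
  for (cat in names(targets)) {
    member <- cats[[cat]](sp)
    if (current[[cat]] > 0)
      prof[member] <- prof[member] * targets[[cat]] / current[[cat]]
  }
  100 * prof / sum(prof)
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate synthetic glycome profiles for a cohort
#'
#' Per-sample abundance vectors are drawn from a Dirichlet distribution
#' around genotype-specific mean profiles (compositional: every draw sums
#' to 100 by construction).  Genotype means redistribute mass between
#' antennarity categories per the effect configuration while scaling
#' species within a category proportionally.
#'
#' @param cohort Cohort table from \code{\link{generateCohort}}.
#' @param panel A \code{\linkS4class{GlycanPanel}}.
#' @param effects Effect configuration
#'   (default \code{\link{defaultGlycomeEffects}}); set
#'   \code{concentration = Inf} for noise-free draws and
#'   \code{category_means = NULL} for a null (no-effect) configuration.
#' @param seed RNG seed.
#' @return A \code{\linkS4class{GlycomeExperiment}} whose metadata
#'   carries \code{ground_truth}: the genotype mean profiles and the
#'   configured category means.
#' @export
generateGlycomeProfiles <- function(cohort, panel = buildDefaultPanel(),
                                    effects = defaultGlycomeEffects(),
                                    seed = 1L) {
  effects <- utils::modifyList(defaultGlycomeEffects(), effects,
                               keep.null = TRUE)
  genos <- unique(cohort$genotype)
  means <- lapply(stats::setNames(genos, genos), function(g) {
    tg <- effects$category_means[[g]]
    if (is.null(tg)) panelBaseline(panel)
    else .genotypeMeanProfile(panel, tg)
  })
  conc <- effects$concentration
  m <- withSeed(seed, {
    vapply(seq_len(nrow(cohort)), function(i) {
      mu <- means[[cohort$genotype[i]]] / 100
      if (is.infinite(conc)) 100 * mu
      else 100 * .rdirichlet(conc * mu)
    }, numeric(length(panel)))
  })
  rownames(m) <- panelNames(panel)
  colnames(m) <- cohort$sample_id
  out <- GlycomeExperiment(m, panel, colData = cohort)
  metadata(out)$ground_truth <- list(genotype_means = means,
                                     category_means = effects$category_means,
                                     concentration = conc)
  out
}

#' Default trace-element generator configuration
#'
#' Per-element geometric mean concentrations (ug/L), configured MDLs and a
#' common coefficient of variation.  Sixteen elements have means well
#' above their MDLs; seven (Be, Cd, Ni, Pt, Te, Tl, W) sit below, giving
#' the canonical 16-included / 7-excluded detectability split.  Only Mn
#' carries a genotype effect by default, with genotype means
#' 0.814/0.732/0.669 ug/L for CC/CT/TT.  The CV (20 percent) is
#' calibrated so the configured Mn contrasts reproduce the reference
#' significance pattern at the reference group sizes.
#'
#' @return List with \code{means}, \code{mdls}, \code{cv},
#'   \code{mn_genotype_means}, \code{qc_level_factor}.
#' @export
defaultElementEffects <- function() {
  means <- c(As = 2.0, Ba = 1.5, Be = 0.05, Cd = 0.04, Co = 0.25,
             Cr = 0.5, Cs = 0.8, Cu = 1000, Hg = 1.0, Mn = 0.814,
             Mo = 1.0, Ni = 0.15, Pb = 0.8, Pt = 0.0125, Sb = 0.3,
             Se = 110, Sn = 0.3, Te = 0.1, Tl = 0.02, U = 0.05,
             V = 0.1, W = 0.0225, Zn = 900)
  mdls <- c(As = 0.3, Ba = 0.3, Be = 0.2, Cd = 0.16, Co = 0.05,
            Cr = 0.12, Cs = 0.1, Cu = 2, Hg = 0.2, Mn = 0.25,
            Mo = 0.2, Ni = 0.6, Pb = 0.15, Pt = 0.05, Sb = 0.08,
            Se = 5, Sn = 0.09, Te = 0.4, Tl = 0.08, U = 0.015,
            V = 0.03, W = 0.09, Zn = 3)
  list(means = means, mdls = mdls, cv = 0.20,
       mn_genotype_means = c(CC = 0.814, CT = 0.732, TT = 0.669),
       qc_level_factor = 2)
}

#' Generate a synthetic trace-element panel with QC runs
#'
#' Concentrations are lognormal (positive, right-skewed) around per-element
#' means; only Mn's mean depends on genotype (set
#' \code{mn_genotype_means = NULL} for a null configuration).  Seven
#' designated elements have means below their MDLs.  QC replicate runs
#' (7 per element) are drawn so that \code{\link{computeMdl}} recovers the
#' configured MDLs in expectation.
#'
#' @param cohort Cohort table from \code{\link{generateCohort}}.
#' @param effects Configuration (default
#'   \code{\link{defaultElementEffects}}).
#' @param seed RNG seed.
#' @param n_qc_runs QC replicates per element (default 7).
#' @return An \code{\linkS4class{ElementExperiment}} (MDLs derived from
#'   the generated QC runs; ground truth in \code{metadata}).
#' @export
generateElementPanel <- function(cohort, effects = defaultElementEffects(),
                                 seed = 1L, n_qc_runs = 7L) {
  effects <- utils::modifyList(defaultElementEffects(), effects,
                               keep.null = TRUE)
  elems <- elementSymbols()
  nsamp <- nrow(cohort)
  sdlog <- sqrt(log(1 + effects$cv^2))
  seeds <- .subSeeds(seed, 2L)
  conc <- withSeed(seeds[1L], {
    m <- vapply(elems, function(el) {
      mu <- rep(effects$means[[el]], nsamp)
      if (el == "Mn" && !is.null(effects$mn_genotype_means))
        mu <- effects$mn_genotype_means[cohort$genotype]
      ## lognormal with arithmetic mean mu and CV effects$cv
      stats::rlnorm(nsamp, log(mu) - sdlog^2 / 2, sdlog)
    }, numeric(nsamp))
    t(m)
  })
  colnames(conc) <- cohort$sample_id
  qc_sd <- effects$mdls / stats::qt(0.99, df = n_qc_runs - 1L)
  qc <- withSeed(seeds[2L], {
    t(vapply(elems, function(el)
      pmax(stats::rnorm(n_qc_runs,
                        effects$qc_level_factor * effects$mdls[[el]],
                        qc_sd[[el]]), 0),
      numeric(n_qc_runs)))
  })
  mdl <- computeMdl(qc)
  out <- ElementExperiment(conc, mdl, colData = cohort, qc_runs = qc)
  metadata(out)$ground_truth <- list(
    means = effects$means, configured_mdls = effects$mdls,
    cv = effects$cv, mn_genotype_means = effects$mn_genotype_means)
  out
}
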