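## End-to-end orchestration: simulate (or read) inputs, run each analysis
## stage, and write tidy CSV artifacts plus the resolved configuration so
## a run is reproducible from its output directory alone.

.resolveConfig <- function(config, defaults) {
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  cfg
}

.writeRunConfig <- function(cfg, outdir) {
  jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                       file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

.logMsg <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the glycome analysis stage
#'
#' Simulates (or accepts) a cohort's glycome, optionally routes every
#' profile through spectrum synthesis / peak picking / annotation /
#' normalization, and writes: the per-glycan genotype comparison table
#' (sorted by mean abundance, with a top-20 view), the category table,
#' the relative-change heat-map matrix and the monosaccharide
#' contribution table.
#'
#' @param config List: \code{seed}, \code{n_per_genotype},
#'   \code{effects}, \code{via_spectra} (route through synthetic spectra,
#'   default TRUE), \code{spectrum_params}, \code{reference} genotype.
#' @param outdir Output directory (created).
#' @param glycome Optional pre-built
#'   \code{\linkS4class{GlycomeExperiment}} (skips simulation).
#' @return Invisible list of result tables (per_glycan, top20, category,
#'   heatmap, monosaccharide).
#' @export
runGlycome <- function(config = list(), outdir = tempfile("glycome_"),
                       glycome = NULL) {
  cfg <- .resolveConfig(config, list(
    seed = 1L, n_per_genotype = c(CC = 33L, CT = 31L, TT = 25L),
    effects = defaultGlycomeEffects(), via_spectra = TRUE,
    spectrum_params = list(), reference = "CC"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  .logMsg(logfile, "glycome stage, seed=", cfg$seed)
  panel <- buildDefaultPanel()
  if (is.null(glycome)) {
    cohort <- generateCohort(cfg$n_per_genotype, seed = cfg$seed)
    glycome <- generateGlycomeProfiles(cohort, panel, cfg$effects,
                                       seed = cfg$seed + 1L)
  }
  m <- glycomePercent(glycome)
  genotype <- colData(glycome)$genotype
  if (isTRUE(cfg$via_spectra)) {
    .logMsg(logfile, "routing ", ncol(m), " profiles through spectra")
    seeds <- .subSeeds(cfg$seed + 2L, ncol(m))
    m <- vapply(seq_len(ncol(m)), function(i) {
      s <- synthesizeSpectrum(m[, i], panel, cfg$spectrum_params,
                              seed = seeds[i], sampleId = colnames(m)[i])
      quantifySpectrum(s, panel)
    }, numeric(nrow(m)))
    rownames(m) <- panelNames(panel)
    colnames(m) <- colnames(glycomePercent(glycome))
  }
  per_glycan <- groupCompare(m, genotype, cfg$reference)
  ord <- order(-rowMeans(m))
  per_glycan <- per_glycan[match(rownames(m)[ord], per_glycan$feature), ]
  top20 <- utils::head(per_glycan, 20L)
  catm <- aggregateByCategory(m, panel)
  category <- groupCompare(catm, genotype, cfg$reference)
  heat <- relativeChangeMatrix(category, cfg$reference)
  mono <- monosaccharideContribution(m, panel)
  mono_tab <- groupCompare(mono, genotype, cfg$reference)
  .writeCsvWithHeader(per_glycan, file.path(outdir, "per_glycan.csv"),
                      "per-glycan genotype comparison (percent abundance)")
  .writeCsvWithHeader(top20, file.path(outdir, "per_glycan_top20.csv"),
                      "20 most abundant glycans (percent abundance)")
  .writeCsvWithHeader(category, file.path(outdir, "category.csv"),
                      "structural-category genotype comparison (percent)")
  .writeCsvWithHeader(as.data.frame(heat$change),
                      file.path(outdir, "heatmap_relative_change.csv"),
                      "relative change vs reference (percent, clip +/-50 for display)")
  .writeCsvWithHeader(mono_tab, file.path(outdir, "monosaccharide.csv"),
                      "monosaccharide contribution (percent of pool)")
  .writeRunConfig(cfg, outdir)
  .logMsg(logfile, "glycome stage done")
  invisible(list(per_glycan = per_glycan, top20 = top20,
                 category = category, heatmap = heat,
                 monosaccharide = mono_tab, percent = m))
}

#' Run the trace-element analysis stage
#'
#' Simulates (or accepts) an element panel, writes the 23-row MDL audit
#' table and the genotype statistics for the included elements, plus Mn
#' percent reductions and covariate regressions.
#'
#' @param config List: \code{seed}, \code{n_per_genotype},
#'   \code{effects}, \code{reference}.
#' @param outdir Output directory.
#' @param panel Optional pre-built
#'   \code{\linkS4class{ElementExperiment}}.
#' @return Invisible list (audit, stats, mn_reduction, regressions).
#' @export
runElements <- function(config = list(), outdir = tempfile("elements_"),
                        panel = NULL) {
  cfg <- .resolveConfig(config, list(
    seed = 1L, n_per_genotype = c(CC = 46L, CT = 46L, TT = 25L),
    effects = defaultElementEffects(), reference = "CC"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  .logMsg(logfile, "elements stage, seed=", cfg$seed)
  if (is.null(panel)) {
    cohort <- generateCohort(cfg$n_per_genotype, seed = cfg$seed)
    panel <- generateElementPanel(cohort, cfg$effects,
                                  seed = cfg$seed + 1L)
  }
  filt <- filterElements(panel)
  stats_tab <- elementGenotypeStats(panel, cfg$reference)
  mn <- stats_tab[stats_tab$feature == "Mn", ]
  mn_red <- data.frame(
    comparison = c("CC_vs_CT", "CC_vs_TT"),
    reduction_pct = c(percentReduction(mn$mean_CC, mn$mean_CT),
                      percentReduction(mn$mean_CC, mn$mean_TT)))
  regs <- lapply(c(age = "age", bmi = "bmi"), function(cv)
    covariateRegression(panel, "Mn", cv))
  reg_tab <- data.frame(covariate = names(regs),
                        slope = vapply(regs, `[[`, 1, "slope"),
                        p = vapply(regs, `[[`, 1, "p"))
  .writeCsvWithHeader(filt$audit, file.path(outdir, "element_audit.csv"),
                      "element mean vs MDL audit (ug/L)")
  .writeCsvWithHeader(stats_tab, file.path(outdir, "element_stats.csv"),
                      "included-element genotype comparison (ug/L)")
  .writeCsvWithHeader(mn_red, file.path(outdir, "mn_reduction.csv"),
                      "Mn percent reduction vs reference genotype")
  .writeCsvWithHeader(reg_tab, file.path(outdir, "mn_regressions.csv"),
                      "Mn covariate regressions")
  .writeRunConfig(cfg, outdir)
  .logMsg(logfile, "elements stage done")
  invisible(list(audit = filt$audit, stats = stats_tab,
                 mn_reduction = mn_red, regressions = reg_tab,
                 panel = panel))
}

#' Run the MRI analysis stage
#'
#' Simulates (or accepts) volume pairs, computes ratio maps, the ROI
#' summary table, per-ROI ANOVA + Dunnett tables (control = reference
#' genotype), a CC-vs-TT LDA classification on the ROI features, and
#' voxel-wise contrasts of each carrier genotype against the reference.
#'
#' @param config List: \code{seed}, \code{n_per_genotype},
#'   \code{effects}, \code{reference}, \code{voxelwise} (logical).
#' @param outdir Output directory.
#' @param pairs Optional pre-built list of
#'   \code{\linkS4class{VolumePair}}.
#' @return Invisible list (roi_table, dunnett, lda, contrasts).
#' @export
runMri <- function(config = list(), outdir = tempfile("mri_"),
                   pairs = NULL) {
  cfg <- .resolveConfig(config, list(
    seed = 1L, n_per_genotype = c(CC = 46L, CT = 44L, TT = 43L),
    effects = defaultMriEffects(), reference = "CC", voxelwise = FALSE))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  .logMsg(logfile, "mri stage, seed=", cfg$seed)
  geom <- toyLabelMap()
  if (is.null(pairs)) {
    cohort <- generateCohort(cfg$n_per_genotype, seed = cfg$seed)
    pairs <- generateVolumePairs(cohort, geom, cfg$effects,
                                 seed = cfg$seed + 1L)
  } else {
    cohort <- data.frame(sample_id = names(pairs),
                         genotype = sub("_.*", "", names(pairs)))
  }
  ratios <- lapply(pairs, function(p) ratioMap(p)$ratio)
  roi_tab <- roiSummary(ratios, geom$labels)
  genotype <- cohort$genotype[match(roi_tab$subject, cohort$sample_id)]
  roi_tab$genotype <- genotype
  rois <- names(geom$labels@dictionary)
  dunnett <- lapply(stats::setNames(rois, rois), function(roi)
    anovaDunnett(roi_tab[[roi]], genotype, control = cfg$reference,
                 seed = cfg$seed))
  dunn_tab <- do.call(rbind, lapply(rois, function(roi) {
    d <- dunnett[[roi]]
    cbind(roi = roi, F = d$anova$F, anova_p = d$anova$p, d$comparisons)
  }))
  keep <- genotype %in% c(cfg$reference, "TT")
  lda <- ldaClassify(as.matrix(roi_tab[keep, rois]),
                     genotype[keep], positive = "TT")
  contrasts <- NULL
  if (isTRUE(cfg$voxelwise)) {
    mask <- geom$mask
    contrasts <- lapply(setdiff(unique(genotype), cfg$reference),
                        function(g) voxelwiseContrast(
                          ratios[genotype == g],
                          ratios[genotype == cfg$reference], mask))
    names(contrasts) <- setdiff(unique(genotype), cfg$reference)
    for (g in names(contrasts))
      writeVolume(contrasts[[g]]$sig,
                  file.path(outdir, paste0("sig_", g, "_vs_",
                                           cfg$reference, ".nii.gz")))
  }
  .writeCsvWithHeader(roi_tab, file.path(outdir, "roi_means.csv"),
                      "per-subject ROI mean T2w/T1w ratio")
  .writeCsvWithHeader(dunn_tab, file.path(outdir, "roi_dunnett.csv"),
                      "per-ROI ANOVA and Dunnett vs control genotype")
  .writeCsvWithHeader(data.frame(roi = rois, weight = lda$weights),
                      file.path(outdir, "lda_weights.csv"),
                      "LDA discriminant weights (standardized features)")
  .writeCsvWithHeader(data.frame(auc = lda$auc),
                      file.path(outdir, "lda_auc.csv"),
                      "LDA CC-vs-TT ROC area under curve")
  .writeRunConfig(cfg, outdir)
  .logMsg(logfile, "mri stage done")
  invisible(list(roi_table = roi_tab, dunnett = dunn_tab, lda = lda,
                 contrasts = contrasts))
}

#' Simulate all assays for one cohort configuration
#'
#' Emits the CSV/NIfTI artifacts the analysis stages read: cohort
#' metadata, per-sample glycome profiles (tidy CSV), element
#' concentrations + QC runs, and (optionally) NIfTI volume pairs.
#'
#' @param config List: \code{seed}, \code{n_per_genotype},
#'   \code{with_mri} (default FALSE; volumes are large).
#' @param outdir Output directory.
#' @return Invisible list of the generated objects.
#' @export
simulateAll <- function(config = list(), outdir = tempfile("sim_")) {
  cfg <- .resolveConfig(config, list(
    seed = 1L, n_per_genotype = c(CC = 33L, CT = 31L, TT = 25L),
    with_mri = FALSE))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generateCohort(cfg$n_per_genotype, seed = cfg$seed)
  panel <- buildDefaultPanel()
  glyco <- generateGlycomeProfiles(cohort, panel, seed = cfg$seed + 1L)
  elements <- generateElementPanel(cohort, seed = cfg$seed + 2L)
  .writeCsvWithHeader(cohort, file.path(outdir, "cohort.csv"),
                      "synthetic cohort metadata (age years, BMI kg/m2)")
  gm <- glycomePercent(glyco)
  tidy <- data.frame(sample_id = rep(colnames(gm), each = nrow(gm)),
                     short_name = rep(rownames(gm), ncol(gm)),
                     percent = as.vector(gm))
  .writeCsvWithHeader(tidy, file.path(outdir, "glycome_profiles.csv"),
                      "relative abundance (percent of 57-species panel)")
  .writeCsvWithHeader(cbind(element = rownames(elementConc(elements)),
                            as.data.frame(elementConc(elements))),
                      file.path(outdir, "element_conc.csv"),
                      "element concentrations (ug/L)")
  .writeCsvWithHeader(cbind(element = rownames(metadata(elements)$qc_runs),
                            as.data.frame(metadata(elements)$qc_runs)),
                      file.path(outdir, "element_qc_runs.csv"),
                      "low-level QC replicate runs (ug/L)")
  pairs <- NULL
  if (isTRUE(cfg$with_mri)) {
    geom <- toyLabelMap()
    pairs <- generateVolumePairs(cohort, geom, seed = cfg$seed + 3L)
    dir.create(file.path(outdir, "mri"), showWarnings = FALSE)
    for (nm in names(pairs)) {
      writeVolume(pairs[[nm]]@t1w,
                  file.path(outdir, "mri", paste0(nm, "_T1w.nii.gz")))
      writeVolume(pairs[[nm]]@t2w,
                  file.path(outdir, "mri", paste0(nm, "_T2w.nii.gz")))
    }
    writeVolume(geom$labels@labels, file.path(outdir, "mri", "labels.nii.gz"))
  }
  .writeRunConfig(cfg, outdir)
  invisible(list(cohort = cohort, glycome = glyco, elements = elements,
                 pairs = pairs))
}
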