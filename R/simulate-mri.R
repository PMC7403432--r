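## Synthetic T1w/T2w volume generation on a schematic 64^3 grid: a
## spherical "brain" of white-matter-like background containing three
## ellipsoidal deep-gray ROIs (GPi, SN, LPut).  Genotype effects are
## multiplicative T2w offsets inside designated ROIs; a per-subject global
## intensity scale multiplies BOTH images, exercising the ratio's
## invariance to coil-loading-style scaling.

#' Packaged schematic ROI label map
#'
#' A 64^3 label volume with a spherical brain mask and ellipsoidal blobs
#' for the globus pallidus interna (GPi), substantia nigra (SN) and
#' lateral putamen (LPut) on a white-matter background.  Geometry is
#' schematic, not anatomical.
#'
#' @param dim Cubic grid size (default 64).
#' @return List with \code{labels} (a \code{\linkS4class{RoiLabelMap}})
#'   and \code{mask} (logical brain mask).
#' @export
toyLabelMap <- function(dim = 64L) {
  ax <- seq_len(dim) - (dim + 1) / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  r <- dim / 2.2
  mask <- array((g$x^2 + g$y^2 + g$z^2) <= r^2, rep(dim, 3L))
  ellipsoid <- function(cx, cy, cz, a, b, c) {
    array(((g$x - cx)^2 / a^2 + (g$y - cy)^2 / b^2 +
             (g$z - cz)^2 / c^2) <= 1, rep(dim, 3L))
  }
  labels <- array(0L, rep(dim, 3L))
  dict <- c(GPi = 1L, SN = 2L, LPut = 3L, WM = 4L)
  gpi <- ellipsoid(-8, 4, 2, 4.5, 4, 4) & mask
  sn <- ellipsoid(0, -10, -6, 4, 3.5, 3.5) & mask
  lput <- ellipsoid(10, 6, 2, 5, 4.5, 4.5) & mask
  labels[gpi] <- dict[["GPi"]]
  labels[sn] <- dict[["SN"]]
  labels[lput] <- dict[["LPut"]]
  ## white-matter reference region: a shell away from the deep-gray blobs
  wm <- mask & labels == 0L & (g$x^2 + g$y^2 + g$z^2) >= (0.55 * r)^2 &
    (g$x^2 + g$y^2 + g$z^2) <= (0.8 * r)^2
  labels[wm] <- dict[["WM"]]
  list(labels = new("RoiLabelMap", labels = labels, dictionary = dict),
       mask = mask)
}

#' Default MRI effect configuration
#'
#' Baseline T2w/T1w ratios per tissue, genotype-specific multiplicative
#' ratio offsets per ROI (TT: decrease in GPi and SN, increase in LPut
#' and diffusely in white matter; CT: same directions, smaller), voxel
#' noise, per-subject ROI-level variability and the per-subject global
#' intensity scale range.  ROI-level between-subject SDs are calibrated
#' so the configured CC-vs-TT contrasts are standardized effects of about
#' 0.9, reproducing the reference significance pattern at the cohort's
#' group sizes.
#'
#' @return Configuration list.
#' @export
defaultMriEffects <- function() {
  list(
    t1w_base = c(background = 0, WM = 1000, GPi = 1100, SN = 1080,
                 LPut = 1050),
    ratio_base = c(WM = 0.38, GPi = 0.279, SN = 0.279, LPut = 0.399,
                   other = 0.40),
    roi_offsets = list(  # additive ratio offsets by genotype and ROI
      CC = c(GPi = 0, SN = 0, LPut = 0, WM = 0),
      CT = c(GPi = -0.006, SN = -0.004, LPut = 0.007, WM = 0.004),
      TT = c(GPi = -0.026, SN = -0.014, LPut = 0.024, WM = 0.012)),
    subject_sd = c(GPi = 0.029, SN = 0.016, LPut = 0.027, WM = 0.014),
    voxel_noise_sd = 0.03,       # on the ratio scale, via T2w noise
    global_scale_range = c(0.8, 1.2))
}

#' Generate synthetic T1w/T2w volume pairs for a cohort
#'
#' For each subject: tissue-dependent base T1w intensities and T2w =
#' T1w x (base ratio + genotype ROI offset + subject ROI effect + voxel
#' noise), then a per-subject global scale multiplying both images.
#'
#' @param cohort Cohort table from \code{\link{generateCohort}}.
#' @param geometry Label map/mask from \code{\link{toyLabelMap}}.
#' @param effects Configuration (default \code{\link{defaultMriEffects}});
#'   set \code{roi_offsets = NULL} for a null configuration.
#' @param seed RNG seed.
#' @return List of \code{\linkS4class{VolumePair}} objects (one per
#'   subject) with attribute \code{ground_truth}.
#' @export
generateVolumePairs <- function(cohort, geometry = toyLabelMap(),
                                effects = defaultMriEffects(), seed = 1L) {
  effects <- utils::modifyList(defaultMriEffects(), effects,
                               keep.null = TRUE)
  labels <- geometry$labels@labels
  dict <- geometry$labels@dictionary
  mask <- geometry$mask
  rois <- names(effects$subject_sd)
  miss <- setdiff(rois, names(dict))
  if (length(miss))
    stop("label map missing configured ROI(s): ",
         paste(miss, collapse = ", "))
  t1w_base <- array(0, dim(labels))
  t1w_base[mask] <- effects$t1w_base[["WM"]]
  ratio_base <- array(0, dim(labels))
  ratio_base[mask] <- effects$ratio_base[["other"]]
  for (nm in names(dict)) {
    vox <- labels == dict[[nm]]
    if (nm %in% names(effects$t1w_base)) t1w_base[vox] <- effects$t1w_base[[nm]]
    if (nm %in% names(effects$ratio_base)) ratio_base[vox] <- effects$ratio_base[[nm]]
  }
  seeds <- .subSeeds(seed, nrow(cohort))
  pairs <- lapply(seq_len(nrow(cohort)), function(i) {
    g <- cohort$genotype[i]
    withSeed(seeds[i], {
      ratio <- ratio_base
      if (!is.null(effects$roi_offsets)) {
        off <- effects$roi_offsets[[g]]
        for (nm in names(off))
          ratio[labels == dict[[nm]]] <- ratio[labels == dict[[nm]]] + off[[nm]]
      }
      for (nm in rois) {
        vox <- labels == dict[[nm]]
        ratio[vox] <- ratio[vox] + stats::rnorm(1, 0, effects$subject_sd[[nm]])
      }
      nvox <- sum(mask)
      if (effects$voxel_noise_sd > 0)
        ratio[mask] <- ratio[mask] +
          stats::rnorm(nvox, 0, effects$voxel_noise_sd)
      ratio[mask] <- pmax(ratio[mask], 0.01)
      scale <- stats::runif(1, effects$global_scale_range[1],
                            effects$global_scale_range[2])
      t2w <- t1w_base * ratio
      new("VolumePair", t1w = t1w_base * scale, t2w = t2w * scale,
          mask = mask, subjectId = cohort$sample_id[i])
    })
  })
  names(pairs) <- cohort$sample_id
  attr(pairs, "ground_truth") <- list(effects = effects)
  pairs
}
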