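## T2w/T1w ratio neuroimaging.  Volumes are plain 3-D arrays (read/written
## as NIfTI via RNifti); subjects are assumed co-registered, so voxel-wise
## statistics operate directly on stacked in-mask vectors.

#' VolumePair: one subject's co-registered T1w/T2w volumes
#'
#' @slot t1w,t2w 3-D intensity arrays of identical dimension.
#' @slot mask Logical 3-D brain mask.
#' @slot subjectId Subject identifier.
#' @export
setClass("VolumePair",
         representation(t1w = "array", t2w = "array", mask = "array",
                        subjectId = "character"))

setValidity("VolumePair", function(object) {
  if (!identical(dim(object@t1w), dim(object@t2w)) ||
      !identical(dim(object@t1w), dim(object@mask)))
    return("t1w, t2w and mask must share the same dimensions")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (any(object@t1w < 0) || any(object@t2w < 0))
    return("intensities must be non-negative")
  TRUE
})

#' RoiLabelMap: integer ROI labels on the volume grid
#'
#' @slot labels Integer 3-D array (0 = unlabeled).
#' @slot dictionary Named integer vector mapping ROI name to label id.
#' @export
setClass("RoiLabelMap",
         representation(labels = "array", dictionary = "integer"))

setValidity("RoiLabelMap", function(object) {
  if (anyDuplicated(object@dictionary) || anyDuplicated(names(object@dictionary)))
    return("label ids and names must be unique")
  if (!all(setdiff(unique(as.vector(object@labels)), 0L) %in%
           object@dictionary))
    return("label volume contains ids absent from the dictionary")
  TRUE
})

#' Compute a subject's T2w/T1w ratio volume
#'
#' Voxel-wise t2w/t1w inside the mask.  The ratio cancels any subject-level
#' multiplicative intensity scaling (coil loading, body size) applied to
#' both images.  Voxels with t1w = 0 are undefined and dropped from the
#' mask.
#'
#' @param pair A \code{\linkS4class{VolumePair}}.
#' @return List with \code{ratio} (3-D array, NA outside mask) and
#'   \code{mask} (possibly shrunk).
#' @export
ratioMap <- function(pair) {
  validObject(pair)
  mask <- pair@mask & pair@t1w > 0
  if (!any(mask)) stop("empty mask after excluding t1w = 0 voxels")
  ratio <- array(NA_real_, dim(pair@t1w))
  ratio[mask] <- pair@t2w[mask] / pair@t1w[mask]
  list(ratio = ratio, mask = mask)
}

## stack a list of ratio volumes into an (in-mask voxel) x subject matrix
.stackRatios <- function(ratios, mask) {
  vapply(ratios, function(r) r[mask], numeric(sum(mask)))
}

## vectorized two-sided Welch t over rows of two matrices
.rowWelch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Voxel-wise two-group contrast with BH-FDR control
#'
#' Welch two-sample t at every in-mask voxel, Benjamini-Hochberg adjusted
#' across in-mask voxels only, and a signed significance mask at
#' q < \code{alpha} (+1 where group A exceeds group B).
#'
#' @param group_a,group_b Lists of ratio volumes (3-D arrays) per subject.
#' @param mask Logical 3-D analysis mask.
#' @param alpha FDR level (default 0.05).
#' @return List with 3-D \code{t}, \code{p}, \code{q} maps (NA outside
#'   mask) and integer \code{sig} map in {-1, 0, +1}.
#' @export
voxelwiseContrast <- function(group_a, group_b, mask, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 subjects")
  a <- .stackRatios(group_a, mask)
  b <- .stackRatios(group_b, mask)
  w <- .rowWelch(a, b)
  q <- stats::p.adjust(w$p, method = "BH")
  shape <- dim(mask)
  mk <- function(v) { out <- array(NA_real_, shape); out[mask] <- v; out }
  sig <- array(0L, shape)
  sig[mask] <- ifelse(q < alpha, ifelse(w$t > 0, 1L, -1L), 0L)
  list(t = mk(w$t), p = mk(w$p), q = mk(q), sig = sig)
}

#' Per-subject ROI mean table
#'
#' Mean ratio of each subject within each ROI of a label map (the ROI is
#' drawn once and propagated to every subject's ratio image).
#'
#' @param ratios Named list of ratio volumes (3-D arrays, NA allowed
#'   outside mask).
#' @param labels A \code{\linkS4class{RoiLabelMap}}.
#' @return \code{data.frame}: subject x ROI means.
#' @export
roiSummary <- function(ratios, labels) {
  dict <- labels@dictionary
  idx <- lapply(dict, function(id) which(labels@labels == id))
  empty <- names(dict)[vapply(idx, length, 1L) == 0L]
  if (length(empty))
    stop("empty ROI label(s): ", paste(empty, collapse = ", "))
  out <- vapply(ratios, function(r)
    vapply(idx, function(i) mean(r[i], na.rm = TRUE), numeric(1)),
    numeric(length(dict)))
  out <- as.data.frame(t(matrix(out, nrow = length(dict),
                                dimnames = list(names(dict),
                                                names(ratios)))))
  cbind(subject = rownames(out), out, row.names = NULL)
}

#' Read/write helpers for NIfTI volumes
#'
#' Thin wrappers over \pkg{RNifti} keeping the package's array-based
#' volume convention.
#'
#' @param path NIfTI file path.
#' @return \code{readVolume}: a numeric 3-D array.
#' @export
readVolume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' @rdname readVolume
#' @param vol 3-D numeric array.
#' @export
writeVolume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
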