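## Synthetic MALDI-TOF spectra and panel-based quantification.
##
## A spectrum is a strictly increasing m/z grid over the acquisition window
## with non-negative intensities.  Species are modelled as Gaussian peaks at
## their theoretical permethylated [M+Na]+ m/z; isotope envelopes are not
## simulated (the monoisotopic centroid stands for the species).

#' MassSpectrum: one sample's m/z-intensity trace
#'
#' @slot mz Strictly increasing m/z grid (Da).
#' @slot intensity Non-negative intensities (arbitrary units).
#' @slot sampleId Sample identifier.
#' @export
setClass("MassSpectrum",
         representation(mz = "numeric", intensity = "numeric",
                        sampleId = "character"))

setValidity("MassSpectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have equal length")
  if (length(object@mz) && any(diff(object@mz) <= 0))
    return("mz grid must be strictly increasing")
  if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
    return("intensities must be finite and non-negative")
  TRUE
})

setMethod("show", "MassSpectrum", function(object) {
  cat("MassSpectrum '", object@sampleId, "': ", length(object@mz),
      " points, m/z [", round(min(object@mz), 1), ", ",
      round(max(object@mz), 1), "]\n", sep = "")
})

#' Default spectrum synthesis parameters
#'
#' \code{peak_sigma} (Da) is the Gaussian peak width; \code{grid_step} (Da)
#' the sampling step; \code{baseline} and \code{noise_sd} are in intensity
#' units relative to \code{total_signal}, the summed area of all peaks.
#' @return Named list of parameters.
#' @export
defaultSpectrumParams <- function() {
  list(peak_sigma = 0.5, baseline = 20, noise_sd = 5, grid_step = 0.1,
       total_signal = 1e6, mz_range = c(1500, 5000))
}

#' Synthesize a MALDI-TOF spectrum from a glycome profile
#'
#' Places a Gaussian peak at each panel species' theoretical m/z with area
#' proportional to its percent abundance, adds a flat baseline and seeded
#' Gaussian noise.  Deterministic given \code{seed}.
#'
#' @param profile Named percent-abundance vector over the panel species
#'   (summing to 100).
#' @param panel A \code{\linkS4class{GlycanPanel}}.
#' @param params Parameter list as \code{\link{defaultSpectrumParams}};
#'   partial lists are merged over the defaults.
#' @param seed Integer RNG seed (only used when \code{noise_sd > 0}).
#' @param sampleId Sample identifier stored in the spectrum.
#' @return A \code{\linkS4class{MassSpectrum}}.
#' @examples
#' panel <- buildDefaultPanel()
#' s <- synthesizeSpectrum(panelBaseline(panel), panel, seed = 1)
#' @export
synthesizeSpectrum <- function(profile, panel, params = list(), seed = 1L,
                               sampleId = "sample") {
  p <- utils::modifyList(defaultSpectrumParams(), params)
  bad <- setdiff(names(profile), panelNames(panel))
  if (length(bad))
    stop("profile keys absent from panel: ", paste(bad, collapse = ", "))
  mzs <- panelMz(panel)[names(profile)]
  grid <- seq(p$mz_range[1], p$mz_range[2], by = p$grid_step)
  intensity <- rep(p$baseline, length(grid))
  areas <- p$total_signal * profile / 100
  height <- areas / (p$peak_sigma * sqrt(2 * pi))
  for (i in seq_along(mzs)) {
    if (areas[i] <= 0) next
    win <- which(abs(grid - mzs[i]) <= 6 * p$peak_sigma)
    intensity[win] <- intensity[win] +
      height[i] * exp(-((grid[win] - mzs[i])^2) / (2 * p$peak_sigma^2))
  }
  if (p$noise_sd > 0)
    intensity <- intensity + withSeed(seed, stats::rnorm(length(grid),
                                                         sd = p$noise_sd))
  intensity[intensity < 0] <- 0
  new("MassSpectrum", mz = grid, intensity = intensity,
      sampleId = as.character(sampleId))
}

#' Pick peaks from a spectrum
#'
#' Detects local maxima exceeding (baseline estimate) + \code{min_snr} x
#' (noise estimate), where the baseline is the median intensity and the
#' noise its median absolute deviation.  Each apex is refined by a
#' three-point Gaussian (parabolic-in-log) interpolation, which recovers
#' the centroid and apex height of an exactly Gaussian peak to machine
#' precision; the reported height is the interpolated apex above baseline.
#'
#' @param spectrum A \code{\linkS4class{MassSpectrum}}.
#' @param min_snr Signal-to-noise threshold (default 5).
#' @return \code{data.frame} with columns \code{mz} (centroid, Da) and
#'   \code{height} (> 0), sorted by m/z.
#' @export
pickPeaks <- function(spectrum, min_snr = 5) {
  y <- spectrum@intensity
  x <- spectrum@mz
  if (!length(y)) stop("empty spectrum")
  baseline <- stats::median(y)
  noise <- stats::mad(y)
  thr <- baseline + min_snr * max(noise, .Machine$double.eps)
  n <- length(y)
  if (n < 3L)
    return(data.frame(mz = numeric(0), height = numeric(0)))
  core <- 2:(n - 1L)
  isMax <- y[core] > y[core - 1L] & y[core] >= y[core + 1L] & y[core] > thr
  idx <- core[isMax]
  if (!length(idx))
    return(data.frame(mz = numeric(0), height = numeric(0)))
  cent <- numeric(length(idx)); ht <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    y0 <- pmax(y[(i - 1L):(i + 1L)] - baseline, .Machine$double.eps)
    if (y0[1] > .Machine$double.eps && y0[3] > .Machine$double.eps &&
        2 * log(y0[2]) - log(y0[1]) - log(y0[3]) > 0) {
      l <- log(y0)
      denom <- l[1] - 2 * l[2] + l[3]
      delta <- 0.5 * (l[1] - l[3]) / denom
      cent[k] <- x[i] + delta * (x[i + 1L] - x[i])
      ht[k] <- exp(l[2] - 0.25 * (l[1] - l[3]) * delta)
    } else {
      w <- y0 / sum(y0)
      cent[k] <- sum(w * x[(i - 1L):(i + 1L)])
      ht[k] <- y0[2]
    }
  }
  data.frame(mz = cent, height = ht)[order(cent), , drop = FALSE]
}

#' Annotate picked peaks against a panel
#'
#' Assigns each peak to the nearest panel species within \code{tolerance}
#' Da; ties between two equidistant species go to the lower-m/z species.
#' Peaks matching no species are returned in the \code{unassigned} side
#' channel for QC.  When several peaks match one species their heights sum;
#' species with no matching peak get height 0.
#'
#' @param peaks Peak \code{data.frame} from \code{\link{pickPeaks}}.
#' @param panel A \code{\linkS4class{GlycanPanel}}.
#' @param tolerance Match half-width in Da
#'   (default \code{\link{defaultAnnotationTolerance}}).
#' @return List with \code{heights} (named vector over all panel species)
#'   and \code{unassigned} (data.frame of unmatched peaks).
#' @export
annotatePeaks <- function(peaks, panel,
                          tolerance = defaultAnnotationTolerance()) {
  if (tolerance <= 0) stop("tolerance must be positive")
  mzs <- panelMz(panel)
  heights <- stats::setNames(rep(0, length(mzs)), names(mzs))
  unassigned <- logical(nrow(peaks))
  ord <- order(mzs)  # lower-m/z species wins exact ties
  for (j in seq_len(nrow(peaks))) {
    d <- abs(mzs[ord] - peaks$mz[j])
    best <- which.min(d)  # first minimum = lower m/z on ties
    if (d[best] <= tolerance)
      heights[ord[best]] <- heights[ord[best]] + peaks$height[j]
    else unassigned[j] <- TRUE
  }
  list(heights = heights, unassigned = peaks[unassigned, , drop = FALSE])
}

#' Normalize annotated heights to percent abundance
#'
#' Relative abundance of each species is its signal divided by the summed
#' signal of all panel species in the spectrum, times 100.
#'
#' @param heights Named non-negative height vector over the panel species.
#' @return Named percent vector summing to 100.
#' @export
normalizeHeights <- function(heights) {
  total <- sum(heights)
  if (!is.finite(total) || total <= 0)
    stop("all heights are zero: profile is uninterpretable (low signal)")
  100 * heights / total
}

#' Quantify a spectrum against a panel
#'
#' Convenience wrapper chaining \code{\link{pickPeaks}},
#' \code{\link{annotatePeaks}} and \code{\link{normalizeHeights}}.
#'
#' @inheritParams pickPeaks
#' @inheritParams annotatePeaks
#' @return Named percent-abundance vector over the panel species.
#' @export
quantifySpectrum <- function(spectrum, panel, min_snr = 5,
                             tolerance = defaultAnnotationTolerance()) {
  ann <- annotatePeaks(pickPeaks(spectrum, min_snr), panel, tolerance)
  normalizeHeights(ann$heights)
}

#' Read a spectrum from two-column text
#'
#' Accepts whitespace- or comma-separated m/z, intensity text with optional
#' \code{#} comment lines.
#'
#' @param path Input file.
#' @param sampleId Sample identifier (default: file base name).
#' @return A \code{\linkS4class{MassSpectrum}}.
#' @export
readSpectrum <- function(path, sampleId = sub("\\.[^.]*$", "",
                                              basename(path))) {
  first <- readLines(path, n = 50L)
  sep <- if (any(grepl(",", first[!startsWith(first, "#")]))) "," else ""
  d <- utils::read.table(path, sep = sep, comment.char = "#",
                         col.names = c("mz", "intensity"))
  new("MassSpectrum", mz = d$mz, intensity = d$intensity,
      sampleId = sampleId)
}

#' Write a spectrum as two-column text
#'
#' @param spectrum A \code{\linkS4class{MassSpectrum}}.
#' @param path Output file.
#' @export
writeSpectrum <- function(spectrum, path) {
  writeLines(c(sprintf("# spectrum %s (m/z intensity)", spectrum@sampleId),
               sprintf("%.6f %.6f", spectrum@mz, spectrum@intensity)),
             path)
  invisible(path)
}
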