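## ICP-MS trace-element panel: MDL computation from replicate QC runs,
## mean-above-MDL inclusion filtering, genotype statistics and covariate
## regressions.

#' Canonical 23-element serum panel symbols
#' @return Character vector of element symbols.
#' @export
elementSymbols <- function() {
  c("As", "Ba", "Be", "Cd", "Co", "Cr", "Cs", "Cu", "Hg", "Mn", "Mo",
    "Ni", "Pb", "Pt", "Sb", "Se", "Sn", "Te", "Tl", "U", "V", "W", "Zn")
}

#' ElementExperiment: per-sample trace-element concentrations
#'
#' A \code{SummarizedExperiment} whose assay \code{conc} holds element x
#' sample concentrations (ug/L), with per-element MDLs in \code{rowData}
#' and cohort metadata in \code{colData}.  The QC replicate table used to
#' derive the MDLs is kept in \code{metadata(x)$qc_runs}.
#'
#' @export
setClass("ElementExperiment", contains = "SummarizedExperiment")

setValidity("ElementExperiment", function(object) {
  if (!"conc" %in% SummarizedExperiment::assayNames(object))
    return("assay 'conc' is required")
  if (any(assay(object, "conc") < 0))
    return("concentrations must be non-negative")
  if (nrow(object) != 23L)
    return("the serum panel measures exactly 23 elements")
  if (!"mdl" %in% colnames(rowData(object)))
    return("rowData must carry per-element 'mdl'")
  if (any(rowData(object)$mdl <= 0))
    return("MDLs must be positive")
  TRUE
})

#' Construct an ElementExperiment
#'
#' @param conc Element x sample concentration matrix (ug/L), rownames the
#'   element symbols.
#' @param mdl Named per-element MDL vector (ug/L).
#' @param colData Sample metadata.
#' @param qc_runs Optional element x replicate QC matrix.
#' @return An \code{\linkS4class{ElementExperiment}}.
#' @export
ElementExperiment <- function(conc, mdl, colData = NULL, qc_runs = NULL) {
  conc <- conc[elementSymbols(), , drop = FALSE]
  if (is.null(colData)) colData <- DataFrame(row.names = colnames(conc))
  se <- SummarizedExperiment(
    assays = list(conc = conc),
    rowData = DataFrame(mdl = unname(mdl[rownames(conc)]),
                        row.names = rownames(conc)),
    colData = DataFrame(colData))
  out <- new("ElementExperiment", se)
  if (!is.null(qc_runs)) metadata(out)$qc_runs <- qc_runs
  out
}

#' Element concentrations
#' @param x An \code{ElementExperiment}.
#' @export
elementConc <- function(x) assay(x, "conc")

#' Per-element MDLs
#' @param x An \code{ElementExperiment}.
#' @export
elementMdl <- function(x) stats::setNames(rowData(x)$mdl, rownames(x))

#' Compute method detection limits from replicate QC runs
#'
#' The MDL of an element is the one-sided 99 percent Student-t quantile at
#' n - 1 degrees of freedom times the standard deviation of its replicate
#' low-level QC measurements (the EPA-style convention; at the standard
#' n = 7 runs the multiplier is t[0.99,6] = 3.143).  The multiplier is
#' computed from the t distribution, not hard-coded.  A plain
#' \code{method = "3sd"} alternative is provided.
#'
#' @param qc Element x replicate matrix of QC measurements (ug/L), one row
#'   per element, or a numeric vector for a single element.
#' @param method \code{"t99"} (default) or \code{"3sd"}.
#' @return Named per-element MDL vector (ug/L).
#' @examples
#' computeMdl(matrix(rnorm(7, 1, 0.01), 1, dimnames = list("Mn", NULL)))
#' @export
computeMdl <- function(qc, method = c("t99", "3sd")) {
  method <- match.arg(method)
  if (!is.matrix(qc)) qc <- matrix(qc, nrow = 1L)
  n <- ncol(qc)
  if (n < 2L) stop("at least 2 QC replicates are required")
  s <- apply(qc, 1L, stats::sd)
  mult <- if (method == "t99") stats::qt(0.99, df = n - 1L) else 3
  stats::setNames(mult * s, rownames(qc))
}

#' Mean-above-MDL element inclusion filter
#'
#' An element is included iff its mean concentration across all samples is
#' strictly greater than its MDL; elements at or below are excluded
#' (measurements below the MDL are not distinguishable from background).
#'
#' @param panel An \code{\linkS4class{ElementExperiment}}.
#' @return List with \code{included} and \code{excluded} element vectors
#'   and an \code{audit} data.frame (element, mean, mdl, included).
#' @export
filterElements <- function(panel) {
  mu <- rowMeans(elementConc(panel))
  mdl <- elementMdl(panel)
  keep <- mu > mdl
  audit <- data.frame(element = names(mu), mean = as.numeric(mu),
                      mdl = as.numeric(mdl), included = as.logical(keep))
  list(included = names(mu)[keep], excluded = names(mu)[!keep],
       audit = audit)
}

#' Genotype statistics for the included elements
#'
#' Runs \code{\link{groupCompare}} (one-way ANOVA, df = groups - 1, then
#' pairwise Welch t-tests) on the elements retained by
#' \code{\link{filterElements}}.  Values below the MDL are retained as
#' measured by default; \code{censor = TRUE} replaces them with MDL/2.
#'
#' @param panel An \code{\linkS4class{ElementExperiment}} with a
#'   \code{genotype} column in its \code{colData}.
#' @param reference Reference genotype (default \code{"CC"}).
#' @param censor Substitute MDL/2 for sub-MDL measurements
#'   (default FALSE).
#' @return A \code{groupCompare} table over the included elements.
#' @export
elementGenotypeStats <- function(panel, reference = "CC", censor = FALSE) {
  keep <- filterElements(panel)$included
  m <- elementConc(panel)[keep, , drop = FALSE]
  if (censor) {
    mdl <- elementMdl(panel)[keep]
    m <- t(vapply(seq_len(nrow(m)), function(i)
      ifelse(m[i, ] < mdl[i], mdl[i] / 2, m[i, ]), numeric(ncol(m))))
    rownames(m) <- keep
  }
  groupCompare(m, colData(panel)$genotype, reference)
}

#' Percent reduction of a group mean versus a reference mean
#'
#' @param mean_ref Reference group mean (> 0).
#' @param mean_alt Alternative group mean.
#' @param digits Rounding for the reported value; \code{0} (default)
#'   reports integer percent as in study summaries, \code{NA} returns the
#'   unrounded value.
#' @return Percent reduction, 100 x (ref - alt)/ref.
#' @examples
#' percentReduction(0.814, 0.732)  # 10
#' percentReduction(0.814, 0.669)  # 18
#' @export
percentReduction <- function(mean_ref, mean_alt, digits = 0) {
  if (mean_ref <= 0) stop("reference mean must be positive")
  x <- 100 * (mean_ref - mean_alt) / mean_ref
  if (is.na(digits)) x else round(x, digits)
}

#' Simple linear regression of an element on a covariate
#'
#' Ordinary least squares with a two-sided test on the slope, used for
#' element-vs-age and element-vs-BMI checks.
#'
#' @param panel An \code{\linkS4class{ElementExperiment}} whose
#'   \code{colData} carries the covariate.
#' @param element Element symbol.
#' @param covariate Covariate column name (e.g. \code{"age"},
#'   \code{"bmi"}).
#' @return List with \code{slope}, \code{intercept}, \code{p},
#'   \code{r_squared} and the fitted \code{lm} object.
#' @export
covariateRegression <- function(panel, element, covariate) {
  y <- elementConc(panel)[element, ]
  x <- colData(panel)[[covariate]]
  if (is.null(x)) stop("covariate not found: ", covariate)
  if (length(y) < 3L) stop("at least 3 samples are required")
  if (stats::sd(x) == 0) stop("constant covariate: ", covariate)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p = sm$coefficients[2L, 4L], r_squared = sm$r.squared, fit = fit)
}
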