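#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' GlycomeExperiment: per-sample relative N-glycan abundances
#'
#' A \code{SummarizedExperiment} whose single assay \code{percent} holds
#' species x samples relative abundances (each column sums to 100), with
#' the panel species table as \code{rowData} and cohort metadata
#' (genotype, sex, age, BMI) as \code{colData}.  The generating
#' \code{\linkS4class{GlycanPanel}} is kept in \code{metadata(x)$panel}.
#'
#' @export
setClass("GlycomeExperiment", contains = "SummarizedExperiment")

setValidity("GlycomeExperiment", function(object) {
  if (!"percent" %in% SummarizedExperiment::assayNames(object))
    return("assay 'percent' is required")
  m <- assay(object, "percent")
  if (any(m < 0)) return("abundances must be non-negative")
  if (ncol(m) && any(abs(colSums(m) - 100) > 1e-6))
    return("each sample's abundances must sum to 100")
  TRUE
})

#' Construct a GlycomeExperiment
#'
#' @param percent Species x samples percent matrix (columns sum to 100);
#'   rownames must match the panel's short names.
#' @param panel A \code{\linkS4class{GlycanPanel}}.
#' @param colData Sample metadata \code{data.frame}/\code{DataFrame}
#'   (e.g. genotype, sex, age, BMI).
#' @return A \code{\linkS4class{GlycomeExperiment}}.
#' @export
GlycomeExperiment <- function(percent, panel, colData = NULL) {
  if (!identical(sort(rownames(percent)), sort(panelNames(panel))))
    stop("rownames of the percent matrix must match the panel species")
  percent <- percent[panelNames(panel), , drop = FALSE]
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(percent))
  se <- SummarizedExperiment(assays = list(percent = percent),
                             rowData = DataFrame(panelSpecies(panel)),
                             colData = DataFrame(colData))
  out <- new("GlycomeExperiment", se)
  metadata(out)$panel <- panel
  out
}

#' Percent-abundance assay of a GlycomeExperiment
#' @param x A \code{GlycomeExperiment}.
#' @return Species x samples matrix.
#' @export
glycomePercent <- function(x) assay(x, "percent")

#' Panel attached to a GlycomeExperiment
#' @param x A \code{GlycomeExperiment}.
#' @export
glycomePanel <- function(x) metadata(x)$panel
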