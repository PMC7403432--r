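#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators are
#' reproducible without disturbing the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  if (!is.null(globalenv()$.Random.seed)) {
    old <- globalenv()$.Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Significance stars at the conventional thresholds
#'
#' @param p Numeric p-value vector.
#' @return Character vector: \code{***} (<0.001), \code{**} (<0.01),
#'   \code{*} (<0.05), else \code{""}.
#' @export
starsFor <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

## derive a stream of sub-seeds from one master seed (kept below 2^31)
.subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## write a csv with a leading comment header naming units/provenance
.writeCsvWithHeader <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header, " | glycomn ",
                    as.character(utils::packageVersion("glycomn"))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.readCsvWithHeader <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
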