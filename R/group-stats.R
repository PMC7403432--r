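## Genotype group comparisons shared by the glycome and trace-element
## stages: one-way ANOVA (classic, equal-variance, df = groups - 1)
## followed by pairwise Welch (unequal-variance) two-sided t-tests, with
## per-group means, SEMs, relative change against a reference group,
## significance stars and a BH-FDR column added for transparency.

#' Compare features between groups
#'
#' For each feature (row of \code{values}): one-way ANOVA across groups,
#' then all pairwise Welch t-tests; per-group mean and SEM; relative
#' change of each group versus the \code{reference}; stars at the
#' 0.05/0.01/0.001 thresholds on the reference contrasts; BH-adjusted
#' ANOVA p across features.
#'
#' @param values Feature x samples numeric matrix (or a vector for one
#'   feature).
#' @param groups Factor/character group label per sample.
#' @param reference Reference group label (default: first level).
#' @return \code{data.frame}, one row per feature: per-group
#'   \code{mean_*}/\code{sem_*}/\code{relchange_*}, \code{anova_F},
#'   \code{anova_df}, \code{anova_p}, pairwise \code{p_<a>_vs_<b>}
#'   columns, \code{stars_*} for non-reference groups, and \code{fdr_q}.
#' @examples
#' m <- rbind(f1 = c(rnorm(5), rnorm(5, 2)))
#' groupCompare(m, rep(c("CC", "TT"), each = 5), reference = "CC")
#' @export
groupCompare <- function(values, groups, reference = NULL) {
  if (!is.matrix(values))
    values <- matrix(values, nrow = 1L,
                     dimnames = list("feature", names(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature", seq_len(nrow(values)))
  groups <- as.factor(as.character(groups))
  lev <- levels(groups)
  if (is.null(reference)) reference <- lev[1L]
  if (!reference %in% lev) stop("reference group absent: ", reference)
  lev <- c(reference, setdiff(lev, reference))
  groups <- factor(groups, levels = lev)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 samples")
  if (ncol(values) != length(groups))
    stop("length of groups must match the number of samples")
  pairs <- utils::combn(lev, 2L)
  res <- lapply(seq_len(nrow(values)), function(i) {
    y <- values[i, ]
    mu <- tapply(y, groups, mean)
    sem <- tapply(y, groups, function(v) stats::sd(v) / sqrt(length(v)))
    if (stats::var(y) == 0) {
      aF <- 0; ap <- 1
    } else {
      a <- stats::oneway.test(y ~ groups, var.equal = TRUE)
      aF <- unname(a$statistic); ap <- a$p.value
    }
    pw <- apply(pairs, 2L, function(pr) {
      ya <- y[groups == pr[1]]; yb <- y[groups == pr[2]]
      if (stats::sd(ya) == 0 && stats::sd(yb) == 0)
        return(if (mean(ya) == mean(yb)) 1 else 0)
      stats::t.test(ya, yb)$p.value
    })
    rel <- if (mu[[reference]] != 0)
      100 * (mu - mu[[reference]]) / mu[[reference]]
    else rep(NA_real_, length(mu))
    row <- c(stats::setNames(as.numeric(mu), paste0("mean_", lev)),
             stats::setNames(as.numeric(sem), paste0("sem_", lev)),
             stats::setNames(as.numeric(rel), paste0("relchange_", lev)),
             anova_F = aF, anova_df = length(lev) - 1, anova_p = ap,
             stats::setNames(pw, apply(pairs, 2L, function(pr)
               paste0("p_", pr[1], "_vs_", pr[2]))))
    row
  })
  out <- as.data.frame(do.call(rbind, res))
  rownames(out) <- rownames(values)
  out <- cbind(feature = rownames(values), out)
  for (g in setdiff(lev, reference))
    out[[paste0("stars_", g)]] <-
      starsFor(out[[paste0("p_", reference, "_vs_", g)]])
  out$fdr_q <- stats::p.adjust(out$anova_p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Relative-change matrix with display clip bounds
#'
#' Extracts the feature x group percent-change-vs-reference matrix from a
#' \code{\link{groupCompare}} table, plus a display copy clipped at the
#' conventional heat-map bounds (+/-50 percentage points for relative
#' change; an absolute-abundance variant clips at +/-5).
#'
#' @param results A \code{groupCompare} result table.
#' @param reference Reference group name.
#' @param clip Clip bound for the display copy (default 50).
#' @return List with \code{change} (data values, unclipped),
#'   \code{display} (clipped), and \code{clip}.
#' @export
relativeChangeMatrix <- function(results, reference, clip = 50) {
  cols <- grep("^relchange_", colnames(results), value = TRUE)
  m <- as.matrix(results[, cols, drop = FALSE])
  colnames(m) <- sub("^relchange_", "", cols)
  rownames(m) <- results$feature
  ref <- m[, reference]
  if (any(is.na(ref)))
    warning("undefined change (zero reference mean) for: ",
            paste(results$feature[is.na(ref)], collapse = ", "))
  list(change = m, display = pmin(pmax(m, -clip), clip), clip = clip)
}

#' Before/after (pre/post) change table
#'
#' Per-feature table of abundance before and after an intervention, with
#' absolute and relative change and an optional comparator column (e.g. a
#' reference-group mean profile).
#'
#' @param pre,post Named percent vectors over the same panel features.
#' @param comparator Optional named comparator vector (same features).
#' @return \code{data.frame} with columns feature, pre, post, comparator
#'   (if given), abs_change, rel_change_pct.
#' @export
pairedChangeTable <- function(pre, post, comparator = NULL) {
  if (!identical(sort(names(pre)), sort(names(post))))
    stop("pre and post profiles cover different features")
  post <- post[names(pre)]
  out <- data.frame(feature = names(pre), pre = as.numeric(pre),
                    post = as.numeric(post))
  if (!is.null(comparator)) {
    if (!all(names(pre) %in% names(comparator)))
      stop("comparator lacks some features")
    out$comparator <- as.numeric(comparator[names(pre)])
  }
  out$abs_change <- out$post - out$pre
  out$rel_change_pct <- ifelse(out$pre != 0,
                               100 * out$abs_change / out$pre, NA_real_)
  out
}

#' Facet a comparison over a metadata column
#'
#' Runs \code{\link{groupCompare}} separately within each level of a
#' stratifying variable (e.g. sex), mirroring sex-stratified analyses.
#'
#' @inheritParams groupCompare
#' @param strata Factor/character stratifying label per sample.
#' @return Named list of \code{groupCompare} tables, one per stratum.
#' @export
groupCompareBy <- function(values, groups, strata, reference = NULL) {
  if (!is.matrix(values))
    values <- matrix(values, nrow = 1L, dimnames = list("feature", NULL))
  strata <- as.character(strata)
  out <- lapply(unique(strata), function(s) {
    keep <- strata == s
    groupCompare(values[, keep, drop = FALSE], groups[keep], reference)
  })
  names(out) <- unique(strata)
  out
}
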