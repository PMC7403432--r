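## Fisher linear discriminant classification of genotype from ROI features,
## with ROC/AUC over the discriminant score.  The AUC is computed from the
## Mann-Whitney rank statistic; leave-one-out scoring is available for
## honest evaluation.

#' Fisher linear discriminant with ROC/AUC
#'
#' Standardizes the features, fits the Fisher discriminant direction
#' w = Sw^-1 (mu1 - mu0) from the pooled within-class covariance, scores
#' every subject, and summarizes separation by the ROC curve and its AUC
#' (rank statistic).  A singular within-class covariance is
#' ridge-regularized with a warning.
#'
#' @param features Subject x feature numeric matrix or data.frame.
#' @param labels Two-level class label per subject; the second level is
#'   treated as the positive class.
#' @param positive Positive class label (default: second level).
#' @param loo Use leave-one-out discriminant scores for the ROC
#'   (default FALSE).
#' @return List with \code{weights}, \code{scores}, \code{roc}
#'   (data.frame fpr/tpr ordered by threshold), \code{auc} and
#'   \code{labels}.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' ldaClassify(x, rep(c("CC", "TT"), each = 20))$auc
#' @export
ldaClassify <- function(features, labels, positive = NULL, loo = FALSE) {
  x <- as.matrix(features)
  if (ncol(x) < 2L) stop("at least 2 features are required")
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  if (is.null(positive)) positive <- levels(labels)[2L]
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes must be present")

  fitDirection <- function(x, y) {
    xs <- scale(x)
    mu0 <- colMeans(xs[!y, , drop = FALSE])
    mu1 <- colMeans(xs[y, , drop = FALSE])
    sw <- (stats::cov(xs[!y, , drop = FALSE]) * (sum(!y) - 1L) +
             stats::cov(xs[y, , drop = FALSE]) * (sum(y) - 1L)) /
      (length(y) - 2L)
    if (rcond(sw) < 1e-10) {
      warning("singular within-class covariance; ridge-regularizing")
      sw <- sw + diag(1e-6 * mean(diag(sw)) + 1e-12, ncol(sw))
    }
    list(w = solve(sw, mu1 - mu0),
         center = attr(xs, "scaled:center"),
         scale = attr(xs, "scaled:scale"))
  }

  if (loo) {
    scores <- vapply(seq_len(nrow(x)), function(i) {
      f <- fitDirection(x[-i, , drop = FALSE], y[-i])
      sum(((x[i, ] - f$center) / f$scale) * f$w)
    }, numeric(1))
    f <- fitDirection(x, y)
  } else {
    f <- fitDirection(x, y)
    scores <- as.numeric(scale(x, f$center, f$scale) %*% f$w)
  }
  roc <- rocCurve(scores, y)
  list(weights = stats::setNames(as.numeric(f$w), colnames(x)),
       scores = scores, roc = roc, auc = aucRank(scores, y),
       labels = labels)
}

#' ROC curve of a score against binary labels
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical vector, TRUE for the positive class.
#' @return \code{data.frame} with \code{threshold}, \code{fpr},
#'   \code{tpr}.
#' @export
rocCurve <- function(scores, positive) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  np <- sum(positive); nn <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(scores >= t & positive) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !positive) / nn,
                numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' AUC via the Mann-Whitney rank statistic
#'
#' AUC = (R1 - n1(n1+1)/2) / (n1 n0) where R1 is the rank sum of the
#' positive scores (ties shared).
#'
#' @inheritParams rocCurve
#' @return AUC in [0, 1].
#' @export
aucRank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
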