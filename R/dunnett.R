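## One-way ANOVA with Dunnett many-to-one post-hoc comparisons against a
## designated control group.  Adjusted p-values use the equicoordinate
## multivariate-t distribution of the simultaneous contrasts, evaluated by
## seeded Monte-Carlo integration: the Dunnett correlation structure is
## one-factor (rho_jk = lambda_j lambda_k with lambda_j =
## sqrt(n_j / (n_j + n_0))), so draws are generated from a single shared
## normal factor plus independent components, divided by a common
## chi-square scale.

#' One-way ANOVA with Dunnett's post-hoc test
#'
#' @param values Numeric response vector.
#' @param groups Group label per observation.
#' @param control Control group label compared against every other group.
#' @param nsim Monte-Carlo draws for the adjusted p (default 2e5).
#' @param seed RNG seed for the Monte-Carlo integration.
#' @return List with \code{anova} (F, df, p) and \code{comparisons}
#'   (data.frame: group, estimate = mean difference vs control, t,
#'   p_unadjusted, p_adjusted).  With a single comparison the adjusted p
#'   is the exact two-sided pooled-variance t-test p.
#' @examples
#' set.seed(1)
#' anovaDunnett(rnorm(30), rep(c("CC", "CT", "TT"), 10), control = "CC")
#' @export
anovaDunnett <- function(values, groups, control, nsim = 2e5, seed = 1L) {
  groups <- as.factor(as.character(groups))
  if (!control %in% levels(groups))
    stop("control group absent: ", control)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 samples")
  lev <- c(control, setdiff(levels(groups), control))
  groups <- factor(groups, levels = lev)
  n <- as.integer(table(groups))
  k <- length(lev) - 1L            # number of comparisons
  N <- length(values)
  df <- N - length(lev)
  mu <- tapply(values, groups, mean)
  ss_within <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  s2 <- ss_within / df             # pooled variance
  grand <- mean(values)
  ss_between <- sum(n * (mu - grand)^2)
  Fstat <- (ss_between / (length(lev) - 1L)) / s2
  anova_p <- stats::pf(Fstat, length(lev) - 1L, df, lower.tail = FALSE)

  est <- mu[-1L] - mu[[1L]]
  se <- sqrt(s2 * (1 / n[-1L] + 1 / n[1L]))
  tstat <- est / se
  p_un <- 2 * stats::pt(-abs(tstat), df)
  if (k == 1L) {
    p_adj <- p_un
  } else {
    lambda <- sqrt(n[-1L] / (n[-1L] + n[1L]))
    maxT <- withSeed(seed, {
      z0 <- stats::rnorm(nsim)
      s <- sqrt(stats::rchisq(nsim, df) / df)
      m <- matrix(0, nsim, k)
      for (j in seq_len(k)) {
        zj <- stats::rnorm(nsim)
        m[, j] <- abs(lambda[j] * z0 + sqrt(1 - lambda[j]^2) * zj) / s
      }
      do.call(pmax, as.data.frame(m))
    })
    p_adj <- vapply(abs(tstat), function(ti) mean(maxT >= ti), numeric(1))
    p_adj <- pmax(p_adj, p_un)     # MC estimate never below the marginal p
  }
  list(anova = list(F = Fstat, df = length(lev) - 1L, df_resid = df,
                    p = anova_p),
       comparisons = data.frame(group = lev[-1L],
                                estimate = as.numeric(est),
                                t = as.numeric(tstat),
                                p_unadjusted = as.numeric(p_un),
                                p_adjusted = as.numeric(p_adj)))
}

#' Two-sided Dunnett critical value by Monte Carlo
#'
#' Equicoordinate quantile of max |T| over \code{k} comparisons at the
#' one-factor correlation implied by group sizes.
#'
#' @param k Number of comparisons.
#' @param df Residual degrees of freedom.
#' @param alpha Familywise level (default 0.05).
#' @param lambda Factor loadings (default balanced, sqrt(1/2)).
#' @param nsim,seed Monte-Carlo settings.
#' @return Critical value.
#' @export
dunnettCritical <- function(k, df, alpha = 0.05, lambda = rep(sqrt(0.5), k),
                            nsim = 2e5, seed = 1L) {
  maxT <- withSeed(seed, {
    z0 <- stats::rnorm(nsim)
    s <- sqrt(stats::rchisq(nsim, df) / df)
    m <- vapply(seq_len(k), function(j)
      abs(lambda[j] * z0 + sqrt(1 - lambda[j]^2) * stats::rnorm(nsim)) / s,
      numeric(nsim))
    do.call(pmax, as.data.frame(m))
  })
  unname(stats::quantile(maxT, 1 - alpha))
}
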