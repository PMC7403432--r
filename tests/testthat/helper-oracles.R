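## Independent oracles used across the test suite.  These deliberately
## re-derive quantities by a different route than the implementation.

## Atom-counting mass oracle: builds the explicit molecular formula of a
## free, fully permethylated glycan from free-monosaccharide formulas
## (methylation sites: Hex 5, HexNAc 5, dHex 4, NeuAc 7) and removes
## H2O + 2 CH3-H (net C2H6O) per glycosidic bond, then sums atomic masses.
oracleMz <- function(hexnac = 0, hex = 0, dhex = 0, neuac = 0) {
  am <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
          O = 15.9949146196, Na = 22.9897692809)
  free <- list(  # fully permethylated free monosaccharides
    hexnac = c(C = 13, H = 25, N = 1, O = 6),
    hex    = c(C = 11, H = 22, N = 0, O = 6),
    dhex   = c(C = 10, H = 20, N = 0, O = 5),
    neuac  = c(C = 18, H = 33, N = 1, O = 9))
  counts <- c(hexnac = hexnac, hex = hex, dhex = dhex, neuac = neuac)
  total <- c(C = 0, H = 0, N = 0, O = 0)
  for (m in names(counts)) total <- total + counts[[m]] * free[[m]]
  nbonds <- sum(counts) - 1
  total <- total - nbonds * c(C = 2, H = 6, N = 0, O = 1)
  sum(total * am[c("C", "H", "N", "O")]) + am[["Na"]]
}

## Textbook Welch two-sample t (two-sided) from first principles.
oracleWelch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Classic one-way ANOVA F from sums of squares.
oracleAnovaF <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  mu <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  ssb <- sum(n * (mu - grand)^2)
  ssw <- sum((values - mu[groups])^2)
  k <- nlevels(groups); N <- length(values)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k,
       p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

## Closed-form simple OLS.
oracleOls <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (length(x) - 2)
  se <- sqrt(s2 / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * pt(-abs(t), length(x) - 2))
}

## Brute-force AUC: fraction of (positive, negative) pairs ranked
## correctly, ties counting one half.
oracleAuc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

## Brute-force local-maximum scan (no thresholding refinements).
oracleLocalMaxima <- function(y, thr) {
  idx <- integer(0)
  for (i in 2:(length(y) - 1))
    if (y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] > thr)
      idx <- c(idx, i)
  idx
}

## A small random valid profile over the panel (non-negative, sums to 100).
randomProfile <- function(panel, seed = 1) {
  withSeed(seed, {
    x <- rgamma(length(panel), shape = 1)
    setNames(100 * x / sum(x), panelNames(panel))
  })
}
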