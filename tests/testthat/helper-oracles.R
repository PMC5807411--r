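# Independent oracles used by several test files.

# Brute-force NNLS oracle: zooming grid search over the non-negative
# orthant, independent of both package solvers.
grid_nnls <- function(A, b, rounds = 12L, pts = 21L) {
  n <- ncol(A)
  sv <- svd(A)$d
  lim <- max(1, 3 * sqrt(sum(b^2)) / min(sv[sv > 1e-12]))
  lo <- rep(0, n)
  hi <- rep(lim, n)
  best <- NULL
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(n), function(j) seq(lo[j], hi[j], length.out = pts))
    X <- t(as.matrix(expand.grid(grids)))
    obj <- colSums((A %*% X - b)^2)
    best <- X[, which.min(obj)]
    step <- (hi - lo) / (pts - 1)
    # keep a two-step margin so the continuous minimizer stays inside
    lo <- pmax(0, best - 2 * step)
    hi <- best + 2 * step
  }
  best
}

# Explicit cell-mean sums-of-squares decomposition for balanced two-way
# layouts: the independent ANOVA oracle.
anova_oracle <- function(y, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  g <- mean(y)
  n <- length(y)
  a <- nlevels(f1); b <- nlevels(f2); r <- n / (a * b)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, list(f1, f2), mean)
  ss1 <- b * r * sum((m1 - g)^2)
  ss2 <- a * r * sum((m2 - g)^2)
  ss12 <- r * sum((m12 - outer(m1 - g, m2 - g, `+`) - g)^2)
  sse <- sum((y - m12[cbind(f1, f2)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), n - a * b)
  ss <- c(ss1, ss2, ss12, sse)
  F <- (ss[1:3] / df[1:3]) / (ss[4] / df[4])
  list(ss = ss, df = df, F = F)
}
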