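# Independent oracles used by both the unit suites and the acceptance
# checks. Each recomputes its quantity by the most direct method available
# (exhaustive scan, explicit least squares, step-by-step greedy), sharing no
# code with the implementation under test.

# Otsu: scan every candidate threshold of a 256-bin histogram and maximize
# between-class variance; tie plateaus resolve to their midpoint.
otsu_oracle <- function(v) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = 257)
  mids <- (edges[-1] + edges[-257]) / 2
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          256), 256)
  between <- rep(-Inf, 255)
  for (t in 1:255) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / w0
    mu1 <- sum(counts[(t + 1):256] * mids[(t + 1):256]) / w1
    between[t] <- w0 * w1 * (mu0 - mu1)^2
  }
  mean(edges[which(between >= max(between) * (1 - 1e-12)) + 1])
}

# Savitzky-Golay: independent windowed polynomial fit at interior points.
sg_oracle <- function(x, window, polyorder) {
  h <- (window - 1) / 2
  n <- length(x)
  out <- x
  for (i in (h + 1):(n - h)) {
    idx <- (i - h):(i + h)
    fit <- stats::lm(x[idx] ~ stats::poly(idx, polyorder, raw = TRUE))
    out[i] <- stats::predict(fit)[h + 1]
  }
  out
}

# Kennard-Stone: exhaustive greedy recomputing all distances at every step.
ks_oracle <- function(X, n_select) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  best <- c(Inf, Inf); bestd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd + 1e-12) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_select) {
    rest <- setdiff(seq_len(n), sel)
    md <- sapply(rest, function(r) min(D[r, sel]))
    sel <- c(sel, rest[which.max(md)])
  }
  sel
}

# SPA chain: explicit Gram-Schmidt with a QR projection at every step.
spa_oracle_chain <- function(X, start, kmax) {
  Xc <- scale(X, scale = FALSE)
  sel <- start
  while (length(sel) < kmax) {
    Q <- qr.Q(qr(Xc[, sel, drop = FALSE]))
    R <- Xc - Q %*% crossprod(Q, Xc)
    nr <- colSums(R^2)
    nr[sel] <- -1
    if (max(nr) < 1e-10 * max(colSums(Xc^2))) break
    sel <- c(sel, which.max(nr))
  }
  sel
}
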