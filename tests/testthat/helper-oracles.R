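# Independent brute-force oracles used to pin down the vectorized
# implementations. Deliberately written as plain loops over the defining
# formulas, sharing no code with the package internals.

# Self-ONN "same" cross-correlation: y[t, co] = b[co] +
#   sum_n sum_k sum_ci W[[n]][k, ci, co] * x[t + k - offset, ci]^n
oracle_selfonn <- function(x, W, b) {
  x <- as.matrix(x)
  L <- nrow(x); Cin <- ncol(x)
  K <- dim(W[[1L]])[1L]; Cout <- dim(W[[1L]])[3L]
  off <- (K + 1L) %/% 2L
  y <- matrix(0, L, Cout)
  for (t in seq_len(L)) {
    for (co in seq_len(Cout)) {
      acc <- b[co]
      for (n in seq_along(W)) {
        for (k in seq_len(K)) {
          tt <- t + k - off
          if (tt >= 1L && tt <= L) {
            for (ci in seq_len(Cin)) {
              acc <- acc + W[[n]][k, ci, co] * x[tt, ci]^n
            }
          }
        }
      }
      y[t, co] <- acc
    }
  }
  y
}

# The seven metrics from their printed formulas, as scalar loops.
oracle_metrics <- function(x, xhat) {
  N <- length(x)
  ssd <- 0; mad <- 0; sae <- 0; sx2 <- 0; sh2 <- 0; sxh <- 0; scm <- 0
  xbar <- sum(x) / N
  for (i in seq_len(N)) {
    e <- x[i] - xhat[i]
    ssd <- ssd + e^2
    if (abs(e) > mad) mad <- abs(e)
    sae <- sae + abs(e)
    sx2 <- sx2 + x[i]^2
    sh2 <- sh2 + xhat[i]^2
    sxh <- sxh + x[i] * xhat[i]
    scm <- scm + (x[i] - xbar)^2
  }
  list(ssd = ssd, mad = mad, prd = sqrt(ssd / scm) * 100,
       cos_sim = if (sx2 == 0 || sh2 == 0) 0 else sxh / sqrt(sx2 * sh2),
       rmse = sqrt(ssd / N), mae = sae / N,
       snr = 10 * log10(sx2 / ssd))
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / (sqrt(sum(am^2)) * sqrt(sum(bm^2)))
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (no ties among |d| assumed).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  min(1, p)
}

# Small random feature matrix.
rand_mat <- function(L, C) matrix(stats::rnorm(L * C), L, C)

# A quick synthetic corrupted pair set shared across tests.
tiny_benchmark <- function(n_train = 24L, n_test = 12L, seed = 5L) {
  make_synthetic_benchmark(synth_config(), n_train, n_test, seed)
}
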