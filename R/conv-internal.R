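# Internal vectorized 1-D convolution machinery.
#
# All feature maps are stored "stacked": a batch of B sequences of length L
# with C channels is a (B*L) x C numeric matrix whose rows are sample-major
# (rows 1..L belong to sample 1, and so on). Convolutions run through
# compiled shifted-dgemm kernels (src/conv.cpp); kernels are flattened to
# the (Cin*K) x Cout "input-channel fastest" layout those kernels expect.

sigmoid <- function(z) 1 / (1 + exp(-z))

# (K, Cin, Cout) kernel array -> flat (Cin*K) x Cout matrix.
.wflat <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

# flat (Cin*K) x Cout gradient -> (K, Cin, Cout) array.
.wunflat <- function(wf, K, Cin, Cout) {
  aperm(array(wf, dim = c(Cin, K, Cout)), c(2L, 1L, 3L))
}

# Forward self-ONN convolution ("same" zero padding, stride 1).
# Wflats: list over orders n = 1..q of flat kernel matrices; bias: length
# Cout. The order-n term cross-correlates the element-wise n-th power of x.
.selfonn_fwd <- function(x, Wflats, bias, B, L, K) {
  Y <- conv_fwd_blas(x, Wflats[[1L]], B, L, K)
  if (length(Wflats) > 1L) {
    xn <- x
    for (n in 2:length(Wflats)) {
      xn <- xn * x
      Y <- Y + conv_fwd_blas(xn, Wflats[[n]], B, L, K)
    }
  }
  Y + rep(bias, each = B * L)
}

# Backward pass of .selfonn_fwd: gradients for x, every kernel bank (flat
# layout) and the bias.
.selfonn_bwd <- function(dY, x, Wflats, B, L, K) {
  q <- length(Wflats)
  dW <- vector("list", q)
  xn <- x
  for (n in seq_len(q)) {
    if (n > 1L) xn <- xn * x
    g <- conv_bwd_blas(xn, dY, Wflats[[n]], B, L, K)
    dW[[n]] <- g$dW
    dx <- if (n == 1L) g$dx else dx + n * x^(n - 1L) * g$dx
  }
  list(dx = dx, dW = dW, db = colSums(dY))
}

# Transpose convolution with stride s implemented as zero-insertion
# upsampling followed by a "same" cross-correlation; output length is s*L
# exactly, which is the length contract the U-Net shape bookkeeping needs.
.deconv_fwd <- function(x, Wflat, bias, B, L, s, K) {
  .selfonn_fwd(stuff_rows(x, B, L, s), list(Wflat), bias, B, s * L, K)
}

.deconv_bwd <- function(dY, x, Wflat, B, L, s, K) {
  g <- .selfonn_bwd(dY, stuff_rows(x, B, L, s), list(Wflat), B, s * L, K)
  list(dx = unstuff_rows(g$dx, B, L, s), dW = g$dW[[1L]], db = g$db)
}

# Per-sample statistics over the time axis via grouped row sums.
.group_mean <- function(x, B, L) {
  rowsum(x, rep(seq_len(B), each = L)) / L
}

# Per-sample, per-channel max over the time axis by pairwise folding.
.group_max <- function(x, B, L) {
  C <- ncol(x)
  v <- matrix(x, L, B * C)
  n <- nrow(v)
  while (n > 1L) {
    h <- n %/% 2L
    top <- v[seq_len(h), , drop = FALSE]
    bot <- v[h + seq_len(h), , drop = FALSE]
    red <- pmax(top, bot)
    if (n %% 2L == 1L) red[1L, ] <- pmax(red[1L, ], v[n, ])
    v <- matrix(red, h, B * C)
    n <- h
  }
  matrix(v, B, C)
}

# Inverted dropout mask (identity when not active).
.dropout_mask <- function(n, rate, active) {
  if (!active || rate <= 0) return(NULL)
  keep <- (stats::runif(n) >= rate)
  keep / (1 - rate)
}

.apply_mask <- function(x, mask) {
  if (is.null(mask)) x else x * mask
}
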