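# Cached forward passes and exact backward passes for every layer, operating
# on stacked batches ((B*L) x C matrices). These are the internals behind
# train(); the exported layer functions in layers.R share the same numerical
# kernels, so the finite-difference tests on these internals cover both.

# The input and gate paths see the same input, so both forward products run
# through one column-concatenated shifted-dgemm pass per order. `s > 1`
# switches to the transpose-convolution (zero-stuffed) variant.
.gated_pair_fwd <- function(x, Wi, bi, Wg, bg, B, L, K, s = 1L) {
  if (s > 1L) {
    x <- stuff_rows(x, B, L, s)
    L <- s * L
  }
  q <- length(Wi)
  Co <- length(bi)
  Y <- conv_fwd_blas(x, cbind(Wi[[1L]], Wg[[1L]]), B, L, K)
  if (q > 1L) {
    xn <- x
    for (n in 2:q) {
      xn <- xn * x
      Y <- Y + conv_fwd_blas(xn, cbind(Wi[[n]], Wg[[n]]), B, L, K)
    }
  }
  list(i = Y[, seq_len(Co), drop = FALSE] + rep(bi, each = B * L),
       g = Y[, Co + seq_len(Co), drop = FALSE] + rep(bg, each = B * L),
       xs = x)
}

.gated_pair_bwd <- function(dYi, dYg, cache, Wi, Wg, B, L, K, s = 1L) {
  q <- length(Wi)
  Co <- ncol(dYi)
  Ls <- if (s > 1L) s * L else L
  dcat <- cbind(dYi, dYg)
  dW <- vector("list", q)
  xn <- cache$xs
  for (n in seq_len(q)) {
    if (n > 1L) xn <- xn * cache$xs
    g <- conv_bwd_blas(xn, dcat, cbind(Wi[[n]], Wg[[n]]), B, Ls, K)
    dW[[n]] <- g$dW
    dx <- if (n == 1L) g$dx else dx + n * cache$xs^(n - 1L) * g$dx
  }
  if (s > 1L) dx <- unstuff_rows(dx, B, L, s)
  list(dx = dx,
       dWi = lapply(dW, function(w) w[, seq_len(Co), drop = FALSE]),
       dWg = lapply(dW, function(w) w[, Co + seq_len(Co), drop = FALSE]),
       dbi = colSums(dYi), dbg = colSums(dYg))
}

.layer_gated_conv_fwd <- function(x, Wi, bi, Wg, bg, B, L, K, rate, training,
                                  s = 1L) {
  fp <- .gated_pair_fwd(x, Wi, bi, Wg, bg, B, L, K, s)
  sg <- sigmoid(fp$g)
  mask <- .dropout_mask(length(sg), rate, training && ncol(sg) > 1L)
  m <- .apply_mask(sg, mask)
  list(y = fp$i * m,
       cache = list(xs = fp$xs, i = fp$i, sg = sg, mask = mask))
}

.layer_gated_conv_bwd <- function(dY, cache, Wi, Wg, B, L, K, s = 1L) {
  m <- .apply_mask(cache$sg, cache$mask)
  di <- dY * m
  dgraw <- .apply_mask(dY * cache$i, cache$mask) * cache$sg * (1 - cache$sg)
  g <- .gated_pair_bwd(di, dgraw, cache, Wi, Wg, B, L, K, s)
  list(dx = g$dx, dWi = g$dWi, dbi = g$dbi, dWg = g$dWg, dbg = g$dbg)
}

.layer_gated_deconv_fwd <- function(x, Wi, bi, Wg, bg, B, L, s, K, rate,
                                    training) {
  .layer_gated_conv_fwd(x, Wi, bi, Wg, bg, B, L, K, rate, training, s = s)
}

.layer_gated_deconv_bwd <- function(dY, cache, Wi, Wg, B, L, s, K) {
  .layer_gated_conv_bwd(dY, cache, Wi, Wg, B, L, K, s = s)
}

.layer_instnorm_fwd <- function(x, gamma, beta, eps, B, L) {
  grp <- rep(seq_len(B), each = L)
  m <- .group_mean(x, B, L)
  v <- pmax(.group_mean(x * x, B, L) - m^2, 0)
  istd <- 1 / sqrt(v + eps)
  xhat <- (x - m[grp, , drop = FALSE]) * istd[grp, , drop = FALSE]
  y <- xhat * rep(gamma, each = B * L) + rep(beta, each = B * L)
  list(y = y, cache = list(xhat = xhat, istd = istd))
}

.layer_instnorm_bwd <- function(dY, cache, gamma, B, L) {
  grp <- rep(seq_len(B), each = L)
  xhat <- cache$xhat
  dxhat <- dY * rep(gamma, each = B * L)
  m1 <- .group_mean(dxhat, B, L)
  m2 <- .group_mean(dxhat * xhat, B, L)
  dx <- cache$istd[grp, , drop = FALSE] *
    (dxhat - m1[grp, , drop = FALSE] - xhat * m2[grp, , drop = FALSE])
  list(dx = dx, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

.layer_leaky_fwd <- function(x, slope) {
  g <- slope + (1 - slope) * (x > 0)  # pointwise gain, also the derivative
  list(y = x * g, cache = g)
}

.layer_leaky_bwd <- function(dY, g, slope) {
  dY * g
}

# Non-overlapping max pool of width 2 along time (L must be even).
.layer_maxpool_fwd <- function(x, B, L) {
  odd <- seq(1L, B * L, by = 2L)
  top <- x[odd, , drop = FALSE]
  bot <- x[odd + 1L, , drop = FALSE]
  sel <- top >= bot
  list(y = pmax(top, bot), cache = sel)
}

.layer_maxpool_bwd <- function(dY, sel, B, L) {
  dx <- matrix(0, B * L, ncol(dY))
  odd <- seq(1L, B * L, by = 2L)
  dx[odd, ] <- dY * sel
  dx[odd + 1L, ] <- dY * !sel
  dx
}

.chleft <- function(v) {
  C <- ncol(v)
  if (C > 1L) cbind(0, v[, -C, drop = FALSE]) else v * 0
}
.chright <- function(v) {
  C <- ncol(v)
  if (C > 1L) cbind(v[, -1L, drop = FALSE], 0) else v * 0
}

.layer_attention_fwd <- function(x, w, b, B, L, rate, training) {
  grp <- rep(seq_len(B), each = L)
  xmax <- .group_max(x, B, L)
  xavg <- .group_mean(x, B, L)
  smax <- sigmoid(w[1L] * .chleft(xmax) + w[2L] * xmax +
                    w[3L] * .chright(xmax) + b)
  savg <- sigmoid(w[1L] * .chleft(xavg) + w[2L] * xavg +
                    w[3L] * .chright(xavg) + b)
  omega <- smax + savg
  mask <- .dropout_mask(length(omega), rate, training && ncol(x) > 1L)
  om <- .apply_mask(omega, mask)
  list(y = x * om[grp, , drop = FALSE],
       cache = list(xmax = xmax, xavg = xavg, smax = smax, savg = savg,
                    mask = mask, om = om))
}

.layer_attention_bwd <- function(dY, x, cache, w, B, L) {
  grp <- rep(seq_len(B), each = L)
  dom <- rowsum(dY * x, grp)
  dx <- dY * cache$om[grp, , drop = FALSE]
  domega <- .apply_mask(dom, cache$mask)
  dzmax <- domega * cache$smax * (1 - cache$smax)
  dzavg <- domega * cache$savg * (1 - cache$savg)
  dw <- c(sum(dzmax * .chleft(cache$xmax)) + sum(dzavg * .chleft(cache$xavg)),
          sum(dzmax * cache$xmax) + sum(dzavg * cache$xavg),
          sum(dzmax * .chright(cache$xmax)) + sum(dzavg * .chright(cache$xavg)))
  db <- sum(dzmax) + sum(dzavg)
  dvmax <- w[1L] * .chright(dzmax) + w[2L] * dzmax + w[3L] * .chleft(dzmax)
  dvavg <- w[1L] * .chright(dzavg) + w[2L] * dzavg + w[3L] * .chleft(dzavg)
  # max-pool scatter: distribute equally among tied maxima of each channel
  E <- (x == cache$xmax[grp, , drop = FALSE]) * 1
  cnt <- rowsum(E, grp)
  dx <- dx + E * (dvmax / cnt)[grp, , drop = FALSE]
  dx <- dx + dvavg[grp, , drop = FALSE] / L
  list(dx = dx, dw = dw, db = db)
}

.layer_resgate_fwd <- function(xin, xres, Win, bin, Wres, bres, B, L, rate,
                               training) {
  A <- xin %*% Win + rep(bin, each = B * L)
  R <- xres %*% Wres + rep(bres, each = B * L)
  mask <- .dropout_mask(length(R), rate, training && ncol(xin) > 1L)
  s <- sigmoid(A + .apply_mask(R, mask))
  list(y = xin * s, cache = list(xin = xin, xres = xres, s = s, mask = mask))
}

.layer_resgate_bwd <- function(dY, cache, Win, Wres) {
  s <- cache$s
  dA <- dY * cache$xin * s * (1 - s)
  dR <- .apply_mask(dA, cache$mask)
  list(dx_in = dY * s + tcrossprod(dA, Win),
       dx_res = tcrossprod(dR, Wres),
       dWin = crossprod(cache$xin, dA), dbin = colSums(dA),
       dWres = crossprod(cache$xres, dR), dbres = colSums(dR))
}
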