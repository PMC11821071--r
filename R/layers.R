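# Layer primitives of the fully gated denoising autoencoder: self-ONN
# convolutions, gated (de)convolutions, channel attention, residual gates and
# instance normalization. The exported functions operate on a single sequence
# (an L x C matrix, time along rows); the .layer_* internals additionally
# carry caches and exact backward passes for the training loop.

.as_feature_matrix <- function(x, what = "x") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  x
}

#' Parameters of a 1-D self-ONN convolution
#'
#' A self-organized operational layer generalizes an ordinary convolution by
#' applying a learnable degree-`q` polynomial (truncated MacLaurin series) to
#' every kernel tap: the order-`n` kernel bank cross-correlates the
#' element-wise n-th power of the input. The constant term of the polynomial
#' is folded into a single per-output-channel bias shared across orders, so
#' raising `q` adds kernel banks but no extra biases. With `q = 1` the layer
#' is exactly an ordinary 1-D convolution.
#'
#' @param q Polynomial order (integer >= 1).
#' @param kernel Odd kernel length (9 in the full model).
#' @param in_channels,out_channels Channel counts.
#' @param W Optional list of `q` kernel arrays, each `kernel x in x out`.
#'   Defaults to Glorot-uniform initialization.
#' @param b Optional bias vector of length `out_channels` (default zeros).
#' @return An object of class `selfonn_params`.
#' @export
self_onn_params <- function(q, kernel, in_channels, out_channels,
                            W = NULL, b = NULL) {
  q <- as.integer(q)
  kernel <- as.integer(kernel)
  if (is.na(q) || q < 1L) stop("q must be an integer >= 1")
  if (kernel < 1L || kernel %% 2L == 0L) stop("kernel length must be odd")
  if (is.null(W)) {
    lim <- sqrt(6 / (kernel * in_channels + kernel * out_channels))
    W <- lapply(seq_len(q), function(n) {
      array(stats::runif(kernel * in_channels * out_channels, -lim, lim),
            dim = c(kernel, in_channels, out_channels))
    })
  } else {
    if (length(W) != q) stop("W must hold exactly q kernel banks")
    W <- lapply(W, function(w) {
      w <- array(as.numeric(w), dim = c(kernel, in_channels, out_channels))
      w
    })
  }
  if (is.null(b)) b <- numeric(out_channels)
  if (length(b) != out_channels) stop("bias length must equal out_channels")
  structure(list(W = W, b = as.numeric(b), q = q, kernel = kernel,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "selfonn_params")
}

.wmats <- function(p) {
  lapply(p$W, .wflat)
}

#' Forward pass of a 1-D self-ONN convolution
#'
#' Computes `y[t, co] = b[co] + sum_n crosscorr(x^n, W[n])[t, co]` with
#' stride 1 and zero-padded "same" output length.
#'
#' @param x Input sequence, an `L x in_channels` matrix (a plain vector is
#'   treated as one channel).
#' @param p A [self_onn_params()] object.
#' @return An `L x out_channels` matrix.
#' @export
selfonn1d_forward <- function(x, p) {
  x <- .as_feature_matrix(x)
  if (ncol(x) != p$in_channels) stop("input channel count mismatch")
  .selfonn_fwd(x, .wmats(p), p$b, 1L, nrow(x), p$kernel)
}

#' Parameters of a gated layer (two parallel paths)
#'
#' @param input_path,gate_path [self_onn_params()] objects of identical shape;
#'   the gate path output is squashed by a sigmoid and multiplies the input
#'   path element-wise.
#' @param dropout_rate Dropout rate applied to the sigmoid mask during
#'   training (inactive at inference and when the layer has one channel).
#' @export
gated_layer_params <- function(input_path, gate_path, dropout_rate = 0.001) {
  stopifnot(inherits(input_path, "selfonn_params"),
            inherits(gate_path, "selfonn_params"))
  if (input_path$in_channels != gate_path$in_channels ||
      input_path$out_channels != gate_path$out_channels ||
      input_path$kernel != gate_path$kernel) {
    stop("input and gate paths must have identical shapes")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0,1)")
  structure(list(input_path = input_path, gate_path = gate_path,
                 dropout_rate = dropout_rate),
            class = "gated_layer_params")
}

#' Gated self-ONN layer forward
#'
#' `y = ONN_i(x) * dropout(sigmoid(ONN_g(x)))`; the dropout is identity at
#' inference and whenever the output has a single channel.
#'
#' @param x Input `L x C` matrix.
#' @param gp A [gated_layer_params()] object.
#' @param training Logical; enables dropout on the gate mask.
#' @param seed Optional integer seeding the dropout draw.
#' @return Gated feature map, same length as `x`.
#' @export
gated_selfonn_forward <- function(x, gp, training = FALSE, seed = NULL) {
  x <- .as_feature_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  p <- gp$input_path
  i <- .selfonn_fwd(x, .wmats(p), p$b, 1L, nrow(x), p$kernel)
  g <- gp$gate_path
  gy <- sigmoid(.selfonn_fwd(x, .wmats(g), g$b, 1L, nrow(x), g$kernel))
  mask <- .dropout_mask(length(gy), gp$dropout_rate,
                        training && p$out_channels > 1L)
  i * .apply_mask(gy, mask)
}

#' Gated transpose-convolution (deconvolution) layer forward
#'
#' Both paths are stride-`stride` transpose convolutions producing exactly
#' `stride * L` output samples; the gate path is squashed by a sigmoid and
#' multiplies the input path.
#'
#' @inheritParams gated_selfonn_forward
#' @param stride Upsampling factor (2 in the full model).
#' @export
gated_deconv_forward <- function(x, gp, stride = 2L, training = FALSE,
                                 seed = NULL) {
  x <- .as_feature_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  stride <- as.integer(stride)
  p <- gp$input_path
  g <- gp$gate_path
  L <- nrow(x)
  i <- .deconv_fwd(x, .wmats(p)[[1L]], p$b, 1L, L, stride, p$kernel)
  gy <- sigmoid(.deconv_fwd(x, .wmats(g)[[1L]], g$b, 1L, L, stride, g$kernel))
  if (nrow(i) != stride * L) stop("transpose convolution length contract violated")
  mask <- .dropout_mask(length(gy), gp$dropout_rate,
                        training && p$out_channels > 1L)
  i * .apply_mask(gy, mask)
}

#' Parameters of the channel attention module
#'
#' A single kernel-3 convolution (with bias, "same" zero padding) shared
#' between the global-max-pool and global-average-pool descriptors.
#'
#' @param w Length-3 shared kernel.
#' @param b Scalar bias.
#' @param dropout_rate Dropout on the attention mask during training.
#' @export
attention_params <- function(w = NULL, b = 0, dropout_rate = 0.001) {
  if (is.null(w)) w <- stats::runif(3L, -sqrt(6 / 4), sqrt(6 / 4))
  if (length(w) != 3L) stop("shared attention kernel has length 3")
  structure(list(w = as.numeric(w), b = as.numeric(b)[1L],
                 dropout_rate = dropout_rate),
            class = "attention_params")
}

.channel_conv3 <- function(v, w, b) {
  C <- ncol(v)
  left <- if (C > 1L) cbind(0, v[, -C, drop = FALSE]) else v * 0
  right <- if (C > 1L) cbind(v[, -1L, drop = FALSE], 0) else v * 0
  w[1L] * left + w[2L] * v + w[3L] * right + b
}

#' Channel attention forward
#'
#' Per channel, the global max and global average over the time axis are
#' passed through the shared kernel-3 convolution along the channel axis;
#' the two sigmoid-activated outputs are summed into a mask in (0, 2) that
#' rescales each channel.
#'
#' @param x Input `L x C` matrix.
#' @param ap An [attention_params()] object.
#' @inheritParams gated_selfonn_forward
#' @export
channel_attention_forward <- function(x, ap, training = FALSE, seed = NULL) {
  x <- .as_feature_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  C <- ncol(x)
  L <- nrow(x)
  xmax <- .group_max(x, 1L, L)
  xavg <- .group_mean(x, 1L, L)
  omega <- sigmoid(.channel_conv3(xmax, ap$w, ap$b)) +
    sigmoid(.channel_conv3(xavg, ap$w, ap$b))
  mask <- .dropout_mask(length(omega), ap$dropout_rate, training && C > 1L)
  omega <- .apply_mask(omega, mask)
  x * rep(as.vector(omega), each = L)
}

#' Parameters of the residual gate
#'
#' Two full-channel point (kernel-1) convolutions with biases: one on the
#' decoder feature map being gated, one on the encoder skip connection.
#'
#' @param Win,Wres `C x C` point-convolution weight matrices.
#' @param bin,bres Length-`C` biases.
#' @param dropout_rate Dropout on the skip path during training.
#' @export
residual_gate_params <- function(Win, bin = NULL, Wres = NULL, bres = NULL,
                                 dropout_rate = 0.001) {
  Win <- as.matrix(Win)
  C <- ncol(Win)
  if (nrow(Win) != C) stop("point convolutions must map C channels to C channels")
  if (is.null(Wres)) Wres <- matrix(stats::runif(C * C, -sqrt(3 / C), sqrt(3 / C)), C, C)
  Wres <- as.matrix(Wres)
  if (!all(dim(Wres) == c(C, C))) stop("Win and Wres must have identical shape")
  if (is.null(bin)) bin <- numeric(C)
  if (is.null(bres)) bres <- numeric(C)
  structure(list(Win = Win, bin = as.numeric(bin), Wres = Wres,
                 bres = as.numeric(bres), dropout_rate = dropout_rate),
            class = "residual_gate_params")
}

#' Residual gate forward
#'
#' `y = x_in * sigmoid(conv_in(x_in) + dropout(conv_res(x_res)))`. The
#' encoder skip `x_res` enters only through the sigmoid mask (no
#' concatenation); output shape equals `x_in`.
#'
#' @param x_in Decoder feature map, `L x C`.
#' @param x_res Encoder skip feature map, same shape as `x_in`.
#' @param rp A [residual_gate_params()] object.
#' @inheritParams gated_selfonn_forward
#' @export
residual_gate_forward <- function(x_in, x_res, rp, training = FALSE,
                                  seed = NULL) {
  x_in <- .as_feature_matrix(x_in, "x_in")
  x_res <- .as_feature_matrix(x_res, "x_res")
  if (!all(dim(x_in) == dim(x_res))) stop("x_in and x_res shapes differ")
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(x_in)
  A <- x_in %*% rp$Win + rep(rp$bin, each = L)
  R <- x_res %*% rp$Wres + rep(rp$bres, each = L)
  mask <- .dropout_mask(length(R), rp$dropout_rate,
                        training && ncol(x_in) > 1L)
  x_in * sigmoid(A + .apply_mask(R, mask))
}

#' Parameters of instance normalization
#'
#' @param gamma,beta Per-channel affine parameters.
#' @param eps Variance guard (> 0).
#' @export
instance_norm_params <- function(gamma, beta = NULL, eps = 1e-3) {
  gamma <- as.numeric(gamma)
  if (is.null(beta)) beta <- numeric(length(gamma))
  if (length(beta) != length(gamma)) stop("gamma/beta lengths differ")
  if (eps <= 0) stop("eps must be positive")
  structure(list(gamma = gamma, beta = as.numeric(beta), eps = eps),
            class = "instance_norm_params")
}

#' Instance normalization forward
#'
#' Standardizes each channel over the time axis of the individual sample
#' (never across a batch), then applies the learned affine map.
#'
#' @param x Input `L x C` matrix with `L >= 2`.
#' @param np_ An [instance_norm_params()] object.
#' @export
instance_norm_forward <- function(x, np_) {
  x <- .as_feature_matrix(x)
  if (ncol(x) != length(np_$gamma)) stop("channel count mismatch")
  L <- nrow(x)
  m <- colMeans(x)
  v <- colMeans(x^2) - m^2
  xhat <- (x - rep(m, each = L)) * rep(1 / sqrt(pmax(v, 0) + np_$eps), each = L)
  xhat * rep(np_$gamma, each = L) + rep(np_$beta, each = L)
}
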