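# Composite training objective: squared-error + maximum-deviation
# reconstruction term, a gradient (first-difference) maximum-deviation term,
# a batch-minimum Pearson correlation morphology term, and an L1 sparsity
# penalty on the encoder weights.

#' Loss configuration
#'
#' @param lambda_mad Weight of the maximum-absolute-deviation term inside the
#'   reconstruction loss (50 in the published setup).
#' @param lambda_morph Weight of the correlation (morphology) term.
#' @param lambda_reg Weight of the encoder L1 penalty.
#' @param corr_eps Guard added to the correlation denominator; zero-variance
#'   segments contribute correlation 0.
#' @export
loss_config <- function(lambda_mad = 50, lambda_morph = 10,
                        lambda_reg = 0.01, corr_eps = 1e-8) {
  if (lambda_mad < 0 || lambda_morph < 0 || lambda_reg < 0) {
    stop("all lambdas must be non-negative")
  }
  structure(list(lambda_mad = lambda_mad, lambda_morph = lambda_morph,
                 lambda_reg = lambda_reg, corr_eps = corr_eps),
            class = "fgdae_loss_config")
}

.as_segment_columns <- function(x) {
  if (is.list(x)) x <- do.call(cbind, lapply(x, as.numeric))
  if (is.null(x)) return(matrix(numeric(0), 0L, 0L))
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  as.matrix(x)
}

#' Reconstruction loss (SSD + weighted MAD)
#'
#' Per segment, the sum of squared distances plus `lambda_mad` times the
#' maximum absolute deviation; for multiple segments (columns or list
#' entries) the batch value is the mean over segments.
#'
#' @param x,xhat Clean target and estimate: vectors, matrices with segments
#'   in columns, or lists of vectors.
#' @param lc A [loss_config()].
#' @export
reconstruction_loss <- function(x, xhat, lc = loss_config()) {
  x <- .as_segment_columns(x); xhat <- .as_segment_columns(xhat)
  if (!all(dim(x) == dim(xhat))) stop("x and xhat lengths differ")
  e <- x - xhat
  mean(colSums(e^2) + lc$lambda_mad * apply(abs(e), 2L, max))
}

#' Gradient loss (maximum deviation between first differences)
#'
#' Unscaled maximum over positions of the absolute difference between the
#' forward first differences of target and estimate; batch value is the mean
#' over segments.
#'
#' @inheritParams reconstruction_loss
#' @export
gradient_loss <- function(x, xhat) {
  x <- .as_segment_columns(x); xhat <- .as_segment_columns(xhat)
  if (!all(dim(x) == dim(xhat))) stop("x and xhat lengths differ")
  if (nrow(x) < 2L) stop("gradient loss needs at least 2 samples")
  d <- diff(x) - diff(xhat)
  mean(apply(abs(d), 2L, max))
}

.pearson <- function(a, b, eps) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  sum(a * b) / max(den, eps)
}

#' Morphology (correlation) loss
#'
#' `lambda_morph * (1 - min_i pearson(x_i, xhat_i))` over the batch; the
#' unscaled term lies in [0, 2]. Zero-variance segments contribute
#' correlation 0.
#'
#' @param batch_x,batch_xhat Lists of vectors or matrices with segments in
#'   columns.
#' @param lc A [loss_config()].
#' @export
morphology_loss <- function(batch_x, batch_xhat, lc = loss_config()) {
  x <- .as_segment_columns(batch_x); xhat <- .as_segment_columns(batch_xhat)
  if (ncol(x) < 1L || nrow(x) < 1L) stop("empty batch")
  if (!all(dim(x) == dim(xhat))) stop("segment lengths differ")
  r <- vapply(seq_len(ncol(x)),
              function(j) .pearson(x[, j], xhat[, j], lc$corr_eps),
              numeric(1))
  lc$lambda_morph * (1 - min(r))
}

#' Encoder L1 penalty
#'
#' `lambda_reg` times the sum of absolute values of every trainable
#' parameter of the five encoder blocks.
#'
#' @param model An `fgdae_model`.
#' @param lc A [loss_config()].
#' @param mask Optional character vector of parameter-name prefixes to
#'   penalize (default: the encoder blocks).
#' @export
encoder_l1_penalty <- function(model, lc = loss_config(), mask = "^enc") {
  nm <- grep(paste(mask, collapse = "|"), names(model$params), value = TRUE)
  lc$lambda_reg * sum(vapply(model$params[nm],
                             function(w) sum(abs(w)), numeric(1)))
}

#' Total training loss with per-component breakdown
#'
#' Runs the model on the noisy segments and returns
#' `J = J_recon + J_grad + J_morph + J_reg` together with the four
#' components.
#'
#' @param batch A list with `noisy` and `clean` (`512 x B` matrices with
#'   segments in columns, or lists of vectors), a `pair_set`, or a list of
#'   (noisy, clean, recipe) pairs.
#' @param model An `fgdae_model`.
#' @param lc A [loss_config()].
#' @param training Logical; forwarded to the model (enables dropout).
#' @return A list with `total`, `j_recon`, `j_grad`, `j_morph`, `j_reg`.
#' @export
total_loss <- function(batch, model, lc = loss_config(), training = FALSE) {
  if (inherits(batch, "pair_set")) batch <- batch$pairs
  if (is.list(batch) && is.null(batch$noisy)) {
    batch <- list(noisy = lapply(batch, `[[`, "noisy"),
                  clean = lapply(batch, `[[`, "clean"))
  }
  noisy <- .as_segment_columns(batch$noisy)
  clean <- .as_segment_columns(batch$clean)
  xhat <- .as_segment_columns(fgdae_denoise(model, noisy, training = training))
  comp <- list(j_recon = reconstruction_loss(clean, xhat, lc),
               j_grad = gradient_loss(clean, xhat),
               j_morph = morphology_loss(clean, xhat, lc),
               j_reg = encoder_l1_penalty(model, lc))
  for (nm in names(comp)) {
    if (!is.finite(comp[[nm]])) stop(sprintf("non-finite loss component %s", nm))
  }
  c(list(total = comp$j_recon + comp$j_grad + comp$j_morph + comp$j_reg), comp)
}

# Data-dependent loss components and their (sub)gradient w.r.t. the estimate.
# X, Xhat: N x B matrices of segment columns. Used by train().
.loss_grad_data <- function(X, Xhat, lc) {
  N <- nrow(X); B <- ncol(X)
  E <- X - Xhat
  dXhat <- -2 * E / B
  # MAD subgradient at the (first) argmax of |error| per segment
  mad_vals <- numeric(B)
  for (j in seq_len(B)) {
    i <- which.max(abs(E[, j]))
    mad_vals[j] <- abs(E[i, j])
    dXhat[i, j] <- dXhat[i, j] - lc$lambda_mad * sign(E[i, j]) / B
  }
  j_recon <- mean(colSums(E^2)) + lc$lambda_mad * mean(mad_vals)

  D <- diff(X) - diff(Xhat)
  gvals <- numeric(B)
  for (j in seq_len(B)) {
    i <- which.max(abs(D[, j]))
    gvals[j] <- abs(D[i, j])
    s <- sign(D[i, j]) / B
    dXhat[i, j] <- dXhat[i, j] + s
    dXhat[i + 1L, j] <- dXhat[i + 1L, j] - s
  }
  j_grad <- mean(gvals)

  r <- vapply(seq_len(B), function(j) .pearson(X[, j], Xhat[, j], lc$corr_eps),
              numeric(1))
  jmin <- which.min(r)
  j_morph <- lc$lambda_morph * (1 - r[jmin])
  a <- X[, jmin] - mean(X[, jmin])
  b <- Xhat[, jmin] - mean(Xhat[, jmin])
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na * nb > lc$corr_eps) {
    gb <- a / (na * nb) - r[jmin] * b / nb^2
    gb <- gb - mean(gb)
    dXhat[, jmin] <- dXhat[, jmin] - lc$lambda_morph * gb
  }
  list(j_recon = j_recon, j_grad = j_grad, j_morph = j_morph, dXhat = dXhat)
}
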