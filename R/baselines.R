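# Classical zero-phase high-pass baselines: a 4th-order Butterworth IIR and
# a linear-phase windowed FIR, both with a 0.67 Hz cutoff at 360 Hz. The IIR
# zero-phase response is applied spectrally: the squared Butterworth
# magnitude (the exact response that bidirectional time-domain filtering
# approximates) multiplies the padded spectrum, which makes the operator
# exactly linear, exactly zero-phase and time-reversal symmetric.

#' Filter specification for the classical baselines
#'
#' @param kind `"iir"` (4th-order Butterworth) or `"fir"` (windowed
#'   linear-phase design).
#' @param cutoff_hz High-pass cutoff (Hz); must be below Nyquist.
#' @param order IIR order.
#' @param zero_phase Apply with zero net phase (always TRUE here).
#' @param fs Sampling rate (Hz).
#' @param fir_taps FIR tap count (odd); the published reference design is
#'   not fully specified, so this is a documented approximation with the
#'   same cutoff and zero-phase contract.
#' @export
filter_spec <- function(kind = c("iir", "fir"), cutoff_hz = 0.67,
                        order = 4L, zero_phase = TRUE, fs = 360,
                        fir_taps = 1441L) {
  kind <- match.arg(kind)
  if (cutoff_hz >= fs / 2) stop("cutoff must be below Nyquist")
  if (fir_taps %% 2L == 0L) stop("fir_taps must be odd (type-I linear phase)")
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase), fs = fs,
                 fir_taps = as.integer(fir_taps)),
            class = "filter_spec")
}

#' Zero-phase Butterworth high-pass baseline
#'
#' Removes baseline drift with the squared-magnitude (forward-backward)
#' response of a 4th-order Butterworth high-pass at `cutoff_hz`. The DC bin
#' is nulled exactly; output length equals input length.
#'
#' @param x Numeric input signal (at `spec$fs`).
#' @param spec A [filter_spec()] with `kind = "iir"`.
#' @export
iir_highpass_denoise <- function(x, spec = filter_spec("iir")) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 32L) stop("input too short for zero-phase filtering")
  bt <- signal::butter(spec$order, spec$cutoff_hz / (spec$fs / 2), "high")
  np <- stats::nextn(4L * n, 2L)
  w <- 2 * pi * (0:(np - 1L)) / np
  deg <- max(length(bt$b), length(bt$a))
  ez <- exp(-1i * outer(w, 0:(deg - 1L)))
  H <- drop(ez[, seq_along(bt$b), drop = FALSE] %*% bt$b) /
    drop(ez[, seq_along(bt$a), drop = FALSE] %*% bt$a)
  M <- Mod(H)^2
  M[1L] <- 0
  z <- c(x, numeric(np - n))
  y <- Re(stats::fft(stats::fft(z) * M, inverse = TRUE)) / np
  y[seq_len(n)]
}

.fir_highpass_taps <- function(spec) {
  h <- signal::fir1(spec$fir_taps - 1L, spec$cutoff_hz / (spec$fs / 2),
                    "high")
  h <- as.numeric(h)
  h - mean(h)  # exact DC null
}

#' Zero-phase FIR high-pass baseline
#'
#' Symmetric (linear-phase) windowed FIR high-pass applied with its group
#' delay compensated, so the net response is zero-phase; output length
#' equals input length.
#'
#' @param x Numeric input signal (at `spec$fs`).
#' @param spec A [filter_spec()] with `kind = "fir"`.
#' @export
fir_highpass_denoise <- function(x, spec = filter_spec("fir")) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 32L) stop("input too short for zero-phase filtering")
  h <- .fir_highpass_taps(spec)
  k <- length(h)
  full <- stats::convolve(x, rev(h), type = "open")
  c0 <- (k - 1L) %/% 2L
  full[(c0 + 1L):(c0 + n)]
}
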