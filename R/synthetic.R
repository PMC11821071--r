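# Synthetic clean ECG (sum-of-Gaussian P-QRS-T beats with heart-rate jitter)
# and the three artifact classes: low-frequency baseline wander, band-limited
# muscle-artifact bursts, and electrode-motion steps/spikes. Enables the full
# benchmark pipeline and training without any data download.

#' Synthetic data configuration
#'
#' The clean ECG is a quasi-periodic train of five Gaussian bumps per beat
#' (P, Q, R, S, T) at fixed phase offsets relative to the R peak, with
#' per-beat heart-rate jitter and millivolt amplitudes. Artifact band edges
#' mirror the classical baseline-wander cutoff (below 0.7 Hz) and the usual
#' surface-EMG band (5-50 Hz).
#'
#' @param fs Sampling rate (Hz); the pipeline operates at 360 Hz.
#' @param duration Signal duration in seconds.
#' @param heart_rate Mean heart rate in bpm.
#' @param hr_jitter Per-beat heart-rate standard deviation in bpm.
#' @param amplitudes Named wave amplitudes in mV (R dominant).
#' @param widths Named Gaussian widths in seconds.
#' @param offsets Named wave centers in seconds relative to the R peak.
#' @param bw_max_hz Upper band edge of baseline wander.
#' @param ma_band Muscle-artifact band in Hz.
#' @param seed Seed used by [synth_ecg()].
#' @export
synth_config <- function(fs = 360, duration = 10, heart_rate = 70,
                         hr_jitter = 3,
                         amplitudes = c(P = 0.15, Q = -0.1, R = 1.0,
                                        S = -0.25, T = 0.35),
                         widths = c(P = 0.025, Q = 0.010, R = 0.012,
                                    S = 0.012, T = 0.060),
                         offsets = c(P = -0.20, Q = -0.035, R = 0,
                                     S = 0.035, T = 0.30),
                         bw_max_hz = 0.7, ma_band = c(5, 50), seed = 1L) {
  if (fs != 360) stop("the pipeline operates at 360 Hz")
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (amplitudes[["R"]] <= max(abs(amplitudes[setdiff(names(amplitudes), "R")]))) {
    stop("R amplitude must dominate")
  }
  structure(list(fs = fs, duration = duration, heart_rate = heart_rate,
                 hr_jitter = hr_jitter, amplitudes = amplitudes,
                 widths = widths, offsets = offsets, bw_max_hz = bw_max_hz,
                 ma_band = ma_band, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic clean ECG
#'
#' Deterministic under `cfg$seed`; the returned series is zero-mean.
#'
#' @param cfg A [synth_config()].
#' @return Numeric vector of `fs * duration` samples (mV).
#' @export
synth_ecg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- round(cfg$fs * cfg$duration)
  t_end <- n / cfg$fs
  # R-peak instants: first beat half a mean interval in, then jittered RR
  beats <- numeric(0)
  tt <- 0.5 * 60 / cfg$heart_rate
  while (tt < t_end) {
    beats <- c(beats, tt)
    hr <- cfg$heart_rate + stats::rnorm(1L, 0, cfg$hr_jitter)
    hr <- max(hr, cfg$heart_rate / 3)
    tt <- tt + 60 / hr
  }
  x <- numeric(n)
  tgrid <- (seq_len(n) - 1L) / cfg$fs
  for (b in beats) {
    for (w in names(cfg$amplitudes)) {
      mu <- b + cfg$offsets[[w]]
      sd <- cfg$widths[[w]]
      lo <- max(1L, floor((mu - 5 * sd) * cfg$fs))
      hi <- min(n, ceiling((mu + 5 * sd) * cfg$fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + cfg$amplitudes[[w]] *
        exp(-(tgrid[idx] - mu)^2 / (2 * sd^2))
    }
  }
  x - mean(x)
}

#' Generate a synthetic artifact series
#'
#' `"bw"`: random-phase sinusoids below `bw_max_hz` plus a low-passed random
#' walk. `"ma"`: band-limited (5-50 Hz) noise under random burst envelopes.
#' `"em"`: sparse step discontinuities plus smoothed spikes over a small
#' noise floor. Deterministic under `seed`.
#'
#' @param kind `"bw"`, `"ma"` or `"em"` (case-insensitive).
#' @param n Series length in samples (>= 512).
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
synth_artifact <- function(kind, n, cfg = synth_config(), seed = 1L) {
  kind <- tolower(kind)
  if (!kind %in% c("bw", "ma", "em")) stop(sprintf("unknown artifact kind '%s'", kind))
  if (n < 512L) stop("artifact series must be at least one segment long")
  set.seed(seed)
  fs <- cfg$fs
  tgrid <- (seq_len(n) - 1L) / fs
  nyq <- fs / 2
  if (kind == "bw") {
    f <- stats::runif(8L, 0.05, cfg$bw_max_hz * 0.92)
    a <- stats::runif(8L, 0.3, 1)
    ph <- stats::runif(8L, 0, 2 * pi)
    x <- drop(sin(outer(tgrid, 2 * pi * f) +
                    matrix(ph, n, 8L, byrow = TRUE)) %*% a)
    walk <- cumsum(stats::rnorm(n)) / sqrt(n)
    lp <- signal::butter(2L, min(0.3, cfg$bw_max_hz / 2) / nyq, "low")
    walk <- signal::filtfilt(lp, walk)
    x <- x + 2 * walk
  } else if (kind == "ma") {
    bp <- signal::butter(4L, cfg$ma_band / nyq, "pass")
    base <- signal::filtfilt(bp, stats::rnorm(n))
    n_bursts <- max(1L, stats::rpois(1L, n / fs / 2))
    env <- rep(0.15, n)
    for (i in seq_len(n_bursts)) {
      c0 <- stats::runif(1L, 0, n / fs)
      w <- stats::runif(1L, 0.5, 2)
      env <- env + exp(-(tgrid - c0)^2 / (2 * w^2))
    }
    x <- base * env
  } else {
    n_steps <- max(2L, stats::rpois(1L, n / fs * 0.4))
    x <- numeric(n)
    pos <- sample.int(n - 1L, n_steps)
    amp <- stats::runif(n_steps, 0.5, 2) * sample(c(-1, 1), n_steps, TRUE)
    imp <- numeric(n)
    imp[pos + 1L] <- amp
    x <- cumsum(imp)
    n_spikes <- max(1L, stats::rpois(1L, n / fs * 0.3))
    spos <- sample.int(n, n_spikes)
    samp <- stats::runif(n_spikes, 0.5, 1.5) * sample(c(-1, 1), n_spikes, TRUE)
    kw <- round(0.03 * fs)
    kern <- exp(-((-kw:kw) / (0.01 * fs))^2 / 2)
    sp <- numeric(n)
    sp[spos] <- samp
    sp <- stats::filter(c(numeric(kw), sp, numeric(kw)), kern, sides = 2L)
    x <- x + as.numeric(sp[(kw + 1L):(kw + n)])
    x <- x + 0.05 * stats::rnorm(n)
  }
  as.numeric(x)
}

#' Build a synthetic random-mixed-noise benchmark
#'
#' Generates synthetic clean ECG and artifacts, segments with the 512/256
#' sliding window, draws one RMN recipe per segment and corrupts, exactly as
#' [build_benchmark()] does for real recordings. Train and test artifacts
#' (and ECG) come from disjoint seeds, mirroring the uncorrelated-noise
#' contract of the real noise splits.
#'
#' @param cfg A [synth_config()].
#' @param n_train,n_test Number of training / testing pairs.
#' @param seed Master seed; all internal seeds derive from it.
#' @return A list with `train` and `test` pair sets (flagged synthetic).
#' @export
make_synthetic_benchmark <- function(cfg = synth_config(), n_train = 256L,
                                     n_test = 64L, seed = 1L) {
  if (n_train < 1L || n_test < 1L) stop("pair counts must be >= 1")
  seed <- as.integer(seed)
  one_side <- function(n_pairs, side_seed, role) {
    nsamp <- (n_pairs - 1L) * 256L + 512L
    ccfg <- cfg
    ccfg$duration <- nsamp / cfg$fs
    ccfg$seed <- side_seed
    ecg <- synth_ecg(ccfg)[seq_len(nsamp)]
    split <- structure(list(
      bw = synth_artifact("bw", nsamp, cfg, side_seed + 1L),
      ma = synth_artifact("ma", nsamp, cfg, side_seed + 2L),
      em = synth_artifact("em", nsamp, cfg, side_seed + 3L),
      version = "synthetic", role = role), class = "noise_split")
    segs <- segment_signal(ecg, source_record = sprintf("synth_%s", role),
                           channel = 1L)
    set.seed(side_seed + 4L)
    .pair_set(.make_pairs(segs, split), "synthetic", side_seed, role,
              synthetic = TRUE)
  }
  list(train = one_side(n_train, seed, "train"),
       test = one_side(n_test, seed + 104729L, "test"))
}
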