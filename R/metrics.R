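# Seven signal-quality metrics for a clean/denoised pair, stratified
# reporting over noise amplitude bins and noise-type combinations, and
# paired Wilcoxon significance testing.

#' Compute the seven evaluation metrics for one pair
#'
#' For a clean segment `x` and its reconstruction `xhat`:
#' sum of squared distances (SSD, mV^2 summed over samples), maximum
#' absolute deviation (MAD, mV), percentage root-mean-square difference
#' (PRD, %, mean-centered denominator), cosine similarity, root mean square
#' error (mV), mean absolute error (mV) and signal-to-noise ratio (dB,
#' non-centered signal energy over error energy).
#'
#' A perfect reconstruction reports SNR at the documented cap (`snr_cap`);
#' cosine similarity with a zero-norm vector is defined as 0; PRD of a
#' constant target is an error (the denominator vanishes).
#'
#' @param x Clean segment (numeric vector, length >= 2).
#' @param xhat Reconstructed segment, same length.
#' @param snr_cap Cap substituted for an infinite SNR.
#' @return A list of class `metrics_report` with elements `ssd`, `mad`,
#'   `prd`, `cos_sim`, `rmse`, `mae`, `snr`.
#' @export
compute_metrics <- function(x, xhat, snr_cap = 300) {
  x <- as.numeric(x); xhat <- as.numeric(xhat)
  if (length(x) != length(xhat)) stop("x and xhat lengths differ")
  N <- length(x)
  if (N < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("non-finite clean segment")
  e <- x - xhat
  ssd <- sum(e^2)
  cden <- sum((x - mean(x))^2)
  if (cden <= 0) stop("PRD undefined for a constant target segment")
  nx <- sqrt(sum(x^2)); nh <- sqrt(sum(xhat^2))
  cs <- if (nx == 0 || nh == 0) 0 else sum(x * xhat) / (nx * nh)
  snr <- if (ssd == 0) snr_cap else {
    min(10 * log10(sum(x^2) / ssd), snr_cap)
  }
  structure(list(ssd = ssd,
                 mad = max(abs(e)),
                 prd = sqrt(ssd / cden) * 100,
                 cos_sim = cs,
                 rmse = sqrt(ssd / N),
                 mae = mean(abs(e)),
                 snr = snr),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "SSD %.4g  MAD %.4g  PRD %.3f%%  CosSim %.4f  RMSE %.4g  MAE %.4g  SNR %.3f dB\n",
    x$ssd, x$mad, x$prd, x$cos_sim, x$rmse, x$mae, x$snr))
  invisible(x)
}

.metric_names <- c("ssd", "mad", "prd", "cos_sim", "rmse", "mae", "snr")

.amplitude_bins <- data.frame(
  stratum = c("0.2to0.6", "0.6to1.0", "1.0to1.5", "1.5to2.0"),
  lo = c(0.2, 0.6, 1.0, 1.5),
  hi = c(0.6, 1.0, 1.5, 2.0))

.combination_labels <- c("Clean", "BW", "MA", "BW+MA", "EM", "BW+EM",
                         "MA+EM", "BW+MA+EM")

# Amplitude bins are left-closed, right-open; the last bin [1.5, 2] is closed.
.amplitude_stratum <- function(a) {
  ifelse(a >= 1.5 & a <= 2, "1.5to2.0",
         ifelse(a >= 1.0, "1.0to1.5",
                ifelse(a >= 0.6, "0.6to1.0",
                       ifelse(a >= 0.2, "0.2to0.6", NA_character_))))
}

#' Stratified metric report
#'
#' Mean and standard deviation of each of the seven metrics per stratum,
#' where strata are either the four noise-amplitude bins
#' `[0.2,0.6) [0.6,1.0) [1.0,1.5) [1.5,2.0]` of the corruption scale, or the
#' eight noise-type combinations (Clean, BW, MA, BW+MA, EM, BW+EM, MA+EM,
#' BW+MA+EM).
#'
#' @param pairs List of pairs; each element is a list with `clean`,
#'   `denoised` (numeric vectors) and `recipe` (a noise recipe carrying
#'   `scale_a` and `combination`).
#' @param mode `"amplitude"` or `"noise_type"`.
#' @return A data frame with columns `stratum`, `n`, and `<metric>_mean`,
#'   `<metric>_sd` for each metric; stratum counts sum to the number of
#'   pairs (every recipe carries a drawn scale).
#' @export
stratified_report <- function(pairs, mode = c("amplitude", "noise_type")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) stop("empty pair list")
  for (p in pairs) {
    if (is.null(p$recipe)) stop("pair without a noise recipe")
  }
  vals <- t(vapply(pairs, function(p) {
    unlist(compute_metrics(p$clean, p$denoised)[.metric_names])
  }, numeric(7)))
  colnames(vals) <- .metric_names
  if (mode == "amplitude") {
    a <- vapply(pairs, function(p) p$recipe$scale_a, numeric(1))
    strat <- .amplitude_stratum(a)
    levels <- .amplitude_bins$stratum
  } else {
    comb <- vapply(pairs, function(p) p$recipe$combination, numeric(1))
    strat <- .combination_labels[comb]
    levels <- .combination_labels
  }
  out <- lapply(levels, function(s) {
    sel <- which(!is.na(strat) & strat == s)
    row <- data.frame(stratum = s, n = length(sel))
    for (m in .metric_names) {
      v <- vals[sel, m]
      row[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(m, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else
        if (length(v) == 1L) 0 else NA_real_
    }
    row
  })
  do.call(rbind, out)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired per-segment errors, with the
#' standard zero-discard convention; if every difference is zero the p-value
#' is defined as 1. Exact when there are no ties among the non-zero
#' differences and n < 50.
#'
#' @param errors_a,errors_b Paired error vectors of equal length.
#' @return The two-sided p-value.
#' @export
paired_wilcoxon <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("unpaired error vectors")
  d <- as.numeric(errors_a) - as.numeric(errors_b)
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  suppressWarnings(
    stats::wilcox.test(d, exact = !any(duplicated(abs(d))) && length(d) < 50,
                       correct = TRUE)$p.value)
}
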