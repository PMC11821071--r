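# Benchmark construction: record loading (WFDB / CSV), resampling to 360 Hz,
# sliding-window segmentation with per-segment mean removal, the
# train/test noise splits, random-mixed-noise (RMN) recipes and additive
# corruption, and assembly of aligned (noisy, clean, recipe) pair sets.

#' QTDB record identifiers reserved for the test set
#'
#' The 14 subjects (of 105) held out for testing in the benchmark split.
#' @export
qtdb_test_records <- c("sel123", "sel233", "sel302", "sel307", "sel820",
                       "sel853", "sel16420", "sel16795", "sel0106",
                       "sel0121", "sel32", "sel49", "sel14046", "sel15815")

# ---- minimal WFDB support (formats 212 and 16) -----------------------------

.parse_wfdb_header <- function(hea) {
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rec <- sub("/.*$", "", top[1L])
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  nsamp <- if (length(top) >= 4L) as.numeric(top[4L]) else NA_real_
  if (is.na(nsig) || nsig < 1L) stop(sprintf("malformed WFDB header %s", hea))
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    if (length(f) < 2L) stop(sprintf("malformed signal line %d in %s", i, hea))
    fmt <- as.integer(sub("x.*$", "", f[2L]))
    gainfield <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gainfield))
    baseline <- if (grepl("\\(", gainfield)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield))
    } else NA_real_
    adczero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    if (is.na(baseline)) baseline <- adczero
    if (is.na(gain) || gain == 0) gain <- 200
    list(file = f[1L], format = fmt, gain = gain, baseline = baseline,
         description = if (length(f) >= 9L) paste(f[-(1:8)], collapse = " ")
         else sprintf("sig%d", i))
  })
  list(record = rec, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

.read_dat_212 <- function(path, nsig, nsamp) {
  raw <- readBin(path, "raw", n = file.size(path))
  npairs <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * npairs)]), nrow = 3L)
  s1 <- b[1L, ] + bitwShiftL(bitwAnd(b[2L, ], 0x0FL), 8L)
  s2 <- b[3L, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2L, ], 4L), 0x0FL), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  ntot <- if (is.na(nsamp)) (length(flat) %/% nsig) * nsig else nsamp * nsig
  matrix(flat[seq_len(ntot)], ncol = nsig, byrow = TRUE)
}

.read_dat_16 <- function(path, nsig, nsamp) {
  v <- readBin(path, "integer", n = file.size(path) %/% 2L, size = 2L,
               signed = TRUE, endian = "little")
  ntot <- if (is.na(nsamp)) (length(v) %/% nsig) * nsig else nsamp * nsig
  matrix(v[seq_len(ntot)], ncol = nsig, byrow = TRUE)
}

.read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop(sprintf("WFDB header not found: %s", hea))
  h <- .parse_wfdb_header(hea)
  datfile <- file.path(dirname(hea), h$signals[[1L]]$file)
  if (!file.exists(datfile)) stop(sprintf("WFDB data file not found: %s", datfile))
  fmt <- h$signals[[1L]]$format
  dig <- switch(as.character(fmt),
                "212" = .read_dat_212(datfile, h$nsig, h$nsamp),
                "16" = .read_dat_16(datfile, h$nsig, h$nsamp),
                stop(sprintf("unsupported WFDB format %d in %s", fmt, hea)))
  phys <- dig
  for (i in seq_len(h$nsig)) {
    phys[, i] <- (dig[, i] - h$signals[[i]]$baseline) / h$signals[[i]]$gain
  }
  colnames(phys) <- vapply(h$signals, `[[`, character(1), "description")
  list(signals = phys, fs = h$fs, record = h$record)
}

#' Write a WFDB record (format 16)
#'
#' Minimal writer used to materialize fixtures and archives: physical units
#' (mV) are digitized with the given gain and stored as 16-bit little-endian
#' samples with a plain-text header.
#'
#' @param signals Numeric matrix (samples x channels) in mV.
#' @param record Record name (file basename).
#' @param dir Output directory.
#' @param fs Sampling rate in Hz.
#' @param gain ADC gain (units per mV).
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb <- function(signals, record, dir, fs = 360, gain = 200) {
  signals <- as.matrix(signals)
  nsig <- ncol(signals)
  n <- nrow(signals)
  dig <- round(signals * gain)
  dig <- pmax(pmin(dig, 32767), -32768)
  hea <- c(sprintf("%s %d %g %d", record, nsig, fs, n),
           vapply(seq_len(nsig), function(i) {
             sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 ch%d",
                     record, gain, as.integer(dig[1L, i]), i)
           }, character(1)))
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  flat <- as.integer(t(dig))
  writeBin(flat, file.path(dir, paste0(record, ".dat")), size = 2L,
           endian = "little")
  invisible(file.path(dir, record))
}

#' Load a multichannel record
#'
#' Reads either a WFDB record (`.hea`/`.dat`, formats 212 and 16, gain and
#' baseline applied to yield mV) or a delimited text file with one channel
#' per column and a header row.
#'
#' @param path Record path: for WFDB the header path or the path without
#'   extension; for CSV the file path.
#' @param format `"auto"` (by extension), `"wfdb"` or `"csv"`.
#' @param fs Sampling rate, required for CSV input.
#' @return A list with `signals` (samples x channels matrix), `fs` and
#'   `record`.
#' @export
load_record <- function(path, format = c("auto", "wfdb", "csv"), fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "wfdb") return(.read_wfdb(path))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (ncol(df) < 1L || nrow(df) < 1L) stop(sprintf("malformed CSV: %s", path))
  m <- as.matrix(df)
  if (!is.numeric(m) || !all(is.finite(m))) {
    stop(sprintf("non-numeric values in CSV: %s", path))
  }
  if (is.null(fs)) stop("fs must be given for CSV input")
  list(signals = m, fs = fs,
       record = sub("\\.csv$", "", basename(path), ignore.case = TRUE))
}

#' Resample a signal to a new rate
#'
#' Band-limited polyphase resampling; the identity when the rates already
#' match. Output length is `round(length(x) * fs_out / fs_in)`.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Sampling rates in Hz.
#' @export
resample_signal <- function(x, fs_in, fs_out = 360) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  if (fs_in == fs_out) return(as.numeric(x))
  r <- round(c(fs_out, fs_in) * 1e6)
  g <- .gcd(r[1L], r[2L])
  p <- r[1L] %/% g; q <- r[2L] %/% g
  y <- signal::resample(as.numeric(x), p, q)
  nout <- round(length(x) * fs_out / fs_in)
  if (length(y) >= nout) y[seq_len(nout)] else c(y, rep(y[length(y)], nout - length(y)))
}

.gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Segment a signal with a sliding window
#'
#' Windows start at index 0 with stride `window - overlap`; incomplete
#' trailing windows are dropped, and the mean of each segment is subtracted
#' (no amplitude normalization is applied).
#'
#' @param x Numeric vector.
#' @param window,overlap Window length and overlap in samples.
#' @param subtract_mean Subtract the per-segment mean.
#' @param fs Sampling rate recorded on the segments.
#' @param source_record,channel Provenance identifiers.
#' @return A list of `signal_segment` objects (possibly empty).
#' @export
segment_signal <- function(x, window = 512L, overlap = 256L,
                           subtract_mean = TRUE, fs = 360,
                           source_record = NA_character_, channel = NA) {
  if (overlap < 0L || window <= overlap) stop("need window > overlap >= 0")
  x <- as.numeric(x)
  n <- length(x)
  if (n < window) return(list())
  stride <- window - overlap
  starts <- seq(0L, n - window, by = stride)
  lapply(starts, function(s) {
    seg <- x[(s + 1L):(s + window)]
    if (subtract_mean) seg <- seg - mean(seg)
    structure(list(samples = seg, fs = fs, source_record = source_record,
                   channel = channel, start_index = s),
              class = "signal_segment")
  })
}

.segment_samples <- function(seg) {
  if (inherits(seg, "signal_segment")) seg$samples else as.numeric(seg)
}

# ---- noise splits and RMN corruption ---------------------------------------

.noise_half <- function(x, half) {
  n <- length(x) %/% 2L
  if (half == "a") x[seq_len(n)] else x[(n + 1L):(2L * n)]
}

#' Build the train/test noise splits
#'
#' Each two-channel noise record is split in half per channel (halves "a"
#' and "b"). Version nv1 trains on channel 1 half "a" and tests on channel 2
#' half "b"; nv2 trains on channel 2 half "a" and tests on channel 1 half
#' "b", so train and test noise are always uncorrelated.
#'
#' @param nstdb_bw,nstdb_ma,nstdb_em Two-channel noise records: matrices
#'   (samples x 2) or lists with a `signals` matrix.
#' @param version `"nv1"` or `"nv2"`.
#' @return A list with `train` and `test` noise splits, each a list of class
#'   `noise_split` with `bw`, `ma`, `em` series, `version` and `role`.
#' @export
make_noise_splits <- function(nstdb_bw, nstdb_ma, nstdb_em,
                              version = c("nv1", "nv2")) {
  version <- match.arg(version)
  getsig <- function(r) {
    m <- if (is.list(r) && !is.null(r$signals)) r$signals else r
    m <- as.matrix(m)
    if (ncol(m) < 2L) stop("noise records must have 2 channels")
    m
  }
  recs <- list(bw = getsig(nstdb_bw), ma = getsig(nstdb_ma),
               em = getsig(nstdb_em))
  train_ch <- if (version == "nv1") 1L else 2L
  test_ch <- if (version == "nv1") 2L else 1L
  mk <- function(ch, half, role) {
    structure(c(lapply(recs, function(m) .noise_half(m[, ch], half)),
                list(version = version, role = role)),
              class = "noise_split")
  }
  list(train = mk(train_ch, "a", "train"), test = mk(test_ch, "b", "test"))
}

.combination_flags <- rbind(
  bw = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
  ma = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
  em = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))

#' Draw random-mixed-noise recipes
#'
#' Each recipe draws one of the 8 noise-type combinations uniformly
#' (combination 1 adds no noise and keeps the segment clean), an amplitude
#' scale uniform on [0.2, 2] independently of the combination, and a uniform
#' start offset into each flagged noise series. Uses the current RNG state;
#' seed with [set.seed()] for reproducibility.
#'
#' @param split A `noise_split` supplying the noise series.
#' @param n Number of recipes to draw.
#' @param segment_length Segment length the offsets must accommodate.
#' @return A single `noise_recipe` if `n == 1`, else a list of them.
#' @export
sample_rmn_recipe <- function(split, n = 1L, segment_length = 512L) {
  stopifnot(inherits(split, "noise_split"))
  draw1 <- function() {
    comb <- sample.int(8L, 1L)
    a <- stats::runif(1L, 0.2, 2)
    offs <- list()
    for (ty in c("bw", "ma", "em")) {
      if (.combination_flags[ty, comb]) {
        hi <- length(split[[ty]]) - segment_length + 1L
        if (hi < 1L) stop(sprintf("noise series '%s' shorter than a segment", ty))
        offs[[ty]] <- sample.int(hi, 1L)
      }
    }
    structure(list(combination = comb,
                   bw = unname(.combination_flags["bw", comb]),
                   ma = unname(.combination_flags["ma", comb]),
                   em = unname(.combination_flags["em", comb]),
                   scale_a = a, noise_offsets = offs),
              class = "noise_recipe")
  }
  if (n == 1L) draw1() else lapply(seq_len(n), function(i) draw1())
}

#' Corrupt a clean segment with a noise recipe
#'
#' The flagged noise slices are summed, the sum is rescaled so its peak
#' equals `scale_a` times the clean segment's peak, and added to the clean
#' segment. Combination 1 returns the clean segment unchanged.
#'
#' @param clean A `signal_segment` or numeric vector.
#' @param split The `noise_split` holding the noise series.
#' @param recipe A `noise_recipe` with offsets valid for `split`.
#' @return The noisy segment, same type as `clean`.
#' @export
corrupt_segment <- function(clean, split, recipe) {
  x <- .segment_samples(clean)
  n <- length(x)
  if (recipe$combination == 1L) return(clean)
  combined <- numeric(n)
  for (ty in c("bw", "ma", "em")) {
    if (isTRUE(recipe[[ty]])) {
      o <- recipe$noise_offsets[[ty]]
      combined <- combined + split[[ty]][o:(o + n - 1L)]
    }
  }
  mc <- max(abs(x))
  if (mc == 0) stop("zero-amplitude clean segment cannot anchor noise scaling")
  mn <- max(abs(combined))
  if (mn == 0) stop("combined noise is identically zero")
  noisy <- x + combined * (recipe$scale_a * mc / mn)
  if (inherits(clean, "signal_segment")) {
    out <- clean
    out$samples <- noisy
    out
  } else noisy
}

.make_pairs <- function(segments, split, seed_tag = NULL) {
  lapply(segments, function(seg) {
    recipe <- sample_rmn_recipe(split, 1L, length(.segment_samples(seg)))
    noisy <- corrupt_segment(seg, split, recipe)
    list(noisy = .segment_samples(noisy), clean = .segment_samples(seg),
         recipe = recipe,
         source_record = if (inherits(seg, "signal_segment")) seg$source_record else NA,
         channel = if (inherits(seg, "signal_segment")) seg$channel else NA,
         start_index = if (inherits(seg, "signal_segment")) seg$start_index else NA)
  })
}

.pair_set <- function(pairs, version, seed, role, synthetic = FALSE) {
  structure(list(pairs = pairs, version = version, seed = seed, role = role,
                 synthetic = synthetic),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %d (noisy, clean, recipe) triples [%s, %s%s, seed %s]\n",
              length(x$pairs), x$role, x$version,
              if (isTRUE(x$synthetic)) ", synthetic" else "",
              as.character(x$seed)))
  invisible(x)
}

#' Build the full random-mixed-noise benchmark
#'
#' Per record and channel: resample to 360 Hz, segment with the 512/256
#' sliding window (subtracting segment means), draw one RMN recipe per
#' segment from the split assigned to its role, and corrupt. Records listed
#' in `test_records` form the test set; both channels of every record are
#' treated as independent single-channel signals. Deterministic under
#' `seed`.
#'
#' @param qtdb_records Named list of records (each a list with `signals` and
#'   `fs`, as returned by [load_record()]).
#' @param noise_records List with two-channel `bw`, `ma`, `em` records
#'   sampled at 360 Hz.
#' @param version Noise split version, `"nv1"` or `"nv2"`.
#' @param seed Integer seed governing all recipe draws.
#' @param test_records Identifiers of test subjects (defaults to the
#'   benchmark's 14 QTDB test records present in `qtdb_records`).
#' @return A list with `train` and `test` pair sets.
#' @export
build_benchmark <- function(qtdb_records, noise_records,
                            version = c("nv1", "nv2"), seed = 1L,
                            test_records = NULL) {
  version <- match.arg(version)
  if (is.null(names(qtdb_records)) || any(!nzchar(names(qtdb_records)))) {
    stop("qtdb_records must be a named list")
  }
  if (is.null(test_records)) {
    test_records <- intersect(qtdb_test_records, names(qtdb_records))
  } else {
    unknown <- setdiff(test_records, names(qtdb_records))
    if (length(unknown)) {
      stop(sprintf("unknown test identifier(s): %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  splits <- make_noise_splits(noise_records$bw, noise_records$ma,
                              noise_records$em, version)
  set.seed(seed)
  segs_of <- function(ids) {
    out <- list()
    for (id in ids) {
      rec <- qtdb_records[[id]]
      m <- as.matrix(rec$signals)
      for (ch in seq_len(ncol(m))) {
        x <- resample_signal(m[, ch], rec$fs, 360)
        out <- c(out, segment_signal(x, source_record = id, channel = ch))
      }
    }
    out
  }
  train_ids <- setdiff(names(qtdb_records), test_records)
  train_pairs <- .make_pairs(segs_of(train_ids), splits$train)
  test_pairs <- .make_pairs(segs_of(test_records), splits$test)
  list(train = .pair_set(train_pairs, version, seed, "train"),
       test = .pair_set(test_pairs, version, seed, "test"))
}

#' Save / load a pair set archive
#'
#' The archive is a single RDS file; a plain-text manifest (`<path>.manifest`)
#' records the role, noise version, seed, synthetic flag and pair count.
#'
#' @param ps A `pair_set`.
#' @param path Output path.
#' @export
save_pair_set <- function(ps, path) {
  stopifnot(inherits(ps, "pair_set"))
  saveRDS(ps, path)
  writeLines(c(sprintf("pairs: %d", length(ps$pairs)),
               sprintf("role: %s", ps$role),
               sprintf("version: %s", ps$version),
               sprintf("seed: %s", as.character(ps$seed)),
               sprintf("synthetic: %s", isTRUE(ps$synthetic))),
             paste0(path, ".manifest"))
  invisible(path)
}

#' @rdname save_pair_set
#' @export
load_pair_set <- function(path) readRDS(path)
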