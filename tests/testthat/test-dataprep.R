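# Record IO, resampling, segmentation, noise splits, RMN recipes and the
# benchmark builder. WFDB fixtures are written at run time in tempdir().

# Minimal format-212 writer (two channels, 12-bit packing) used only to
# exercise the 212 reader against known digital values.
write_wfdb_212 <- function(dig, record, dir, fs = 250, gain = 200) {
  n <- nrow(dig)
  hea <- c(sprintf("%s 2 %g %d", record, fs, n),
           sprintf("%s.dat 212 %g(0)/mV 12 0 %d 0 0 ch1", record, gain, dig[1, 1]),
           sprintf("%s.dat 212 %g(0)/mV 12 0 %d 0 0 ch2", record, gain, dig[1, 2]))
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  flat <- as.vector(t(dig))
  flat[flat < 0] <- flat[flat < 0] + 4096L
  b1 <- flat[c(TRUE, FALSE)] %% 256L
  hi1 <- flat[c(TRUE, FALSE)] %/% 256L
  hi2 <- flat[c(FALSE, TRUE)] %/% 256L
  b2 <- hi1 + 16L * hi2
  b3 <- flat[c(FALSE, TRUE)] %% 256L
  raw <- as.raw(as.vector(rbind(b1, b2, b3)))
  writeBin(raw, file.path(dir, paste0(record, ".dat")))
}

test_that("CSV records load with explicit sampling rate", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(ch1 = sin(1:100), ch2 = cos(1:100)), f,
            row.names = FALSE)
  r <- load_record(f, fs = 360)
  expect_equal(dim(r$signals), c(100L, 2L))
  expect_equal(r$fs, 360)
  expect_error(load_record(f), "fs")
  expect_error(load_record(tempfile(fileext = ".csv"), fs = 360), "not found")
})

test_that("WFDB format 16 round-trips physical units", {
  d <- tempdir()
  # a 15-minute two-channel record at 250 Hz: 2 x 225000 samples
  n <- 15 * 60 * 250
  x <- cbind(sin((1:n) / 10), cos((1:n) / 17)) * 1.5
  write_wfdb(x, "rt16", d, fs = 250, gain = 200)
  r <- load_record(file.path(d, "rt16"))
  expect_equal(r$fs, 250)
  expect_equal(dim(r$signals), c(225000L, 2L))
  expect_lt(max(abs(r$signals - x)), 1 / 200)  # quantization only
  expect_error(load_record(file.path(d, "missing_rec")), "header")
})

test_that("WFDB format 212 unpacks signed 12-bit samples", {
  d <- tempdir()
  set.seed(16)
  dig <- matrix(as.integer(round(runif(2 * 600, -2048, 2047))), ncol = 2)
  write_wfdb_212(dig, "rt212", d, fs = 250, gain = 100)
  r <- load_record(file.path(d, "rt212"))
  expect_equal(r$fs, 250)
  expect_equal(r$signals, dig / 100, ignore_attr = TRUE)
  # a 15-minute two-channel record at 250 Hz yields 2 x 225000 samples
  expect_equal(15 * 60 * 250, 225000)
})

test_that("resampling is band-limited with the exact length contract", {
  x <- rnorm(1000)
  expect_identical(resample_signal(x, 360, 360), x)
  t250 <- (0:224999) / 250
  s <- sin(2 * pi * t250)
  y <- resample_signal(s, 250, 360)
  expect_length(y, 324000L)
  t360 <- (0:323999) / 360
  interior <- 2000:322000
  expect_lt(sqrt(mean((y[interior] - sin(2 * pi * t360[interior]))^2)), 1e-3)
})

test_that("segmentation follows the 512/256 sliding-window contract", {
  expect_length(segment_signal(rnorm(511)), 0L)
  s1 <- segment_signal(rnorm(512))
  expect_length(s1, 1L)
  expect_equal(s1[[1]]$start_index, 0L)
  s3 <- segment_signal(rnorm(1024))
  expect_length(s3, 3L)
  expect_equal(vapply(s3, function(s) s$start_index, numeric(1)),
               c(0, 256, 512))
  expect_length(segment_signal(rnorm(324000)), 1264L)
  segs <- segment_signal(rnorm(2000) + 5)
  for (s in segs) {
    expect_length(s$samples, 512L)
    expect_equal(s$start_index %% 256L, 0L)
    expect_lt(abs(mean(s$samples)), 1e-9)
  }
  # no amplitude normalization beyond mean removal
  xs <- rnorm(512) * 7
  expect_equal(segment_signal(xs)[[1]]$samples, xs - mean(xs))
})

test_that("noise splits assign channels and halves per the split table", {
  n <- 1000L
  mk <- function(base) cbind(base + seq_len(n), -(base + seq_len(n)))
  bw <- mk(0); ma <- mk(10000); em <- mk(20000)
  s1 <- make_noise_splits(bw, ma, em, "nv1")
  # nv1: train channel 1 half a, test channel 2 half b
  expect_equal(s1$train$bw, bw[1:500, 1])
  expect_equal(s1$test$bw, bw[501:1000, 2])
  expect_equal(s1$train$ma, ma[1:500, 1])
  s2 <- make_noise_splits(bw, ma, em, "nv2")
  expect_equal(s2$train$bw, bw[1:500, 2])
  expect_equal(s2$test$bw, bw[501:1000, 1])
  # disjoint in channel and half within each version
  expect_length(intersect(s1$train$em, s1$test$em), 0L)
  expect_error(make_noise_splits(bw[, 1, drop = FALSE], ma, em, "nv1"),
               "2 channels")
})

test_that("RMN recipes are uniform over combinations with scale in [0.2, 2]", {
  split <- structure(list(bw = rnorm(4000), ma = rnorm(4000), em = rnorm(4000),
                          version = "nv1", role = "train"),
                     class = "noise_split")
  set.seed(17)
  recs <- sample_rmn_recipe(split, 80000L)
  combs <- vapply(recs, function(r) r$combination, numeric(1))
  freq <- tabulate(combs, 8) / length(combs)
  se <- sqrt((1 / 8) * (7 / 8) / length(combs))
  expect_true(all(abs(freq - 1 / 8) < 3 * se))
  a <- vapply(recs, function(r) r$scale_a, numeric(1))
  expect_true(all(a >= 0.2 & a <= 2))
  # flags follow the combination table
  for (r in recs[1:200]) {
    expect_equal(r$bw, r$combination %in% c(2, 4, 6, 8))
    expect_equal(r$ma, r$combination %in% c(3, 4, 7, 8))
    expect_equal(r$em, r$combination %in% c(5, 6, 7, 8))
    for (ty in c("bw", "ma", "em")) {
      if (isTRUE(r[[ty]])) {
        expect_true(r$noise_offsets[[ty]] >= 1 &&
                      r$noise_offsets[[ty]] <= 4000 - 512 + 1)
      }
    }
  }
  set.seed(17)
  recs2 <- sample_rmn_recipe(split, 80000L)
  expect_identical(recs, recs2)
})

test_that("corruption is additive with exact peak-ratio scaling", {
  set.seed(18)
  split <- structure(list(bw = rnorm(3000), ma = rnorm(3000), em = rnorm(3000),
                          version = "nv1", role = "train"),
                     class = "noise_split")
  clean <- sin(2 * pi * (1:512) / 100)
  for (i in 1:20) {
    r <- sample_rmn_recipe(split)
    noisy <- corrupt_segment(clean, split, r)
    if (r$combination == 1L) {
      expect_identical(noisy, clean)
    } else {
      ratio <- max(abs(noisy - clean)) / max(abs(clean))
      expect_equal(ratio, r$scale_a, tolerance = 1e-9)
      # purely additive: the residual reconstructs the scaled noise sum
      comb <- numeric(512)
      for (ty in c("bw", "ma", "em")) {
        if (isTRUE(r[[ty]])) {
          o <- r$noise_offsets[[ty]]
          comb <- comb + split[[ty]][o:(o + 511)]
        }
      }
      scaled <- comb * (r$scale_a * max(abs(clean)) / max(abs(comb)))
      expect_lt(max(abs((noisy - clean) - scaled)), 1e-12)
    }
  }
  rc <- sample_rmn_recipe(split)
  while (rc$combination == 1L) rc <- sample_rmn_recipe(split)
  expect_error(corrupt_segment(numeric(512), split, rc), "zero-amplitude")
})

test_that("benchmark builder splits subjects, segments and corrupts deterministically", {
  # one training subject (15 min at 250 Hz, one channel) and one test subject
  set.seed(19)
  tr <- list(signals = matrix(rnorm(225000), ncol = 1), fs = 250)
  te <- list(signals = matrix(rnorm(45000), ncol = 1), fs = 250)
  noise <- list(bw = cbind(rnorm(40000), rnorm(40000)),
                ma = cbind(rnorm(40000), rnorm(40000)),
                em = cbind(rnorm(40000), rnorm(40000)))
  recs <- list(subj1 = tr, sel123 = te)
  bm <- build_benchmark(recs, noise, "nv1", seed = 3)
  expect_length(bm$train$pairs, 1264L)  # resample to 324000 then window
  expect_length(bm$test$pairs, floor((45000 * 36 / 25 - 512) / 256) + 1)
  expect_true(all(vapply(bm$train$pairs, function(p) length(p$noisy), numeric(1)) == 512))
  bm2 <- build_benchmark(recs, noise, "nv1", seed = 3)
  expect_identical(bm$train$pairs, bm2$train$pairs)
  expect_error(build_benchmark(recs, noise, "nv1", seed = 3,
                               test_records = "sel999"), "unknown test identifier")
  expect_length(qtdb_test_records, 14L)
})
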