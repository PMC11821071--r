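# Model assembly: shape contracts, the documented feature-map trace, exact
# parameter accounting, batch independence, gradient flow, checkpoints.

test_that("default model maps 512x1 to 512x1 deterministically", {
  m <- build_fgdae(model_config(q = 1), seed = 1)
  x <- sin(2 * pi * (1:512) / 90)
  y <- fgdae_denoise(m, x)
  expect_length(y, 512L)
  expect_true(all(is.finite(y)))
  expect_identical(y, fgdae_denoise(m, x))
  # zero input: finite output of the right shape
  y0 <- fgdae_denoise(m, numeric(512))
  expect_length(y0, 512L)
  expect_true(all(is.finite(y0)))
})

test_that("q only changes the number of self-ONN kernel banks", {
  m1 <- build_fgdae(model_config(q = 1), seed = 1)
  m2 <- build_fgdae(model_config(q = 2), seed = 1)
  extra <- setdiff(names(m2$params), names(m1$params))
  expect_true(all(grepl("^enc[1-5]\\.g[ig]\\.W2$", extra)))
  expect_length(extra, 10L)
  same <- intersect(names(m1$params), names(m2$params))
  expect_identical(lapply(m1$params[same], dim), lapply(m2$params[same], dim))
})

test_that("encoder/decoder feature-map trace follows the halving/doubling schedule", {
  m <- build_fgdae(model_config(q = 1), seed = 2)
  fw <- fgdae:::.model_forward(m, matrix(rnorm(512), 512, 1), 1L, keep = TRUE)
  enc_L <- vapply(fw$caches$enc, function(cc) cc$L, numeric(1))
  expect_equal(enc_L, c(512, 256, 128, 64, 32))  # block input lengths
  enc_C <- vapply(fw$caches$enc, function(cc) ncol(cc$at$om), numeric(1))
  expect_equal(enc_C, c(16, 32, 64, 64, 1))      # block output channels
  dec_L <- vapply(fw$caches$dec, function(cc) cc$L, numeric(1))
  expect_equal(dec_L, c(32, 64, 128, 256, 512))  # block output lengths
  dec_C <- vapply(fw$caches$dec, function(cc) ncol(cc$at$om), numeric(1))
  expect_equal(dec_C, c(64, 64, 32, 16, 1))
  # encoder block 3: input 128 x 32 -> output 64 x 64
  expect_equal(ncol(fw$caches$enc[[3]]$g$xs), 32)
  expect_equal(fw$caches$enc[[3]]$L / 2, 64)
})

test_that("batched inference equals per-segment inference", {
  m <- build_fgdae(model_config(q = 2), seed = 3)
  set.seed(8)
  X <- matrix(rnorm(512 * 3), 512, 3)
  Yb <- fgdae_denoise(m, X)
  Ys <- vapply(1:3, function(j) fgdae_denoise(m, X[, j]), numeric(512))
  expect_equal(Yb, Ys)
  # array input round-trips shape
  A <- array(t(X), dim = c(3, 512, 1))
  Ya <- fgdae_denoise(m, A)
  expect_equal(dim(Ya), c(3, 512, 1))
  expect_equal(t(matrix(Ya, 3, 512)), Yb)
})

test_that("parameter count reproduces the published totals exactly", {
  counts <- vapply(1:4, function(q) {
    count_trainable_parameters(build_fgdae(model_config(q = q), seed = 1))
  }, numeric(1))
  expect_equal(round(counts[1] / 1000, 2), 263.25)
  expect_equal(round(counts[2] / 1000, 2), 384.50)
  # constant per-order increment
  expect_equal(diff(counts), rep(121248, 3))
  # full decomposition closes exactly
  q <- 2
  expect_equal(counts[q],
               121248 * q + 121248 + 354 + 354 + 354 + 354 + 40 + 19296)
})

test_that("every parameter array receives gradient from the total loss", {
  m <- build_fgdae(model_config(q = 2), seed = 4)
  set.seed(10)
  B <- 4L; L <- 512L
  Xn <- matrix(rnorm(B * L), L, B)
  Xc <- matrix(rnorm(B * L), L, B)
  fw <- fgdae:::.model_forward(m, matrix(Xn, B * L, 1), B, keep = TRUE)
  lg <- fgdae:::.loss_grad_data(Xc, matrix(fw$out, L, B), loss_config())
  gr <- fgdae:::.model_backward(m, fw$caches, matrix(lg$dXhat, B * L, 1), B)
  expect_setequal(names(gr), names(m$params))
  for (nm in names(gr)) {
    expect_gt(max(abs(gr[[nm]])), 0, label = sprintf("gradient norm of %s", nm))
  }
})

test_that("checkpoints round-trip config and weights", {
  m <- build_fgdae(model_config(q = 2), seed = 5)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$params, m$params)
  expect_equal(m2$config$q, 2L)
  x <- rnorm(512)
  expect_equal(fgdae_denoise(m2, x), fgdae_denoise(m, x))
})

test_that("configurations round-trip through the plain-text format", {
  cfg <- model_config(q = 3, input_length = 1024L)
  f <- tempfile(fileext = ".cfg")
  write_model_config(cfg, f)
  cfg2 <- read_model_config(f)
  expect_equal(cfg2$q, 3L)
  expect_equal(cfg2$input_length, 1024L)
  expect_equal(cfg2$encoder_out_channels, cfg$encoder_out_channels)
})

test_that("invalid architecture configurations are rejected", {
  expect_error(model_config(q = 0), "q")
  expect_error(model_config(encoder_out_channels = c(16, 32, 64, 64, 2)),
               "bottleneck")
  expect_error(model_config(input_length = 500), "divisible")
  expect_error(fgdae_denoise(build_fgdae(model_config(), 1), rnorm(100)),
               "length")
})
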