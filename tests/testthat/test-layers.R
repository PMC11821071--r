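# Layer primitives: hand-computed values, brute-force oracle agreement,
# mask ranges, determinism, shape contracts and exact gradients.

test_that("self-ONN forward reproduces hand-computed polynomial values", {
  # K=1, q=2: y = 0.1 + 0.5 x + 0.25 x^2 per sample
  p <- self_onn_params(2, 1, 1, 1,
                       W = list(array(0.5, c(1, 1, 1)), array(0.25, c(1, 1, 1))),
                       b = 0.1)
  expect_equal(as.vector(selfonn1d_forward(c(1, 2), p)), c(0.85, 2.1))

  # identity kernel: center tap one
  w <- array(0, c(9, 1, 1)); w[5, 1, 1] <- 1
  pid <- self_onn_params(1, 9, 1, 1, W = list(w), b = 0)
  x <- rnorm(40)
  expect_equal(as.vector(selfonn1d_forward(x, pid)), x)
})

test_that("higher kernel banks set to zero reduce q=3 to q=1", {
  set.seed(1)
  w1 <- array(rnorm(9 * 2 * 3), c(9, 2, 3))
  z <- array(0, c(9, 2, 3))
  p3 <- self_onn_params(3, 9, 2, 3, W = list(w1, z, z), b = rnorm(3))
  p1 <- self_onn_params(1, 9, 2, 3, W = list(w1), b = p3$b)
  x <- rand_mat(20, 2)
  expect_equal(selfonn1d_forward(x, p3), selfonn1d_forward(x, p1))
})

test_that("self-ONN forward matches the brute-force polynomial oracle", {
  set.seed(42)
  for (case in 1:6) {
    L <- sample(4:32, 1); Cin <- sample(1:4, 1); Cout <- sample(1:4, 1)
    q <- sample(1:4, 1); K <- sample(c(1, 3, 5, 9), 1)
    W <- lapply(seq_len(q), function(n) array(rnorm(K * Cin * Cout) / n,
                                              c(K, Cin, Cout)))
    b <- rnorm(Cout)
    p <- self_onn_params(q, K, Cin, Cout, W = W, b = b)
    x <- rand_mat(L, Cin)
    got <- selfonn1d_forward(x, p)
    want <- oracle_selfonn(x, W, b)
    expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-12)
  }
})

test_that("q=1 self-ONN equals an ordinary convolution", {
  set.seed(7)
  K <- 9; Cin <- 3; Cout <- 2; L <- 25
  W <- list(array(rnorm(K * Cin * Cout), c(K, Cin, Cout)))
  p <- self_onn_params(1, K, Cin, Cout, W = W, b = rnorm(Cout))
  x <- rand_mat(L, Cin)
  got <- selfonn1d_forward(x, p)
  # direct cross-correlation via stats::filter per channel pair
  want <- matrix(rep(p$b, each = L), L, Cout)
  xp <- rbind(matrix(0, 4, Cin), x, matrix(0, 4, Cin))
  for (co in seq_len(Cout)) {
    for (ci in seq_len(Cin)) {
      for (k in seq_len(K)) {
        want[, co] <- want[, co] + W[[1]][k, ci, co] * xp[(1:L) + k - 1, ci]
      }
    }
  }
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("gated self-ONN gating follows the sigmoid-mask formula", {
  set.seed(3)
  mk <- function(Wi, bi, Wg, bg, K = 1) {
    gated_layer_params(self_onn_params(1, K, 1, 1, W = list(array(Wi, c(K, 1, 1))), b = bi),
                       self_onn_params(1, K, 1, 1, W = list(array(Wg, c(K, 1, 1))), b = bg))
  }
  x <- c(2, -4)
  # zero gate path: y = 0.5 * input path
  gp <- mk(1, 0, 0, 0)
  expect_equal(as.vector(gated_selfonn_forward(x, gp)), 0.5 * x)
  # hand case: input W=1,b=0; gate zero -> y = [1, -2]
  expect_equal(as.vector(gated_selfonn_forward(c(2, -4), gp)), c(1, -2))
  # saturated gate: y ~ input path
  gsat <- mk(1, 0, 0, 20)
  y <- as.vector(gated_selfonn_forward(x, gsat))
  expect_lt(max(abs(y - x) / abs(x)), 1e-8)
})

test_that("gated deconvolution doubles length and halves with a zero gate", {
  set.seed(4)
  pi_ <- self_onn_params(1, 9, 1, 2)
  pg <- self_onn_params(1, 9, 1, 2,
                        W = list(array(0, c(9, 1, 2))), b = c(0, 0))
  gp <- gated_layer_params(pi_, pg)
  x <- rnorm(16)
  y <- gated_deconv_forward(x, gp, stride = 2)
  expect_equal(nrow(y), 32L)
  # zero gate -> exactly half of the transpose-conv output
  yi <- fgdae:::.deconv_fwd(matrix(x), fgdae:::.wflat(pi_$W[[1]]), pi_$b,
                            1L, 16L, 2L, 9L)
  expect_equal(y, 0.5 * yi)

  # degenerate K=1, stride 1: input W=2, gate zero, x=[1,3] -> y=[1,3]
  g1 <- gated_layer_params(
    self_onn_params(1, 1, 1, 1, W = list(array(2, c(1, 1, 1))), b = 0),
    self_onn_params(1, 1, 1, 1, W = list(array(0, c(1, 1, 1))), b = 0))
  expect_equal(as.vector(gated_deconv_forward(c(1, 3), g1, stride = 1)),
               c(1, 3))
})

test_that("channel attention mask is sigmoid-sum bounded in (0, 2)", {
  # zero kernel and bias: omega = 1, y = x
  x <- rand_mat(12, 4)
  expect_equal(channel_attention_forward(x, attention_params(c(0, 0, 0), 0)), x)
  # symmetric pooled descriptors: sigma(1) + sigma(-1) = 1 exactly
  a1 <- attention_params(c(0, 1, 0), 0)
  x1 <- matrix(c(1, -3), 2, 1)
  expect_equal(channel_attention_forward(x1, a1), x1)
  # strict range of the mask for random parameters
  set.seed(11)
  for (i in 1:5) {
    ap <- attention_params(rnorm(3), rnorm(1))
    xx <- rand_mat(20, 5)
    y <- channel_attention_forward(xx, ap)
    om <- y / xx
    expect_true(all(om > 0 & om < 2))
  }
})

test_that("residual gate mixes skip content only through the mask", {
  C <- 3; L <- 8
  z <- matrix(0, C, C)
  rp0 <- residual_gate_params(z, numeric(C), z, numeric(C))
  x_in <- rand_mat(L, C); x_res <- rand_mat(L, C)
  expect_equal(residual_gate_forward(x_in, x_res, rp0), 0.5 * x_in)
  # saturating input conv: mask ~ 1 regardless of the skip
  rsat <- residual_gate_params(z, rep(40, C), z, numeric(C))
  expect_lt(max(abs(residual_gate_forward(x_in, x_res, rsat) - x_in)), 1e-8)
  # zero input stays zero: 0 * sigmoid(...) = 0
  r1 <- residual_gate_params(matrix(1), 0, matrix(0), 0)
  expect_equal(residual_gate_forward(matrix(0), matrix(rnorm(1)), r1),
               matrix(0))
  expect_error(residual_gate_forward(rand_mat(4, 2), rand_mat(5, 2), rp0),
               "shape")
})

test_that("instance normalization standardizes each channel over time", {
  set.seed(9)
  x <- rand_mat(50, 3)
  np <- instance_norm_params(rep(1, 3), rep(0, 3), eps = 1e-8)
  y <- instance_norm_forward(x, np)
  expect_lt(max(abs(colMeans(y))), 1e-10)
  expect_lt(max(abs(colMeans(y^2) - 1)), 1e-4)
  # constant channel collapses to beta
  xc <- cbind(rep(2, 50), rnorm(50))
  npc <- instance_norm_params(c(1, 1), c(7, 0), eps = 1e-3)
  expect_lt(max(abs(instance_norm_forward(xc, npc)[, 1] - 7)), 1e-9)
  # x=[0,2], gamma=2, beta=1, eps->0: y=[-1, 3]
  np2 <- instance_norm_params(2, 1, eps = 1e-14)
  expect_equal(as.vector(instance_norm_forward(matrix(c(0, 2)), np2)),
               c(-1, 3), tolerance = 1e-6)
})

test_that("all layer forwards are deterministic at inference and preserve length", {
  set.seed(21)
  for (i in 1:4) {
    L <- 2 * sample(4:16, 1); C <- sample(1:4, 1); Co <- sample(1:4, 1)
    x <- rand_mat(L, C)
    gp <- gated_layer_params(self_onn_params(2, 9, C, Co),
                             self_onn_params(2, 9, C, Co))
    y1 <- gated_selfonn_forward(x, gp); y2 <- gated_selfonn_forward(x, gp)
    expect_identical(y1, y2)
    expect_equal(nrow(y1), L)
    gd <- gated_layer_params(self_onn_params(1, 9, C, Co),
                             self_onn_params(1, 9, C, Co))
    yd <- gated_deconv_forward(x, gd, stride = 2)
    expect_equal(nrow(yd), 2L * L)
    ap <- attention_params()
    expect_identical(channel_attention_forward(x, ap),
                     channel_attention_forward(x, ap))
    expect_equal(dim(channel_attention_forward(x, ap)), c(L, C))
    np <- instance_norm_params(rnorm(C) + 1, rnorm(C))
    expect_equal(dim(instance_norm_forward(x, np)), c(L, C))
  }
})

test_that("analytic backward passes match central finite differences", {
  cfg <- model_config(q = 2, encoder_out_channels = c(2L, 3L, 4L, 4L, 1L),
                      kernel = 5L, input_length = 32L)
  model <- build_fgdae(cfg, seed = 7)
  set.seed(42)
  B <- 2L; L <- 32L
  Xn <- matrix(rnorm(B * L), L, B)
  Xc <- matrix(rnorm(B * L), L, B)
  lc <- loss_config()
  dloss <- function(m) {
    fw <- fgdae:::.model_forward(m, matrix(Xn, B * L, 1), B)
    g <- fgdae:::.loss_grad_data(Xc, matrix(fw$out, L, B), lc)
    g$j_recon + g$j_grad + g$j_morph
  }
  fw <- fgdae:::.model_forward(model, matrix(Xn, B * L, 1), B, keep = TRUE)
  lg <- fgdae:::.loss_grad_data(Xc, matrix(fw$out, L, B), lc)
  gr <- fgdae:::.model_backward(model, fw$caches, matrix(lg$dXhat, B * L, 1), B)
  h <- 1e-6
  set.seed(1)
  for (nm in names(model$params)) {
    k <- sample(length(model$params[[nm]]), 1)
    mp <- model; mp$params[[nm]][k] <- mp$params[[nm]][k] + h
    mm <- model; mm$params[[nm]][k] <- mm$params[[nm]][k] - h
    num <- (dloss(mp) - dloss(mm)) / (2 * h)
    expect_lt(abs(num - gr[[nm]][k]) / max(1e-4, abs(num)), 1e-3,
              label = sprintf("gradient of %s", nm))
  }
})
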