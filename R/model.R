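# Assembly of the fully gated denoising autoencoder: five encoder blocks
# (gated self-ONN -> instance norm -> LeakyReLU -> max pool -> channel
# attention), five decoder blocks (gated transpose conv -> instance norm ->
# LeakyReLU -> channel attention) and four residual gates pairing each
# decoder output with the same-shape encoder skip.

#' Architecture configuration
#'
#' Defaults reproduce the published compact architecture: a 512-sample,
#' single-channel input at 360 Hz, kernel length 9, channel schedule
#' 16/32/64/64/1 down the encoder (mirrored by the decoder as
#' 1/64/64/32/16/1), width-2 max pooling, stride-2 transpose convolutions,
#' kernel-3 channel attention and LeakyReLU slope 0.3. Dropout rates are
#' `0.001 * q` on the gated self-ONN mask and `dropout_base` elsewhere.
#'
#' @param q Self-ONN polynomial order of the encoder (the decoder transpose
#'   convolutions are always order 1).
#' @param encoder_out_channels Five encoder output channel counts; the last
#'   must be 1 (the bottleneck carries a single channel).
#' @param kernel,pool,deconv_stride,attention_kernel Structural constants.
#' @param leaky_slope LeakyReLU negative slope.
#' @param dropout_base Base dropout rate.
#' @param input_length Segment length; must be divisible by 2^5.
#' @param input_channels Number of input channels.
#' @param instance_norm_eps Variance guard of instance normalization.
#' @return A list of class `fgdae_config`.
#' @export
model_config <- function(q = 1L,
                         encoder_out_channels = c(16L, 32L, 64L, 64L, 1L),
                         kernel = 9L, pool = 2L, deconv_stride = 2L,
                         attention_kernel = 3L, leaky_slope = 0.3,
                         dropout_base = 0.001, input_length = 512L,
                         input_channels = 1L, instance_norm_eps = 1e-3) {
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("q must be an integer >= 1")
  if (length(encoder_out_channels) != 5L) {
    stop("encoder_out_channels must list exactly 5 blocks")
  }
  if (encoder_out_channels[5L] != 1L) {
    stop("the bottleneck (encoder block 5) must have 1 channel")
  }
  if (input_length %% 32L != 0L) {
    stop("input_length must be divisible by 2^5")
  }
  if (kernel %% 2L == 0L || attention_kernel != 3L) {
    stop("kernel must be odd and attention_kernel fixed at 3")
  }
  structure(list(q = q,
                 encoder_out_channels = as.integer(encoder_out_channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 deconv_stride = as.integer(deconv_stride),
                 attention_kernel = 3L, leaky_slope = leaky_slope,
                 dropout_base = dropout_base,
                 input_length = as.integer(input_length),
                 input_channels = as.integer(input_channels),
                 instance_norm_eps = instance_norm_eps),
            class = "fgdae_config")
}

.enc_in_channels <- function(cfg) {
  c(cfg$input_channels, cfg$encoder_out_channels[-5L])
}
.dec_out_channels <- function(cfg) {
  c(rev(cfg$encoder_out_channels[1:4]), cfg$input_channels)
}
.dec_in_channels <- function(cfg) {
  c(cfg$encoder_out_channels[5L], .dec_out_channels(cfg)[-5L])
}

.glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Build a fully gated denoising autoencoder
#'
#' Instantiates every learnable array of the architecture (seeded
#' Glorot-uniform kernels, zero biases, unit-gain instance norm) and returns
#' the assembled model.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `fgdae_model`.
#' @export
build_fgdae <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "fgdae_config"))
  set.seed(seed)
  K <- cfg$kernel
  p <- list()
  enc_in <- .enc_in_channels(cfg)
  enc_out <- cfg$encoder_out_channels
  for (k in 1:5) {
    ci <- enc_in[k]; co <- enc_out[k]
    for (path in c("gi", "gg")) {
      for (n in seq_len(cfg$q)) {
        p[[sprintf("enc%d.%s.W%d", k, path, n)]] <-
          .glorot(c(K, ci, co), K * ci, K * co)
      }
      p[[sprintf("enc%d.%s.b", k, path)]] <- numeric(co)
    }
    p[[sprintf("enc%d.in.gamma", k)]] <- rep(1, co)
    p[[sprintf("enc%d.in.beta", k)]] <- numeric(co)
    p[[sprintf("enc%d.at.w", k)]] <- as.vector(.glorot(3L, 3, 1))
    p[[sprintf("enc%d.at.b", k)]] <- 0
  }
  dec_in <- .dec_in_channels(cfg)
  dec_out <- .dec_out_channels(cfg)
  for (k in 1:5) {
    ci <- dec_in[k]; co <- dec_out[k]
    for (path in c("di", "dg")) {
      p[[sprintf("dec%d.%s.W1", k, path)]] <- .glorot(c(K, ci, co), K * ci, K * co)
      p[[sprintf("dec%d.%s.b", k, path)]] <- numeric(co)
    }
    p[[sprintf("dec%d.in.gamma", k)]] <- rep(1, co)
    p[[sprintf("dec%d.in.beta", k)]] <- numeric(co)
    p[[sprintf("dec%d.at.w", k)]] <- as.vector(.glorot(3L, 3, 1))
    p[[sprintf("dec%d.at.b", k)]] <- 0
  }
  for (k in 1:4) {
    C <- dec_out[k]
    p[[sprintf("rg%d.Win", k)]] <- .glorot(c(C, C), C, C)
    p[[sprintf("rg%d.bin", k)]] <- numeric(C)
    p[[sprintf("rg%d.Wres", k)]] <- .glorot(c(C, C), C, C)
    p[[sprintf("rg%d.bres", k)]] <- numeric(C)
  }
  structure(list(config = cfg, params = p, init_seed = seed),
            class = "fgdae_model")
}

#' @export
print.fgdae_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("fgdae model (q = %d)\n", cfg$q))
  cat(sprintf("  input: %d x %d\n", cfg$input_length, cfg$input_channels))
  cat(sprintf("  encoder channels: %s\n",
              paste(cfg$encoder_out_channels, collapse = " -> ")))
  cat(sprintf("  decoder channels: %s\n",
              paste(.dec_out_channels(cfg), collapse = " -> ")))
  cat(sprintf("  trainable parameters: %d (%.2fk)\n",
              count_trainable_parameters(x),
              count_trainable_parameters(x) / 1000))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of learnable scalars: all kernel banks, biases, instance-norm
#' affine parameters, shared attention kernels with biases and residual-gate
#' point convolutions with biases.
#'
#' @param model An `fgdae_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "fgdae_model"))
  sum(vapply(model$params, length, integer(1)))
}

.param_wmats <- function(p, prefix, q, K, ci, co) {
  lapply(seq_len(q), function(n) .wflat(p[[sprintf("%s.W%d", prefix, n)]]))
}

# Full forward pass over a stacked batch, optionally keeping layer caches.
.model_forward <- function(model, x, B, training = FALSE, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  K <- cfg$kernel
  q <- cfg$q
  L <- cfg$input_length
  enc_in <- .enc_in_channels(cfg)
  enc_out <- cfg$encoder_out_channels
  dec_in <- .dec_in_channels(cfg)
  dec_out <- .dec_out_channels(cfg)
  skips <- vector("list", 4L)
  cc <- if (keep) list(enc = vector("list", 5L), dec = vector("list", 5L),
                       rg = vector("list", 4L)) else NULL

  .chk <- function(z, where) {
    if (!all(is.finite(z))) stop(sprintf("non-finite output in %s", where))
    z
  }

  for (k in 1:5) {
    Wi <- .param_wmats(p, sprintf("enc%d.gi", k), q, K, enc_in[k], enc_out[k])
    Wg <- .param_wmats(p, sprintf("enc%d.gg", k), q, K, enc_in[k], enc_out[k])
    g <- .layer_gated_conv_fwd(x, Wi, p[[sprintf("enc%d.gi.b", k)]],
                               Wg, p[[sprintf("enc%d.gg.b", k)]],
                               B, L, K, cfg$dropout_base * q, training)
    nn <- .layer_instnorm_fwd(g$y, p[[sprintf("enc%d.in.gamma", k)]],
                              p[[sprintf("enc%d.in.beta", k)]],
                              cfg$instance_norm_eps, B, L)
    a <- .layer_leaky_fwd(nn$y, cfg$leaky_slope)
    pl <- .layer_maxpool_fwd(a$y, B, L)
    Lp <- L %/% 2L
    at <- .layer_attention_fwd(pl$y, p[[sprintf("enc%d.at.w", k)]],
                               p[[sprintf("enc%d.at.b", k)]], B, Lp,
                               cfg$dropout_base, training)
    x <- .chk(at$y, sprintf("encoder block %d", k))
    if (k <= 4L) skips[[k]] <- x
    if (keep) {
      cc$enc[[k]] <- list(g = g$cache, n = nn$cache, a = a$cache,
                          p = pl$cache, at = at$cache, at_x = pl$y,
                          L = L)
    }
    L <- Lp
  }

  for (k in 1:5) {
    Wi <- .param_wmats(p, sprintf("dec%d.di", k), 1L, K, dec_in[k], dec_out[k])
    Wg <- .param_wmats(p, sprintf("dec%d.dg", k), 1L, K, dec_in[k], dec_out[k])
    g <- .layer_gated_deconv_fwd(x, Wi, p[[sprintf("dec%d.di.b", k)]],
                                 Wg, p[[sprintf("dec%d.dg.b", k)]],
                                 B, L, cfg$deconv_stride, K,
                                 cfg$dropout_base, training)
    L <- L * cfg$deconv_stride
    nn <- .layer_instnorm_fwd(g$y, p[[sprintf("dec%d.in.gamma", k)]],
                              p[[sprintf("dec%d.in.beta", k)]],
                              cfg$instance_norm_eps, B, L)
    a <- .layer_leaky_fwd(nn$y, cfg$leaky_slope)
    at <- .layer_attention_fwd(a$y, p[[sprintf("dec%d.at.w", k)]],
                               p[[sprintf("dec%d.at.b", k)]], B, L,
                               cfg$dropout_base, training)
    x <- at$y
    if (keep) {
      cc$dec[[k]] <- list(g = g$cache, n = nn$cache, a = a$cache,
                          at = at$cache, at_x = a$y, L = L)
    }
    if (k <= 4L) {
      rg <- .layer_resgate_fwd(x, skips[[5L - k]],
                               p[[sprintf("rg%d.Win", k)]],
                               p[[sprintf("rg%d.bin", k)]],
                               p[[sprintf("rg%d.Wres", k)]],
                               p[[sprintf("rg%d.bres", k)]],
                               B, L, cfg$dropout_base, training)
      x <- rg$y
      if (keep) cc$rg[[k]] <- rg$cache
    }
    x <- .chk(x, sprintf("decoder block %d", k))
  }
  list(out = x, caches = cc)
}

# Backward pass matching .model_forward(keep = TRUE). Returns the gradient
# of the loss w.r.t. every parameter array, under the same names.
.model_backward <- function(model, caches, dOut, B) {
  cfg <- model$config
  p <- model$params
  K <- cfg$kernel
  q <- cfg$q
  enc_in <- .enc_in_channels(cfg)
  enc_out <- cfg$encoder_out_channels
  dec_in <- .dec_in_channels(cfg)
  dec_out <- .dec_out_channels(cfg)
  gr <- list()
  dskip <- vector("list", 4L)
  dx <- dOut

  for (k in 5:1) {
    if (k <= 4L) {
      rb <- .layer_resgate_bwd(dx, caches$rg[[k]],
                               p[[sprintf("rg%d.Win", k)]],
                               p[[sprintf("rg%d.Wres", k)]])
      gr[[sprintf("rg%d.Win", k)]] <- rb$dWin
      gr[[sprintf("rg%d.bin", k)]] <- rb$dbin
      gr[[sprintf("rg%d.Wres", k)]] <- rb$dWres
      gr[[sprintf("rg%d.bres", k)]] <- rb$dbres
      dskip[[5L - k]] <- rb$dx_res
      dx <- rb$dx_in
    }
    dc <- caches$dec[[k]]
    ab <- .layer_attention_bwd(dx, dc$at_x, dc$at,
                               p[[sprintf("dec%d.at.w", k)]], B, dc$L)
    gr[[sprintf("dec%d.at.w", k)]] <- ab$dw
    gr[[sprintf("dec%d.at.b", k)]] <- ab$db
    dx <- .layer_leaky_bwd(ab$dx, dc$a, cfg$leaky_slope)
    nb <- .layer_instnorm_bwd(dx, dc$n, p[[sprintf("dec%d.in.gamma", k)]],
                              B, dc$L)
    gr[[sprintf("dec%d.in.gamma", k)]] <- nb$dgamma
    gr[[sprintf("dec%d.in.beta", k)]] <- nb$dbeta
    Wi <- .param_wmats(p, sprintf("dec%d.di", k), 1L, K, dec_in[k], dec_out[k])
    Wg <- .param_wmats(p, sprintf("dec%d.dg", k), 1L, K, dec_in[k], dec_out[k])
    gb <- .layer_gated_deconv_bwd(nb$dx, dc$g, Wi, Wg, B,
                                  dc$L %/% cfg$deconv_stride,
                                  cfg$deconv_stride, K)
    gr[[sprintf("dec%d.di.W1", k)]] <- .wunflat(gb$dWi[[1L]], K, dec_in[k],
                                                dec_out[k])
    gr[[sprintf("dec%d.di.b", k)]] <- gb$dbi
    gr[[sprintf("dec%d.dg.W1", k)]] <- .wunflat(gb$dWg[[1L]], K, dec_in[k],
                                                dec_out[k])
    gr[[sprintf("dec%d.dg.b", k)]] <- gb$dbg
    dx <- gb$dx
  }

  for (k in 5:1) {
    if (k <= 4L) dx <- dx + dskip[[k]]
    ec <- caches$enc[[k]]
    Lp <- ec$L %/% 2L
    ab <- .layer_attention_bwd(dx, ec$at_x, ec$at,
                               p[[sprintf("enc%d.at.w", k)]], B, Lp)
    gr[[sprintf("enc%d.at.w", k)]] <- ab$dw
    gr[[sprintf("enc%d.at.b", k)]] <- ab$db
    dx <- .layer_maxpool_bwd(ab$dx, ec$p, B, ec$L)
    dx <- .layer_leaky_bwd(dx, ec$a, cfg$leaky_slope)
    nb <- .layer_instnorm_bwd(dx, ec$n, p[[sprintf("enc%d.in.gamma", k)]],
                              B, ec$L)
    gr[[sprintf("enc%d.in.gamma", k)]] <- nb$dgamma
    gr[[sprintf("enc%d.in.beta", k)]] <- nb$dbeta
    Wi <- .param_wmats(p, sprintf("enc%d.gi", k), q, K, enc_in[k], enc_out[k])
    Wg <- .param_wmats(p, sprintf("enc%d.gg", k), q, K, enc_in[k], enc_out[k])
    gb <- .layer_gated_conv_bwd(nb$dx, ec$g, Wi, Wg, B, ec$L, K)
    for (n in seq_len(q)) {
      gr[[sprintf("enc%d.gi.W%d", k, n)]] <-
        .wunflat(gb$dWi[[n]], K, enc_in[k], enc_out[k])
      gr[[sprintf("enc%d.gg.W%d", k, n)]] <-
        .wunflat(gb$dWg[[n]], K, enc_in[k], enc_out[k])
    }
    gr[[sprintf("enc%d.gi.b", k)]] <- gb$dbi
    gr[[sprintf("enc%d.gg.b", k)]] <- gb$dbg
    dx <- gb$dx
  }
  gr
}

.as_stacked_batch <- function(x, L) {
  if (is.array(x) && length(dim(x)) == 3L) {
    B <- dim(x)[1L]
    if (dim(x)[2L] != L || dim(x)[3L] != 1L) stop("expected B x L x 1 input")
    m <- t(matrix(x, B, L))
  } else if (is.matrix(x)) {
    if (nrow(x) != L) stop(sprintf("segments must have length %d", L))
    m <- x
    B <- ncol(x)
  } else {
    if (length(x) != L) stop(sprintf("segments must have length %d", L))
    m <- matrix(as.numeric(x), L, 1L)
    B <- 1L
  }
  if (!all(is.finite(m))) stop("non-finite values in input")
  list(stack = matrix(as.vector(m), B * L, 1L), B = B)
}

#' Denoise ECG segments with a model
#'
#' Runs the full encoder/decoder forward pass. Inference-mode calls
#' (`training = FALSE`) are deterministic; all per-sample normalizations make
#' the result of a batched call identical to per-segment calls.
#'
#' @param model An `fgdae_model`.
#' @param x A length-512 vector, a `512 x B` matrix of segment columns, or a
#'   `B x 512 x 1` array.
#' @param training Logical; enables dropout.
#' @param seed Optional seed for the dropout draws.
#' @return Denoised output with the same shape as `x`.
#' @export
fgdae_denoise <- function(model, x, training = FALSE, seed = NULL) {
  stopifnot(inherits(model, "fgdae_model"))
  if (!is.null(seed)) set.seed(seed)
  sb <- .as_stacked_batch(x, model$config$input_length)
  out <- .model_forward(model, sb$stack, sb$B, training = training)$out
  L <- model$config$input_length
  y <- matrix(out, L, sb$B)
  if (is.array(x) && length(dim(x)) == 3L) {
    array(t(y), dim = c(sb$B, L, 1L))
  } else if (is.matrix(x)) y else as.vector(y)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a self-describing archive (RDS) holding the architecture
#' configuration, every named weight array and the initialization seed.
#'
#' @param model An `fgdae_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `fgdae_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fgdae_model"))
  saveRDS(list(config = unclass(model$config), params = model$params,
               init_seed = model$init_seed), path)
  invisible(path)
}

#' Read / write a configuration as a plain key-value text file
#'
#' One `key: value` pair per line; vector values are comma-separated.
#'
#' @param cfg A [model_config()].
#' @param path File path.
#' @return `read_model_config` returns the parsed `fgdae_config`.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fgdae_config"))
  lines <- vapply(names(cfg), function(nm) {
    sprintf("%s: %s", nm, paste(cfg[[nm]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], ":\\s*")
  vals <- lapply(kv, function(p) as.numeric(strsplit(p[2L], ",")[[1L]]))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  do.call(model_config, vals[intersect(names(vals),
                                       names(formals(model_config)))])
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(model_config, obj$config[names(formals(model_config))])
  structure(list(config = cfg, params = obj$params,
                 init_seed = obj$init_seed),
            class = "fgdae_model")
}
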