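# Optimization: Adam with validation-plateau learning-rate halving, early
# stopping, best-checkpoint selection, and the evaluation driver.

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 64, Adam with initial
#' learning rate 1e-3, learning rate halved when the validation loss fails
#' to improve by at least 0.05 for 2 consecutive epochs (floor 1e-10), early
#' stop after 10 epochs without improvement, best-validation checkpoint
#' kept.
#'
#' @param batch_size Segments per optimization step.
#' @param lr0 Initial learning rate.
#' @param lr_factor Multiplicative plateau reduction (0.5 = halving).
#' @param lr_min Learning-rate floor.
#' @param plateau_min_delta Absolute improvement that resets the plateau.
#' @param plateau_patience Stale epochs before a reduction.
#' @param early_stop_patience Stale epochs before stopping.
#' @param max_epochs Epoch cap.
#' @param seed Seed for shuffling, dropout and the validation split.
#' @param validation_fraction Fraction of training pairs held out when no
#'   explicit validation set is given.
#' @export
train_config <- function(batch_size = 64L, lr0 = 1e-3, lr_factor = 0.5,
                         lr_min = 1e-10, plateau_min_delta = 0.05,
                         plateau_patience = 2L, early_stop_patience = 10L,
                         max_epochs = 1e5, seed = 1L,
                         validation_fraction = 0.2) {
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must lie in (0,1)")
  if (lr_min <= 0) stop("lr_min must be positive")
  if (plateau_patience < 1L || early_stop_patience < 1L) {
    stop("patience values must be >= 1")
  }
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_factor = lr_factor, lr_min = lr_min,
                 plateau_min_delta = plateau_min_delta,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = max_epochs, seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "fgdae_train_config")
}

#' Plateau learning-rate schedule
#'
#' Replays the validation-loss history: an epoch is "stale" when it fails to
#' improve on the best loss seen before it by at least `plateau_min_delta`.
#' After every `plateau_patience` consecutive stale epochs the rate is
#' multiplied by `lr_factor`, never dropping below `lr_min`.
#'
#' @param history Validation losses, one per epoch (most recent last).
#' @param current_lr Learning rate in effect.
#' @param tc A [train_config()].
#' @return The learning rate for the next epoch.
#' @export
lr_schedule_step <- function(history, current_lr, tc = train_config()) {
  if (length(history) == 0L) stop("empty validation history")
  best <- Inf
  stale <- 0L
  for (v in history) {
    if (best - v >= tc$plateau_min_delta) stale <- 0L else stale <- stale + 1L
    best <- min(best, v)
  }
  if (stale > 0L && stale %% tc$plateau_patience == 0L) {
    max(current_lr * tc$lr_factor, tc$lr_min)
  } else {
    current_lr
  }
}

.pairs_list <- function(x) {
  if (inherits(x, "pair_set")) x$pairs else x
}

.pairs_matrices <- function(pairs) {
  list(noisy = vapply(pairs, function(p) p$noisy, numeric(length(pairs[[1L]]$noisy))),
       clean = vapply(pairs, function(p) p$clean, numeric(length(pairs[[1L]]$clean))))
}

# Inference over segment columns in bounded-size chunks.
.denoise_matrix <- function(model, X, chunk = 128L) {
  out <- matrix(0, nrow(X), ncol(X))
  j <- 1L
  while (j <= ncol(X)) {
    jj <- min(j + chunk - 1L, ncol(X))
    out[, j:jj] <- fgdae_denoise(model, X[, j:jj, drop = FALSE])
    j <- jj + 1L
  }
  out
}

.val_loss <- function(model, Xn, Xc, lc) {
  Xhat <- .denoise_matrix(model, Xn)
  g <- .loss_grad_data(Xc, Xhat, lc)
  g$j_recon + g$j_grad + g$j_morph + encoder_l1_penalty(model, lc)
}

#' Train a model
#'
#' Adam optimization of the composite loss with per-epoch seeded shuffling,
#' plateau learning-rate halving, early stopping and best-validation
#' checkpointing. The encoder L1 penalty contributes its subgradient
#' `lambda_reg * sign(w)` to every encoder parameter.
#'
#' @param model An `fgdae_model` (updated copy returned; R is value-based).
#' @param train_pairs A `pair_set` or list of (noisy, clean, recipe) pairs.
#' @param val_pairs Optional validation pairs; when `NULL` a seeded random
#'   `validation_fraction` of `train_pairs` is held out.
#' @param lc A [loss_config()].
#' @param tc A [train_config()].
#' @param verbose Emit one progress line per epoch to stderr.
#' @return A list with `history` (per-epoch data frame: epoch, lr, loss
#'   components, validation loss), `best` (the best-validation
#'   `fgdae_model`), `best_val`, `final` (the final-epoch model) and
#'   `stopped_epoch`.
#' @export
train <- function(model, train_pairs, val_pairs = NULL, lc = loss_config(),
                  tc = train_config(), verbose = TRUE) {
  stopifnot(inherits(model, "fgdae_model"))
  pairs <- .pairs_list(train_pairs)
  if (length(pairs) == 0L) stop("empty training set")
  if (is.null(val_pairs)) {
    set.seed(tc$seed)
    nval <- max(1L, round(tc$validation_fraction * length(pairs)))
    vidx <- sample.int(length(pairs), nval)
    vp <- pairs[vidx]
    pairs <- pairs[-vidx]
  } else {
    vp <- .pairs_list(val_pairs)
  }
  if (length(vp) == 0L) stop("empty validation set")
  tr <- .pairs_matrices(pairs)
  va <- .pairs_matrices(vp)
  L <- model$config$input_length
  if (nrow(tr$noisy) != L) stop(sprintf("segments must have length %d", L))

  enc_names <- grep("^enc", names(model$params), value = TRUE)
  mstate <- lapply(model$params, function(w) w * 0)
  vstate <- mstate
  tstep <- 0L
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- tc$lr0
  val_hist <- numeric(0)
  hist_rows <- list()
  best_val <- Inf
  best_params <- model$params
  stale <- 0L
  stopped <- 0L
  N <- ncol(tr$noisy)

  for (epoch in seq_len(tc$max_epochs)) {
    set.seed(tc$seed + epoch)
    ord <- sample.int(N)
    comp <- c(j_recon = 0, j_grad = 0, j_morph = 0, j_reg = 0)
    nb <- 0L
    for (start in seq(1L, N, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, N)]
      B <- length(idx)
      Xn <- tr$noisy[, idx, drop = FALSE]
      Xc <- tr$clean[, idx, drop = FALSE]
      fw <- .model_forward(model, matrix(Xn, B * L, 1L), B,
                           training = TRUE, keep = TRUE)
      Xhat <- matrix(fw$out, L, B)
      lg <- .loss_grad_data(Xc, Xhat, lc)
      if (!all(is.finite(c(lg$j_recon, lg$j_grad, lg$j_morph)))) {
        warning("non-finite loss; aborting with last-good checkpoint")
        stopped <- epoch
        model$params <- best_params
        return(list(history = do.call(rbind, hist_rows), best = model,
                    best_val = best_val, final = model,
                    stopped_epoch = stopped))
      }
      gr <- .model_backward(model, fw$caches,
                            matrix(lg$dXhat, B * L, 1L), B)
      for (nm in enc_names) {
        gr[[nm]] <- gr[[nm]] + lc$lambda_reg * sign(model$params[[nm]])
      }
      j_reg <- encoder_l1_penalty(model, lc)
      tstep <- tstep + 1L
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (nm in names(model$params)) {
        g <- gr[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g * g
        model$params[[nm]] <- model$params[[nm]] -
          lr * corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + aeps)
      }
      comp <- comp + c(lg$j_recon, lg$j_grad, lg$j_morph, j_reg)
      nb <- nb + 1L
    }
    comp <- comp / nb
    vloss <- .val_loss(model, va$noisy, va$clean, lc)
    val_hist <- c(val_hist, vloss)
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, j_recon = comp[["j_recon"]],
      j_grad = comp[["j_grad"]], j_morph = comp[["j_morph"]],
      j_reg = comp[["j_reg"]], train_total = sum(comp), val_loss = vloss)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.3f  val %.3f",
                      epoch, lr, sum(comp), vloss))
    }
    if (vloss < best_val) {
      best_val <- vloss
      best_params <- model$params
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    lr <- lr_schedule_step(val_hist, lr, tc)
    stopped <- epoch
    if (stale >= tc$early_stop_patience) break
  }
  best <- model
  best$params <- best_params
  list(history = do.call(rbind, hist_rows), best = best, best_val = best_val,
       final = model, stopped_epoch = stopped)
}

.denoiser <- function(model) {
  if (inherits(model, "fgdae_model")) {
    function(X) .denoise_matrix(model, X)
  } else if (is.function(model)) {
    function(X) apply(X, 2L, model)
  } else if (is.character(model) && length(model) == 1L) {
    m <- load_checkpoint(model)
    function(X) .denoise_matrix(m, X)
  } else {
    stop("model must be an fgdae_model, a checkpoint path, or a function")
  }
}

#' Evaluate a model (or baseline) on a pair set
#'
#' Denoises every noisy segment, computes the seven metrics against the
#' clean reference, and reports the aggregate mean and standard deviation
#' plus reports stratified by noise amplitude and by noise-type
#' combination.
#'
#' @param model An `fgdae_model`, a checkpoint path, or a function mapping a
#'   noisy segment vector to a denoised vector (e.g. a classical filter).
#' @param test_pairs A `pair_set` or list of pairs.
#' @return A list with `aggregate` (data frame of metric mean/sd),
#'   `by_amplitude`, `by_noise_type`, and `per_pair` (metric matrix).
#' @export
evaluate <- function(model, test_pairs) {
  pairs <- .pairs_list(test_pairs)
  if (length(pairs) == 0L) stop("empty test set")
  mats <- .pairs_matrices(pairs)
  fn <- .denoiser(model)
  Xhat <- fn(mats$noisy)
  if (!all(dim(Xhat) == dim(mats$noisy))) stop("denoiser changed the shape")
  dpairs <- lapply(seq_along(pairs), function(j) {
    list(clean = mats$clean[, j], denoised = Xhat[, j],
         recipe = pairs[[j]]$recipe)
  })
  vals <- t(vapply(dpairs, function(p) {
    unlist(compute_metrics(p$clean, p$denoised)[.metric_names])
  }, numeric(7)))
  colnames(vals) <- .metric_names
  agg <- data.frame(metric = .metric_names,
                    mean = colMeans(vals),
                    sd = apply(vals, 2L, stats::sd))
  rownames(agg) <- NULL
  list(aggregate = agg,
       by_amplitude = stratified_report(dpairs, "amplitude"),
       by_noise_type = stratified_report(dpairs, "noise_type"),
       per_pair = vals)
}
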