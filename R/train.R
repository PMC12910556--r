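# Training: full backward pass, Adam, learning-rate warm-down with
# plateau reduction, early stopping, checkpointing, and batched inference.

#' Training configuration
#'
#' Defaults implement the published schedule: start the learning rate at
#' 0.0212 and decay by 0.9 per epoch so it reaches 0.001 at epoch 30, then
#' hold; halve it when the validation loss fails to improve by at least
#' 0.1% (relative) for 15 epochs; stop early after 30 epochs without
#' improvement.
#'
#' @param lr_initial,lr_target,lr_decay warm-down schedule parameters.
#' @param plateau_patience_epochs,plateau_min_improvement,plateau_factor
#'   plateau-based reduction: patience, relative improvement threshold, and
#'   multiplicative factor.
#' @param early_stop_epochs stop after this many epochs without improvement.
#' @param batch_size minibatch size (cells).
#' @param validation_fraction fraction of cells held out for validation.
#' @param max_epochs hard epoch cap.
#' @param seed seed controlling the split, shuffling, and initialization
#'   downstream.
#' @return object of class `zipo_train_config`.
#' @export
train_config <- function(lr_initial = 0.0212, lr_target = 0.001,
                         lr_decay = 0.9,
                         plateau_patience_epochs = 15L,
                         plateau_min_improvement = 0.001,
                         plateau_factor = 0.5,
                         early_stop_epochs = 30L,
                         batch_size = 128L,
                         validation_fraction = 0.1,
                         max_epochs = 500L,
                         seed = 1L) {
  if (lr_target >= lr_initial) zipo_stop("lr_target must be below lr_initial")
  if (lr_decay <= 0 || lr_decay >= 1) zipo_stop("lr_decay must lie in (0, 1)")
  if (plateau_patience_epochs < 1 || early_stop_epochs < 1) {
    zipo_stop("patience values must be at least 1")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    zipo_stop("validation_fraction must lie in (0, 1)")
  }
  structure(list(
    lr_initial = lr_initial, lr_target = lr_target, lr_decay = lr_decay,
    plateau_patience_epochs = as.integer(plateau_patience_epochs),
    plateau_min_improvement = plateau_min_improvement,
    plateau_factor = plateau_factor,
    early_stop_epochs = as.integer(early_stop_epochs),
    batch_size = as.integer(batch_size),
    validation_fraction = validation_fraction,
    max_epochs = as.integer(max_epochs),
    seed = as.integer(seed)
  ), class = "zipo_train_config")
}

#' Scheduled learning rate at a given epoch
#'
#' `max(lr_target, lr_initial * lr_decay^(epoch - 1))`: geometric warm-down
#' clamped at the target rate (plateau reductions apply on top during
#' training).
#'
#' @param epoch epoch number (1-based).
#' @param cfg a [train_config()].
#' @return positive learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg = train_config()) {
  stopifnot(epoch >= 1)
  pmax(cfg$lr_target, cfg$lr_initial * cfg$lr_decay^(epoch - 1))
}

# ---- backward pass ---------------------------------------------------------

# Assembles parameter gradients for one batch given the forward cache and
# the loss gradients w.r.t. the distribution parameters.
.backward <- function(model, cache, dist, dgrads) {
  spec <- model$spec
  params <- model$params
  grads <- list()
  n <- nrow(cache$V)
  # mean head: log-softmax backward, then linear
  dmu_raw <- dgrads$d_logmu -
    exp(cache$log_mu) * rowSums(dgrads$d_logmu)
  lb <- linear_backward(dmu_raw, cache$V, params[["mu.W"]])
  grads[["mu.W"]] <- lb$dW; grads[["mu.b"]] <- lb$db
  dV <- lb$dx
  # zero-logit head
  lb <- linear_backward(dgrads$d_r, cache$V, params[["z.W"]])
  grads[["z.W"]] <- lb$dW; grads[["z.b"]] <- lb$db
  dV <- dV + lb$dx
  # dispersion head
  if (!is.null(dgrads$d_logtheta)) {
    lb <- linear_backward(dgrads$d_logtheta, cache$V, params[["theta.W"]])
    grads[["theta.W"]] <- lb$dW; grads[["theta.b"]] <- lb$db
    dV <- dV + lb$dx
  }
  # library head: final linear, then blocks in reverse
  dtop <- matrix(dgrads$d_logl, n, 1)
  lb <- linear_backward(dtop, cache$lib_top, params[["libout.W"]])
  grads[["libout.W"]] <- lb$dW; grads[["libout.b"]] <- lb$db
  dh <- lb$dx
  for (i in rev(seq_along(spec$lib_head_sizes))) {
    key <- paste0("lib", i)
    par <- list(W = params[[paste0(key, ".W")]],
                gamma = params[[paste0(key, ".gamma")]],
                beta = params[[paste0(key, ".beta")]])
    bb <- block_backward(dh, cache$lib[[i]], par, spec$activation,
                         spec$batch_norm)
    grads[[paste0(key, ".W")]] <- bb$grads$W
    grads[[paste0(key, ".b")]] <- bb$grads$b
    if (spec$batch_norm) {
      grads[[paste0(key, ".gamma")]] <- bb$grads$gamma
      grads[[paste0(key, ".beta")]] <- bb$grads$beta
    }
    dh <- bb$dx
  }
  dV <- dV + dh
  # covariate columns receive no gradient
  n_latent <- spec$encoder_sizes[length(spec$encoder_sizes)]
  dH <- vector("list", length(spec$encoder_sizes))
  dH[[length(dH)]] <- dV[, seq_len(n_latent), drop = FALSE]
  # encoder blocks in reverse; the latent block fans gradients out to the
  # residual projections
  t_blocks <- length(spec$encoder_sizes)
  for (i in rev(seq_len(t_blocks))) {
    key <- paste0("enc", i)
    par <- list(W = params[[paste0(key, ".W")]],
                gamma = params[[paste0(key, ".gamma")]],
                beta = params[[paste0(key, ".beta")]])
    bb <- block_backward(dH[[i]], cache$encoder[[i]], par, spec$activation,
                         spec$batch_norm)
    grads[[paste0(key, ".W")]] <- bb$grads$W
    grads[[paste0(key, ".b")]] <- bb$grads$b
    if (spec$batch_norm) {
      grads[[paste0(key, ".gamma")]] <- bb$grads$gamma
      grads[[paste0(key, ".beta")]] <- bb$grads$beta
    }
    if (i == t_blocks && length(spec$residual_idx) > 0) {
      for (j in spec$residual_idx) {
        rk <- paste0("res", j)
        h_j <- cache$outs[[j]]
        grads[[paste0(rk, ".W")]] <- crossprod(h_j, bb$dz)
        grads[[paste0(rk, ".b")]] <- colSums(bb$dz)
        dH[[j]] <- (dH[[j]] %||% 0) + bb$dz %*% t(params[[paste0(rk, ".W")]])
      }
    }
    if (i > 1) dH[[i - 1]] <- (dH[[i - 1]] %||% 0) + bb$dx
  }
  # scale-invariant sparsity penalty acts on the first encoding layer
  if (spec$alpha_w > 0) {
    grads[["enc1.W"]] <- grads[["enc1.W"]] +
      .weight_penalty_grad(params[["enc1.W"]], spec$alpha_w)
  }
  grads
}

# Loss + gradients for one batch (raw counts x_batch, encoder input
# x_input_batch). Returns breakdown, grads, updated bn_state.
.batch_step <- function(model, x_batch, x_input_batch, cov_batch) {
  fwd <- zipo_forward(model, x_input_batch, cov_batch, train = TRUE,
                      keep_cache = TRUE)
  breakdown <- total_loss(x_batch, fwd$dist, first_layer_weights(model),
                          model$spec)
  dgrads <- .loss_grads(x_batch, fwd$dist, model$spec)
  cache <- fwd$cache
  cache$log_mu <- fwd$dist$log_mu
  grads <- .backward(model, cache, fwd$dist, dgrads)
  list(breakdown = breakdown, grads = grads, bn_state = fwd$bn_state)
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_update <- function(params, grads, opt, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(grads)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- training loop ---------------------------------------------------------

.check_finite_loss <- function(breakdown, where) {
  terms <- unlist(breakdown)
  bad <- names(terms)[!is.finite(terms)]
  if (length(bad) > 0) {
    zipo_runtime_stop(sprintf("non-finite loss term '%s' %s", bad[1], where))
  }
}

.eval_loss <- function(model, x, x_input, cov_m, idx, batch_size = 512L) {
  terms <- c(nll = 0, zero_penalty = 0, weight_penalty = 0,
             theta_penalty = 0, rate_penalty = 0, total = 0)
  n <- length(idx)
  chunks <- split(idx, ceiling(seq_along(idx) / batch_size))
  for (ch in chunks) {
    fwd <- zipo_forward(model, x_input[ch, , drop = FALSE],
                        if (is.null(cov_m)) NULL else cov_m[ch, , drop = FALSE],
                        train = FALSE)
    b <- total_loss(x[ch, , drop = FALSE], fwd$dist,
                    first_layer_weights(model), model$spec)
    w <- length(ch) / n
    terms <- terms + w * unlist(b)
  }
  as.list(terms)
}

#' Train a model
#'
#' Splits cells into training and validation sets by a seeded permutation,
#' optimizes the [total_loss()] with Adam under the learning-rate schedule
#' of [train_config()], retains the parameters with the best validation
#' loss, and stops early when validation stops improving.
#'
#' @param model a `zipo_model` from [build_model()].
#' @param x a [zipo_counts] (raw counts; the likelihood always sees these).
#' @param covariates optional [covariate_table()].
#' @param cfg a [train_config()].
#' @param preprocess a [preprocess_spec()] applied to the encoder input
#'   copy only. Default: log1p transform, no library normalization — raw
#'   UMI counts saturate sigmoid first-layer units, while log counts keep
#'   library-size information available to the latent space.
#' @param checkpoint_path optional path; the best model is saved there via
#'   [save_checkpoint()].
#' @param log_path optional path for the per-epoch delimited training log.
#' @param verbose print per-epoch progress.
#' @return object of class `zipo_fit`: `model` (best weights),
#'   `best_validation_loss`, `epochs_run`, `history` (data frame with
#'   train/validation loss terms and learning rate per epoch),
#'   `checkpoint_path`.
#' @export
train_zipo <- function(model, x, covariates = NULL, cfg = train_config(),
                       preprocess = preprocess_spec(log_transform = TRUE),
                       checkpoint_path = NULL, log_path = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "zipo_model"), inherits(x, "zipo_counts"))
  xv <- x$values
  n <- nrow(xv)
  if (n < 2) zipo_stop("need at least 2 cells to train")
  x_input <- preprocess_counts(x, preprocess)
  cov_m <- if (is.null(covariates)) NULL else {
    if (inherits(covariates, "zipo_covariates")) covariates$values else as.matrix(covariates)
  }
  set.seed(cfg$seed)
  perm <- sample.int(n)
  n_val <- max(1L, floor(cfg$validation_fraction * n))
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[-seq_len(n_val)]
  opt <- .adam_init(model$params)
  best_val <- Inf
  best_params <- model$params
  best_bn <- model$bn_state
  plateau_scale <- 1
  since_best <- 0L
  since_rel <- 0L
  history <- vector("list", cfg$max_epochs)
  epochs_run <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_at_epoch(epoch, cfg) * plateau_scale
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    acc <- NULL
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      step <- .batch_step(model,
                          xv[idx, , drop = FALSE],
                          x_input[idx, , drop = FALSE],
                          if (is.null(cov_m)) NULL else cov_m[idx, , drop = FALSE])
      .check_finite_loss(step$breakdown,
                         sprintf("at epoch %d, batch %d", epoch, bi))
      model$bn_state <- step$bn_state
      upd <- .adam_update(model$params, step$grads, opt, lr)
      model$params <- upd$params
      opt <- upd$opt
      b <- unlist(step$breakdown)
      acc <- if (is.null(acc)) b else acc + b
    }
    train_terms <- acc / length(batches)
    val_terms <- .eval_loss(model, xv, x_input, cov_m, val_idx)
    .check_finite_loss(val_terms, sprintf("in validation at epoch %d", epoch))
    val_total <- val_terms$total
    epochs_run <- epoch
    history[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_nll = train_terms[["nll"]],
      train_zero_penalty = train_terms[["zero_penalty"]],
      train_weight_penalty = train_terms[["weight_penalty"]],
      train_theta_penalty = train_terms[["theta_penalty"]],
      train_rate_penalty = train_terms[["rate_penalty"]],
      train_total = train_terms[["total"]],
      val_nll = val_terms$nll,
      val_zero_penalty = val_terms$zero_penalty,
      val_weight_penalty = val_terms$weight_penalty,
      val_theta_penalty = val_terms$theta_penalty,
      val_rate_penalty = val_terms$rate_penalty,
      val_total = val_total
    )
    if (verbose) {
      message(sprintf("epoch %3d lr %.5f train %.5g val %.5g",
                      epoch, lr, train_terms[["total"]], val_total))
    }
    rel_improved <- is.finite(best_val) &&
      (best_val - val_total) / abs(best_val) >= cfg$plateau_min_improvement
    if (!is.finite(best_val)) rel_improved <- TRUE
    if (val_total < best_val) {
      best_val <- val_total
      best_params <- model$params
      best_bn <- model$bn_state
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (rel_improved) {
      since_rel <- 0L
    } else {
      since_rel <- since_rel + 1L
      # plateau reduction only applies once the warm-down has finished
      if (lr_at_epoch(epoch, cfg) <= cfg$lr_target &&
          since_rel >= cfg$plateau_patience_epochs) {
        plateau_scale <- plateau_scale * cfg$plateau_factor
        since_rel <- 0L
      }
    }
    if (since_best >= cfg$early_stop_epochs) break
  }

  model$params <- best_params
  model$bn_state <- best_bn
  model$preprocess <- preprocess
  history <- do.call(rbind, history[seq_len(epochs_run)])
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  if (!is.null(log_path)) {
    data.table::fwrite(history, log_path, sep = "\t")
  }
  structure(list(model = model, best_validation_loss = best_val,
                 epochs_run = epochs_run, history = history,
                 checkpoint_path = checkpoint_path),
            class = "zipo_fit")
}

#' @export
print.zipo_fit <- function(x, ...) {
  cat(sprintf("<zipo_fit> %d epoch(s); best validation loss %.6g\n",
              x$epochs_run, x$best_validation_loss))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding the architectural spec, the
#' weights, batch-norm running statistics, the input preprocessing flags,
#' and the build seed.
#'
#' @param model a `zipo_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `zipo_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "zipo_model"))
  saveRDS(list(spec = model$spec, params = model$params,
               bn_state = model$bn_state,
               preprocess = model$preprocess,
               seed = model$seed,
               version = as.character(packageVersion("zipo"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    zipo_stop(sprintf("checkpoint not found: %s", path), class = "zipo_io_error")
  }
  ck <- readRDS(path)
  structure(list(spec = ck$spec, params = ck$params, bn_state = ck$bn_state,
                 preprocess = ck$preprocess, seed = ck$seed),
            class = "zipo_model")
}

#' Predict distribution parameters for all cells
#'
#' Runs the model in evaluation mode (batch-norm running statistics) over
#' all cells in batches, so results are independent of batch size.
#'
#' @param model a trained `zipo_model` (or a fit from [train_zipo()]).
#' @param x a [zipo_counts] with the same genes the model was trained on.
#' @param covariates optional [covariate_table()].
#' @param batch_size inference batch size.
#' @return list with `dist` (`zipo_distribution` over all cells) and
#'   `embedding` (`zipo_embedding`).
#' @export
zipo_impute <- function(model, x, covariates = NULL, batch_size = 256L) {
  if (inherits(model, "zipo_fit")) model <- model$model
  stopifnot(inherits(model, "zipo_model"), inherits(x, "zipo_counts"))
  if (ncol(x$values) != model$spec$n_genes) {
    zipo_stop(sprintf("data has %d genes but the model expects %d",
                      ncol(x$values), model$spec$n_genes))
  }
  x_input <- preprocess_counts(x, model$preprocess %||% preprocess_spec())
  cov_m <- if (is.null(covariates)) NULL else {
    if (inherits(covariates, "zipo_covariates")) covariates$values else as.matrix(covariates)
  }
  n <- nrow(x_input)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  log_l <- numeric(n)
  r <- matrix(0, n, model$spec$n_genes)
  log_mu <- matrix(0, n, model$spec$n_genes)
  log_theta <- if (model$spec$distribution == "zinb") {
    matrix(0, n, model$spec$n_genes)
  } else NULL
  U <- NULL
  for (ch in chunks) {
    fwd <- zipo_forward(model, x_input[ch, , drop = FALSE],
                        if (is.null(cov_m)) NULL else cov_m[ch, , drop = FALSE],
                        train = FALSE)
    log_l[ch] <- fwd$dist$log_l
    r[ch, ] <- fwd$dist$r
    log_mu[ch, ] <- fwd$dist$log_mu
    if (!is.null(log_theta)) log_theta[ch, ] <- fwd$dist$log_theta
    if (is.null(U)) {
      U <- matrix(0, n, ncol(fwd$embedding$U))
    }
    U[ch, ] <- fwd$embedding$U
  }
  rownames(U) <- x$cell_ids
  dist <- structure(list(log_l = log_l, r = r, log_mu = log_mu,
                         log_theta = log_theta),
                    class = "zipo_distribution")
  V <- if (!is.null(cov_m)) cbind(U, cov_m) else U
  list(dist = dist,
       embedding = structure(list(U = U, V = V), class = "zipo_embedding"))
}
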