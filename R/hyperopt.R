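# Hyperparameter search over encoder structures and regularization
# strengths. The sampler is pluggable (random or grid); the objective is
# the best validation total loss of a full training run.

#' Hyperparameter search space
#'
#' Defaults cover the five encoder structures searched in practice, with
#' both regularization strengths sampled log-uniformly on `[0.01, 1]`.
#'
#' @param encoder_structures character vector of structure strings.
#' @param alpha_z_range,alpha_w_range `(low, high)` with `0 < low < high`;
#'   sampled log-uniformly by the random sampler.
#' @param alpha_z_values,alpha_w_values optional explicit grids used by the
#'   grid sampler (default: `alpha_z_values = c(0.01, 0.1, 1)`,
#'   `alpha_w_values = 0.1`).
#' @param n_trials number of trials (default 96).
#' @param seed sampler seed.
#' @return object of class `zipo_search_space`.
#' @export
search_space <- function(encoder_structures = c(
                           "2048-1024-512-256-128", "1024-512-256-128",
                           "1024-512-256-128-64", "512-256-128",
                           "512-256-128-64"
                         ),
                         alpha_z_range = c(0.01, 1),
                         alpha_w_range = c(0.01, 1),
                         alpha_z_values = NULL,
                         alpha_w_values = NULL,
                         n_trials = 96L, seed = 1L) {
  for (rng in list(alpha_z_range, alpha_w_range)) {
    if (length(rng) != 2 || rng[1] <= 0 || rng[1] >= rng[2]) {
      zipo_stop("alpha ranges must satisfy 0 < low < high")
    }
  }
  lapply(encoder_structures, parse_structure)  # validate
  structure(list(
    encoder_structures = encoder_structures,
    alpha_z_range = alpha_z_range, alpha_w_range = alpha_w_range,
    alpha_z_values = alpha_z_values %||% c(0.01, 0.1, 1),
    alpha_w_values = alpha_w_values %||% 0.1,
    n_trials = as.integer(n_trials), seed = as.integer(seed)
  ), class = "zipo_search_space")
}

#' Log-uniform sampling
#'
#' @param n number of draws.
#' @param low,high positive range bounds.
#' @return numeric vector; `log(x)` is uniform on `[log(low), log(high)]`.
#' @export
sample_log_uniform <- function(n, low, high) {
  exp(runif(n, log(low), log(high)))
}

#' Run a hyperparameter search
#'
#' Each trial builds a model with the sampled encoder structure (full
#' residual connections) and sampled `alpha_z` / `alpha_w`, trains it with
#' the supplied configuration, and records the best validation loss.
#' Individual trial failures are recorded (`status = "failed"`), not fatal;
#' the search errors only if every trial fails. Deterministic given the
#' space seed.
#'
#' @param space a [search_space()].
#' @param data a [zipo_counts].
#' @param base_cfg a [train_config()]; its `max_epochs` caps the per-trial
#'   training budget.
#' @param sampler `"random"` (structures uniform, alphas log-uniform) or
#'   `"grid"` (cross product of structures and the explicit alpha grids,
#'   truncated at `n_trials`).
#' @param covariates optional covariates passed to training.
#' @param preprocess encoder-input preprocessing for every trial.
#' @param verbose print per-trial progress.
#' @return list with `trials` (data frame: trial_id, structure, alpha_z,
#'   alpha_w, objective, status, epochs_run) and `best` (the argmin row).
#' @export
run_search <- function(space, data, base_cfg = train_config(),
                       sampler = c("random", "grid"),
                       covariates = NULL,
                       preprocess = preprocess_spec(log_transform = TRUE),
                       verbose = FALSE) {
  stopifnot(inherits(space, "zipo_search_space"), inherits(data, "zipo_counts"))
  sampler <- match.arg(sampler)
  set.seed(space$seed)
  if (sampler == "random") {
    k <- space$n_trials
    configs <- data.frame(
      structure = sample(space$encoder_structures, k, replace = TRUE),
      alpha_z = sample_log_uniform(k, space$alpha_z_range[1],
                                   space$alpha_z_range[2]),
      alpha_w = sample_log_uniform(k, space$alpha_w_range[1],
                                   space$alpha_w_range[2]),
      stringsAsFactors = FALSE
    )
  } else {
    configs <- expand.grid(
      structure = space$encoder_structures,
      alpha_z = space$alpha_z_values,
      alpha_w = space$alpha_w_values,
      stringsAsFactors = FALSE
    )
    configs <- head(configs, space$n_trials)
  }
  trial_seeds <- sample.int(.Machine$integer.max, nrow(configs))
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg_i <- base_cfg
    cfg_i$seed <- trial_seeds[i]
    res <- tryCatch({
      spec <- model_spec(configs$structure[i], n_genes = ncol(data$values),
                         residuals = "full",
                         alpha_z = configs$alpha_z[i],
                         alpha_w = configs$alpha_w[i])
      mdl <- build_model(spec, seed = trial_seeds[i])
      fit <- train_zipo(mdl, data, covariates = covariates, cfg = cfg_i,
                        preprocess = preprocess)
      list(objective = fit$best_validation_loss, status = "ok",
           epochs_run = fit$epochs_run)
    }, error = function(e) {
      list(objective = NA_real_, status = "failed", epochs_run = NA_integer_,
           message = conditionMessage(e))
    })
    if (verbose) {
      message(sprintf("trial %d/%d %s az=%.4g aw=%.4g -> %s (%s)",
                      i, nrow(configs), configs$structure[i],
                      configs$alpha_z[i], configs$alpha_w[i],
                      format(res$objective), res$status))
    }
    rows[[i]] <- data.frame(
      trial_id = i, structure = configs$structure[i],
      alpha_z = configs$alpha_z[i], alpha_w = configs$alpha_w[i],
      max_epochs = cfg_i$max_epochs, seed = trial_seeds[i],
      objective = res$objective, status = res$status,
      epochs_run = res$epochs_run, stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, rows)
  ok <- trials[trials$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) zipo_runtime_stop("all search trials failed")
  best <- ok[which.min(ok$objective), , drop = FALSE]
  list(trials = trials, best = best)
}
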