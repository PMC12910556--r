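# First-layer weight normalization and magnitude pruning.

#' Row-normalize a weight matrix by its maximum absolute entry
#'
#' Each row (neuron) is divided by its maximum absolute weight, so every
#' row attains +/-1 at its largest-magnitude entry; relative weights are
#' what matter because a row rescaling can be absorbed by the following
#' batch-norm layer. All-zero rows are left as zeros with a warning.
#'
#' @param W weight matrix, neurons x genes.
#' @return matrix with entries in `[-1, 1]`.
#' @export
normalize_weights <- function(W) {
  W <- as.matrix(W)
  mx <- apply(abs(W), 1, max)
  zero_rows <- mx == 0
  if (any(zero_rows)) {
    warning(sprintf("%d all-zero row(s) left unnormalized", sum(zero_rows)),
            call. = FALSE)
    mx[zero_rows] <- 1
  }
  W / mx
}

#' Prune small first-layer weights
#'
#' Sets to exactly zero every first-encoding-layer weight whose
#' max-normalized absolute value falls below the threshold `delta`, then
#' (optionally) measures validation NLL and rate MSE before and after on a
#' supplied evaluation set. Pruning is permanent zeroing of the underlying
#' unnormalized weights.
#'
#' @param model a trained `zipo_model`.
#' @param delta threshold in `[0, 1]` on normalized absolute weights.
#' @param eval_data optional [zipo_counts] used to measure the before/after
#'   NLL and rate MSE.
#' @param covariates optional covariates for `eval_data`.
#' @return list with `model` (pruned) and `report` (class
#'   `zipo_prune_report`): `delta`, `fraction_pruned` (share of exactly-zero
#'   weights after pruning), `nll_before`, `nll_after`, `mse_before`,
#'   `mse_after` (NA when no `eval_data`).
#' @export
prune_model <- function(model, delta, eval_data = NULL, covariates = NULL) {
  stopifnot(inherits(model, "zipo_model"))
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta > 1) {
    zipo_stop("delta must be a single value in [0, 1]")
  }
  measure <- function(m) {
    if (is.null(eval_data)) return(c(nll = NA_real_, mse = NA_real_))
    imp <- zipo_impute(m, eval_data, covariates)
    c(nll = -zi_log_likelihood(eval_data, imp$dist),
      mse = rate_mse(eval_data, imp$dist))
  }
  before <- measure(model)
  W_stored <- model$params[["enc1.W"]]  # genes x neurons
  W_norm <- suppressWarnings(normalize_weights(t(W_stored)))
  mask <- t(abs(W_norm) < delta)       # back to genes x neurons
  W_stored[mask] <- 0
  model$params[["enc1.W"]] <- W_stored
  after <- measure(model)
  report <- structure(list(
    delta = delta,
    fraction_pruned = mean(W_stored == 0),
    nll_before = before[["nll"]], nll_after = after[["nll"]],
    mse_before = before[["mse"]], mse_after = after[["mse"]]
  ), class = "zipo_prune_report")
  list(model = model, report = report)
}

#' @export
print.zipo_prune_report <- function(x, ...) {
  cat(sprintf(
    "<zipo_prune_report> delta %.2g: %.1f%% weights zero; NLL %.6g -> %.6g; MSE %.6g -> %.6g\n",
    x$delta, 100 * x$fraction_pruned, x$nll_before, x$nll_after,
    x$mse_before, x$mse_after
  ))
  invisible(x)
}

#' Fraction of normalized first-layer weights below a threshold
#'
#' Sparsity diagnostic: the share of max-normalized absolute first-layer
#' weights smaller than `threshold`.
#'
#' @param model a `zipo_model`.
#' @param threshold normalized magnitude cutoff (default 0.01).
#' @return fraction in `[0, 1]`.
#' @export
small_weight_fraction <- function(model, threshold = 0.01) {
  W_norm <- suppressWarnings(normalize_weights(first_layer_weights(model)))
  mean(abs(W_norm) < threshold)
}
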