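# Evaluation metrics and multi-seed model comparison.

#' Mean squared error of predicted expression rates
#'
#' Mean over all entries of `(l_c * mu_cg - x_cg)^2`: the predicted rate
#' (the model's expected count) against the observed count.
#'
#' @param x counts (matrix or [zipo_counts]).
#' @param dist a `zipo_distribution`.
#' @return scalar MSE.
#' @export
rate_mse <- function(x, dist) {
  x <- .as_count_matrix(x, dist)
  mean((denoised_rates(dist) - x)^2)
}

#' Mean predicted zero-inflation probability
#'
#' @param dist a `zipo_distribution`.
#' @return mean over entries of `sigmoid(r)`.
#' @export
mean_zero_probability <- function(dist) {
  mean(plogis(dist$r))
}

#' Error-bar half-width multiplier
#'
#' `lambda = qnorm(confidence) / sqrt(2)`; at the default 99% confidence
#' this is 1.64 (two decimals). With this multiplier on the standard error
#' of the mean, non-overlapping bars across two models' per-seed losses
#' reject equality at the stated one-sided confidence (equal variances,
#' normality). `divisor = "two"` selects a plain `/2` variant (1.163 at
#' 99%) for comparison.
#'
#' @param confidence confidence level in (0, 1).
#' @param divisor `"sqrt2"` (default) or `"two"`.
#' @return scalar multiplier.
#' @export
error_bar_lambda <- function(confidence = 0.99, divisor = c("sqrt2", "two")) {
  divisor <- match.arg(divisor)
  qnorm(confidence) / if (divisor == "sqrt2") sqrt(2) else 2
}

#' Compare models across random seeds
#'
#' Summarizes per-seed losses per model (mean, standard error of the mean,
#' error-bar half-width `lambda * sem`) and flags each pair of models as
#' separated when their intervals `mean +/- lambda * sem` do not overlap.
#'
#' @param per_model_losses named list; each element a numeric vector of
#'   per-seed losses (length >= 2).
#' @param confidence confidence level (default 0.99).
#' @param divisor passed to [error_bar_lambda()].
#' @return object of class `zipo_comparison`: `summary` data frame (label,
#'   n_seeds, mean, sem, bar_halfwidth, lambda) and `separated`, a logical
#'   matrix over model pairs.
#' @export
compare_models <- function(per_model_losses, confidence = 0.99,
                           divisor = c("sqrt2", "two")) {
  divisor <- match.arg(divisor)
  if (length(per_model_losses) < 1 || is.null(names(per_model_losses))) {
    zipo_stop("per_model_losses must be a named list of numeric vectors")
  }
  lens <- vapply(per_model_losses, length, integer(1))
  if (any(lens < 2)) {
    zipo_stop(sprintf("model '%s' has fewer than 2 seeds",
                      names(per_model_losses)[lens < 2][1]))
  }
  lambda <- error_bar_lambda(confidence, divisor)
  means <- vapply(per_model_losses, mean, numeric(1))
  sems <- vapply(per_model_losses, function(v) sd(v) / sqrt(length(v)),
                 numeric(1))
  summary <- data.frame(
    label = names(per_model_losses), n_seeds = lens,
    mean = means, sem = sems, bar_halfwidth = lambda * sems,
    lambda = lambda, row.names = NULL
  )
  k <- nrow(summary)
  separated <- matrix(FALSE, k, k,
                      dimnames = list(summary$label, summary$label))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      lo_i <- means[i] - lambda * sems[i]; hi_i <- means[i] + lambda * sems[i]
      lo_j <- means[j] - lambda * sems[j]; hi_j <- means[j] + lambda * sems[j]
      separated[i, j] <- hi_i < lo_j || hi_j < lo_i
    }
  }
  structure(list(summary = summary, separated = separated),
            class = "zipo_comparison")
}

#' @export
print.zipo_comparison <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
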