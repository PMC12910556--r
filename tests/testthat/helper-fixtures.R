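# Shared fixtures: small random models/distributions and the naive
# zero-inflated mixture oracle used to cross-check the stable likelihood.

# Naive mixture evaluation log(z 1[x=0] + (1-z) e^f), with f from the
# stock d* densities — independent of the package's stable form. z and
# 1-z are each taken straight from plogis (1 - plogis(r) cancels
# catastrophically near r = 30, which would corrupt the oracle itself).
naive_zi_loglik <- function(x, r, log_m, log_theta = NULL) {
  z <- plogis(r)
  one_minus_z <- plogis(-r)
  f <- if (is.null(log_theta)) {
    dpois(x, exp(log_m), log = TRUE)
  } else {
    dnbinom(x, mu = exp(log_m), size = exp(log_theta), log = TRUE)
  }
  log(z * (x == 0) + one_minus_z * exp(f))
}

# A random distribution object with moderate parameter ranges.
random_dist <- function(n, G, zinb = FALSE, r_range = c(-3, 3),
                        log_l_range = c(0, 3)) {
  log_mu_raw <- matrix(rnorm(n * G), n, G)
  log_mu <- log_mu_raw - log(rowSums(exp(log_mu_raw)))
  structure(list(
    log_l = runif(n, log_l_range[1], log_l_range[2]),
    r = matrix(runif(n * G, r_range[1], r_range[2]), n, G),
    log_mu = log_mu,
    log_theta = if (zinb) matrix(runif(n * G, -1, 3), n, G) else NULL
  ), class = "zipo_distribution")
}

# Counts drawn loosely compatible with a distribution's shape.
random_counts <- function(n, G, lambda = 3, zero_frac = 0.3) {
  x <- matrix(rpois(n * G, lambda), n, G)
  x[runif(n * G) < zero_frac] <- 0L
  x
}

# Small trained-ish model fixture for structural tests (built, not trained).
tiny_model <- function(G = 12, sizes = c(10, 6, 4), seed = 1, ...) {
  build_model(model_spec(sizes, n_genes = G, ...), seed = seed)
}
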