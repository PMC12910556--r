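# Ground-truth count simulator.
#
# Generates cells x genes counts from the same generative family the model
# fits: a low-rank latent factor model pushed through a row softmax gives
# the normalized means mu (rows sum to 1), log-normal library sizes l span
# about two orders of magnitude, and an i.i.d. per-entry zero-inflation
# probability z is drawn on the logit scale. Counts are zero with
# probability z, otherwise Poisson(l*mu) or NB(mean = l*mu, size = theta).

#' Specification of a simulated dataset
#'
#' Defaults describe a realistic small UMI experiment: median library size
#' ~2000 counts with `lib_log_sd = 1.15` so the central 95% of libraries
#' spans roughly 100-fold, mean dropout probability ~0.18
#' (`zero_logit_mean = -1.5`), and a rank-4 latent structure.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_factors latent rank of the generator; must be smaller than both
#'   dimensions.
#' @param lib_log_mean,lib_log_sd natural-log mean/sd of library sizes.
#' @param zero_logit_mean,zero_logit_sd logit-scale mean/sd of per-entry
#'   zero-inflation probabilities.
#' @param dispersion NB dispersion theta; `NULL` (default) simulates
#'   zero-inflated Poisson.
#' @param gene_abundance_sd standard deviation of per-gene baseline
#'   abundance offsets added to the mean logits before the softmax
#'   (default 0). Real per-gene totals span several orders of magnitude;
#'   a value around 2 reproduces that skew, leaving most genes rarely
#'   detected. At 0 all genes are exchangeable.
#' @param gene_logit_offsets optional per-gene offsets added to the zero
#'   logits (length `n_genes`), for gene-structured dropout.
#' @param seed integer RNG seed; the same spec is bit-reproducible.
#' @return object of class `zipo_sim_spec`.
#' @export
sim_spec <- function(n_cells, n_genes, n_factors = 4,
                     lib_log_mean = log(2000), lib_log_sd = 1.15,
                     zero_logit_mean = -1.5, zero_logit_sd = 0.5,
                     dispersion = NULL, gene_abundance_sd = 0,
                     gene_logit_offsets = NULL,
                     seed = 1L) {
  if (n_cells < 1 || n_genes < 1 || n_factors < 1) {
    zipo_stop("n_cells, n_genes and n_factors must be positive")
  }
  if (n_factors >= min(n_cells, n_genes)) {
    zipo_stop("n_factors must be smaller than both n_cells and n_genes")
  }
  if (lib_log_sd <= 0 || zero_logit_sd < 0) {
    zipo_stop("lib_log_sd must be positive and zero_logit_sd non-negative")
  }
  if (!is.null(dispersion) && dispersion <= 0) {
    zipo_stop("dispersion must be positive (or NULL for Poisson)")
  }
  if (!is.null(gene_logit_offsets) && length(gene_logit_offsets) != n_genes) {
    zipo_stop("gene_logit_offsets must have length n_genes")
  }
  if (gene_abundance_sd < 0) {
    zipo_stop("gene_abundance_sd must be non-negative")
  }
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_factors = as.integer(n_factors),
    lib_log_mean = lib_log_mean, lib_log_sd = lib_log_sd,
    zero_logit_mean = zero_logit_mean, zero_logit_sd = zero_logit_sd,
    dispersion = dispersion, gene_abundance_sd = gene_abundance_sd,
    gene_logit_offsets = gene_logit_offsets,
    seed = as.integer(seed)
  ), class = "zipo_sim_spec")
}

#' Draw the generating truth of a simulated dataset
#'
#' @param spec a [sim_spec()].
#' @return object of class `zipo_truth`: `factors` (cells x n_factors),
#'   `loadings` (n_factors x genes), `true_l`, `true_z`, `true_mu` (rows sum
#'   to 1).
#' @export
simulate_truth <- function(spec) {
  stopifnot(inherits(spec, "zipo_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; G <- spec$n_genes; k <- spec$n_factors
  factors <- matrix(rnorm(n * k), n, k)
  loadings <- matrix(rnorm(k * G), k, G)
  eta <- factors %*% loadings
  if (spec$gene_abundance_sd > 0) {
    # gene baseline abundance: a constant "intercept factor" shared by all
    # cells, giving the heavy-tailed per-gene totals seen in real data
    abundance <- rnorm(G, 0, spec$gene_abundance_sd)
    eta <- eta + rep(abundance, each = n)
  }
  true_mu <- exp(eta - .row_logsumexp(eta))
  true_l <- exp(rnorm(n, spec$lib_log_mean, spec$lib_log_sd))
  logits <- matrix(rnorm(n * G, spec$zero_logit_mean, spec$zero_logit_sd), n, G)
  if (!is.null(spec$gene_logit_offsets)) {
    logits <- sweep(logits, 2, spec$gene_logit_offsets, `+`)
  }
  true_z <- plogis(logits)
  structure(list(factors = factors, loadings = loadings,
                 true_l = true_l, true_z = true_z, true_mu = true_mu),
            class = "zipo_truth")
}

#' Draw counts given a fixed generating truth
#'
#' Used directly by Monte Carlo tests that need replicate draws from the
#' same truth; [simulate_counts()] wraps it for one-shot use.
#'
#' @param truth a `zipo_truth`.
#' @param dispersion NB dispersion; `NULL` for Poisson.
#' @param seed RNG seed for this draw.
#' @return a [zipo_counts] (empty cells retained for truth alignment).
#' @export
draw_counts <- function(truth, dispersion = NULL, seed = 1L) {
  stopifnot(inherits(truth, "zipo_truth"))
  set.seed(as.integer(seed))
  n <- length(truth$true_l); G <- ncol(truth$true_mu)
  m <- truth$true_l * truth$true_mu
  x <- if (is.null(dispersion)) {
    matrix(rpois(n * G, lambda = m), n, G)
  } else {
    matrix(rnbinom(n * G, mu = m, size = dispersion), n, G)
  }
  drop_mask <- matrix(runif(n * G) < truth$true_z, n, G)
  x[drop_mask] <- 0L
  zipo_counts(x, drop_empty = FALSE)
}

#' Simulate a zero-inflated count matrix with known ground truth
#'
#' @param spec a [sim_spec()].
#' @return list with elements `counts` (a [zipo_counts]) and `truth`
#'   (a `zipo_truth`). Identical specs give bit-identical output.
#' @export
simulate_counts <- function(spec) {
  truth <- simulate_truth(spec)
  # separate stream for the counts so truth and draw are individually seeded
  counts <- draw_counts(truth, dispersion = spec$dispersion,
                        seed = spec$seed + 1L)
  list(counts = counts, truth = truth)
}

#' Empirical summary of a count matrix
#'
#' @param x a `zipo_counts`.
#' @param probs quantile probabilities for the library-size summary.
#' @return list: `fraction_nonzero` (share of entries > 0),
#'   `library_size_quantiles`, `gene_totals` (per-gene column sums).
#' @export
empirical_summary <- function(x, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(inherits(x, "zipo_counts"))
  list(
    fraction_nonzero = mean(x$values > 0),
    library_size_quantiles = quantile(rowSums(x$values), probs = probs),
    gene_totals = colSums(x$values)
  )
}

.row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
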