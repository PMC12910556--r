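# Model construction and the forward pass.
#
# The encoder is a chain of blocks (linear -> activation -> batch norm)
# with strictly decreasing widths ending in the latent dimension. With
# residual connections enabled, each interior block output (blocks
# 2..t-1) is passed through its own linear projection to the latent width
# and summed into the latent block's pre-activation. Known covariates are
# concatenated to the latent embedding U to form V; four shallow heads map
# V to the distribution parameters: a small block stack plus linear output
# for log library size, one linear layer each for the zero-inflation
# logits, the log-softmax normalized means, and (ZINB) the log dispersions.

#' Parse / format encoder structure strings
#'
#' Structures are written in the `s1-s2-...-sp` convention, e.g.
#' `"2048-1024-512-256-128"`.
#'
#' @param s structure string.
#' @return integer vector of layer sizes.
#' @export
parse_structure <- function(s) {
  parts <- strsplit(gsub("–", "-", s), "-", fixed = TRUE)[[1]]
  sizes <- suppressWarnings(as.integer(parts))
  if (length(sizes) == 0 || any(is.na(sizes)) || any(sizes < 1)) {
    zipo_stop(sprintf("malformed structure string '%s'", s))
  }
  sizes
}

#' @rdname parse_structure
#' @param sizes integer vector of layer sizes.
#' @export
format_structure <- function(sizes) paste(sizes, collapse = "-")

#' Geometric-mean middle layer size
#'
#' For a three-layer encoder the middle width is the geometric mean of the
#' first layer size and the latent dimension, rounded to the nearest
#' integer.
#'
#' @param s_first first-layer size.
#' @param n_latent number of latent variables.
#' @return positive integer.
#' @export
middle_layer_size <- function(s_first, n_latent) {
  stopifnot(s_first >= 1, n_latent >= 1)
  as.integer(round(sqrt(as.numeric(s_first) * as.numeric(n_latent))))
}

#' Architectural specification of a model
#'
#' @param encoder_sizes integer vector of encoder widths; the last entry is
#'   the latent dimension. A warning (not an error) is issued if the sizes
#'   are not strictly decreasing.
#' @param n_genes number of input genes.
#' @param residuals `"none"`, `"full"` (projections from every interior
#'   block, i.e. blocks 2..t-1, into the latent pre-activation), or an
#'   integer vector of block indices in 1..t-1.
#' @param activation `"sigmoid"` (default) or `"gelu"`.
#' @param batch_norm include batch normalization in each block (default
#'   `TRUE`).
#' @param distribution `"zip"` (zero-inflated Poisson) or `"zinb"`.
#' @param n_covariates number of known per-cell covariates appended to the
#'   latent embedding.
#' @param lib_head_sizes hidden widths of the library-size head (default
#'   `c(16, 4)`).
#' @param alpha_z L2 penalty weight on predicted zero probabilities.
#' @param alpha_w weight of the scale-invariant L1/L2 first-layer penalty.
#' @param alpha_theta L2 penalty weight on NB dispersions.
#' @return object of class `zipo_model_spec`.
#' @export
model_spec <- function(encoder_sizes, n_genes,
                       residuals = "none",
                       activation = c("sigmoid", "gelu"),
                       batch_norm = TRUE,
                       distribution = c("zip", "zinb"),
                       n_covariates = 0L,
                       lib_head_sizes = c(16L, 4L),
                       alpha_z = 0.1, alpha_w = 0.1, alpha_theta = 0) {
  activation <- match.arg(activation)
  distribution <- match.arg(distribution)
  if (is.character(encoder_sizes)) encoder_sizes <- parse_structure(encoder_sizes)
  encoder_sizes <- as.integer(encoder_sizes)
  if (length(encoder_sizes) < 1 || any(encoder_sizes < 1)) {
    zipo_stop("encoder_sizes must be positive integers")
  }
  if (length(encoder_sizes) > 1 && any(diff(encoder_sizes) >= 0)) {
    warning("encoder_sizes are not strictly decreasing", call. = FALSE)
  }
  t_blocks <- length(encoder_sizes)
  res_idx <- resolve_residuals(residuals, t_blocks)
  if (alpha_z < 0 || alpha_w < 0 || alpha_theta < 0) {
    zipo_stop("regularization strengths must be non-negative")
  }
  structure(list(
    encoder_sizes = encoder_sizes,
    n_genes = as.integer(n_genes),
    residuals = residuals,
    residual_idx = res_idx,
    activation = activation,
    batch_norm = isTRUE(batch_norm),
    distribution = distribution,
    n_covariates = as.integer(n_covariates),
    lib_head_sizes = as.integer(lib_head_sizes),
    alpha_z = alpha_z, alpha_w = alpha_w, alpha_theta = alpha_theta
  ), class = "zipo_model_spec")
}

resolve_residuals <- function(residuals, t_blocks) {
  if (identical(residuals, "none")) return(integer(0))
  if (identical(residuals, "full")) {
    if (t_blocks < 3) return(integer(0))
    return(seq(2L, t_blocks - 1L))
  }
  idx <- as.integer(residuals)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > t_blocks - 1)) {
    zipo_stop("residual block indices must lie in 1..(number of blocks - 1)")
  }
  sort(unique(idx))
}

#' Build a model with seeded initial weights
#'
#' All linear layers use uniform `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' initialization for weights and biases; batch-norm scale/shift start at
#' 1/0. The same seed reproduces the initial weights bit for bit.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return object of class `zipo_model`: list with `spec`, `params` (flat
#'   named list of weight arrays), `bn_state` (running statistics), `seed`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "zipo_model_spec"))
  set.seed(as.integer(seed))
  sizes <- spec$encoder_sizes
  t_blocks <- length(sizes)
  d_in <- c(spec$n_genes, sizes[-t_blocks])
  params <- list()
  bn_state <- list()
  for (i in seq_len(t_blocks)) {
    key <- paste0("enc", i)
    lin <- init_linear(d_in[i], sizes[i])
    params[[paste0(key, ".W")]] <- lin$W
    params[[paste0(key, ".b")]] <- lin$b
    if (spec$batch_norm) {
      bn <- init_batchnorm(sizes[i])
      params[[paste0(key, ".gamma")]] <- bn$gamma
      params[[paste0(key, ".beta")]] <- bn$beta
      bn_state[[key]] <- list(rm = rep(0, sizes[i]), rv = rep(1, sizes[i]))
    }
  }
  n_latent <- sizes[t_blocks]
  for (j in spec$residual_idx) {
    lin <- init_linear(sizes[j], n_latent)
    params[[paste0("res", j, ".W")]] <- lin$W
    params[[paste0("res", j, ".b")]] <- lin$b
  }
  v_dim <- n_latent + spec$n_covariates
  lib_in <- c(v_dim, spec$lib_head_sizes)
  for (i in seq_along(spec$lib_head_sizes)) {
    key <- paste0("lib", i)
    lin <- init_linear(lib_in[i], spec$lib_head_sizes[i])
    params[[paste0(key, ".W")]] <- lin$W
    params[[paste0(key, ".b")]] <- lin$b
    if (spec$batch_norm) {
      bn <- init_batchnorm(spec$lib_head_sizes[i])
      params[[paste0(key, ".gamma")]] <- bn$gamma
      params[[paste0(key, ".beta")]] <- bn$beta
      bn_state[[key]] <- list(rm = rep(0, spec$lib_head_sizes[i]),
                              rv = rep(1, spec$lib_head_sizes[i]))
    }
  }
  lib_out_in <- if (length(spec$lib_head_sizes) > 0) {
    spec$lib_head_sizes[length(spec$lib_head_sizes)]
  } else {
    v_dim
  }
  lin <- init_linear(lib_out_in, 1L)
  params[["libout.W"]] <- lin$W
  params[["libout.b"]] <- lin$b
  for (head in c("z", "mu", if (spec$distribution == "zinb") "theta")) {
    lin <- init_linear(v_dim, spec$n_genes)
    params[[paste0(head, ".W")]] <- lin$W
    params[[paste0(head, ".b")]] <- lin$b
  }
  structure(list(spec = spec, params = params, bn_state = bn_state,
                 seed = as.integer(seed)),
            class = "zipo_model")
}

#' @export
print.zipo_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<zipo_model> %s genes -> %s (%s, %s); %d residual projection(s); %s parameters\n",
    x$spec$n_genes, format_structure(x$spec$encoder_sizes),
    x$spec$activation, x$spec$distribution,
    length(x$spec$residual_idx), format(n_par, big.mark = ",")
  ))
  invisible(x)
}

#' Forward pass through the model
#'
#' @param model a `zipo_model`.
#' @param x_input numeric matrix, cells x genes (already preprocessed if the
#'   model was trained with preprocessing).
#' @param covariates optional [covariate_table()] aligned with the rows of
#'   `x_input`.
#' @param train `TRUE` uses batch statistics in batch-norm layers (and
#'   updates running statistics in the returned state); `FALSE` (default)
#'   uses running statistics so outputs are independent of batch
#'   composition.
#' @param keep_cache keep intermediate activations for backpropagation
#'   (internal use).
#' @return list with `embedding` (`zipo_embedding`: `U`, `V`), `dist`
#'   (`zipo_distribution`: `log_l`, `r`, `log_mu`, `log_theta`),
#'   `bn_state`, and (if requested) `cache`.
#' @export
zipo_forward <- function(model, x_input, covariates = NULL, train = FALSE,
                         keep_cache = FALSE) {
  spec <- model$spec
  x_input <- as.matrix(x_input)
  if (ncol(x_input) != spec$n_genes) {
    zipo_stop(sprintf("input has %d columns but the model expects %d genes",
                      ncol(x_input), spec$n_genes))
  }
  if (any(!is.finite(x_input))) zipo_stop("non-finite values in model input")
  cov_m <- NULL
  if (spec$n_covariates > 0) {
    if (is.null(covariates)) {
      zipo_stop(sprintf("model expects %d covariates but none were supplied",
                        spec$n_covariates))
    }
    cov_m <- if (inherits(covariates, "zipo_covariates")) covariates$values else as.matrix(covariates)
    if (nrow(cov_m) != nrow(x_input) || ncol(cov_m) != spec$n_covariates) {
      zipo_stop("covariate dimensions do not match the input")
    }
  } else if (!is.null(covariates)) {
    cov_m <- NULL  # model was built without covariates; ignore
  }
  params <- model$params
  bn_state <- model$bn_state
  sizes <- spec$encoder_sizes
  t_blocks <- length(sizes)
  caches <- vector("list", t_blocks)
  outs <- vector("list", t_blocks)
  h <- x_input
  res_pre <- NULL
  res_caches <- list()
  for (i in seq_len(t_blocks)) {
    key <- paste0("enc", i)
    par <- list(W = params[[paste0(key, ".W")]], b = params[[paste0(key, ".b")]],
                gamma = params[[paste0(key, ".gamma")]],
                beta = params[[paste0(key, ".beta")]])
    extra <- NULL
    if (i == t_blocks && length(spec$residual_idx) > 0) {
      extra <- 0
      for (j in spec$residual_idx) {
        rk <- paste0("res", j)
        proj <- linear_forward(outs[[j]], params[[paste0(rk, ".W")]],
                               params[[paste0(rk, ".b")]])
        res_caches[[rk]] <- outs[[j]]
        extra <- extra + proj
      }
    }
    bf <- block_forward(h, par, bn_state[[key]], spec$activation,
                        spec$batch_norm, train, extra_pre = extra)
    outs[[i]] <- bf$out
    caches[[i]] <- bf$cache
    if (spec$batch_norm) bn_state[[key]] <- bf$state
    h <- bf$out
  }
  U <- h
  V <- if (!is.null(cov_m)) cbind(U, cov_m) else U
  # library-size head
  lh <- V
  lib_caches <- vector("list", length(spec$lib_head_sizes))
  for (i in seq_along(spec$lib_head_sizes)) {
    key <- paste0("lib", i)
    par <- list(W = params[[paste0(key, ".W")]], b = params[[paste0(key, ".b")]],
                gamma = params[[paste0(key, ".gamma")]],
                beta = params[[paste0(key, ".beta")]])
    bf <- block_forward(lh, par, bn_state[[key]], spec$activation,
                        spec$batch_norm, train)
    lib_caches[[i]] <- bf$cache
    if (spec$batch_norm) bn_state[[key]] <- bf$state
    lh <- bf$out
  }
  log_l <- drop(linear_forward(lh, params[["libout.W"]], params[["libout.b"]]))
  r <- linear_forward(V, params[["z.W"]], params[["z.b"]])
  mu_raw <- linear_forward(V, params[["mu.W"]], params[["mu.b"]])
  log_mu <- mu_raw - .row_logsumexp(mu_raw)
  log_theta <- NULL
  if (spec$distribution == "zinb") {
    log_theta <- linear_forward(V, params[["theta.W"]], params[["theta.b"]])
  }
  embedding <- structure(list(U = U, V = V), class = "zipo_embedding")
  dist <- structure(list(log_l = log_l, r = r, log_mu = log_mu,
                         log_theta = log_theta),
                    class = "zipo_distribution")
  out <- list(embedding = embedding, dist = dist, bn_state = bn_state)
  if (keep_cache) {
    out$cache <- list(encoder = caches, outs = outs, res_inputs = res_caches,
                      lib = lib_caches, lib_top = lh, V = V, U = U,
                      mu_raw = mu_raw, log_mu = log_mu, cov = cov_m)
  }
  out
}

#' First-layer weight matrix in neurons x genes orientation
#' @param model a `zipo_model`.
#' @return matrix with one row per first-layer neuron.
#' @export
first_layer_weights <- function(model) {
  t(model$params[["enc1.W"]])
}
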