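test_that("Poisson log-pmf matches the closed form and dpois", {
  expect_equal(poisson_log_pmf(0, log(1)), -1)
  expect_equal(poisson_log_pmf(1, log(1)), -1)
  expect_equal(poisson_log_pmf(3, log(2.5)), dpois(3, 2.5, log = TRUE))
  set.seed(2)
  x <- rpois(50, 4)
  lm <- runif(50, -2, 3)
  expect_equal(poisson_log_pmf(x, lm), dpois(x, exp(lm), log = TRUE),
               tolerance = 1e-12)
  expect_error(poisson_log_pmf(1.5, 0), class = "zipo_validation_error")
})

test_that("NB log-pmf matches dnbinom, its zero closed form, and the Poisson limit", {
  set.seed(3)
  x <- rpois(50, 3)
  lm <- runif(50, -2, 3)
  lt <- runif(50, -1, 3)
  expect_equal(nb_log_pmf(x, lm, lt),
               dnbinom(x, mu = exp(lm), size = exp(lt), log = TRUE),
               tolerance = 1e-10)
  # x = 0: theta * log(theta / (theta + m))
  th <- exp(lt); m <- exp(lm)
  expect_equal(nb_log_pmf(0 * x, lm, lt), th * log(th / (th + m)),
               tolerance = 1e-10)
  # theta = 1 is geometric: P(x) = (m/(1+m))^x / (1+m); at m=1, x=2 -> 1/8
  expect_equal(nb_log_pmf(2, log(1), log(1)), log(1 / 8))
  # Poisson limit
  expect_equal(nb_log_pmf(x, lm, rep(20, 50)), poisson_log_pmf(x, lm),
               tolerance = 1e-4)
})

test_that("stable zero-inflated likelihood matches the naive mixture", {
  # no-inflation limit: reduces to the plain count likelihood
  n <- 4; G <- 6
  set.seed(5)
  x <- random_counts(n, G)
  dist <- random_dist(n, G)
  dist$r <- matrix(-40, n, G)
  plain <- sum(dpois(x, exp(dist$log_l + dist$log_mu), log = TRUE)) / n
  expect_equal(zi_log_likelihood(x, dist), plain, tolerance = 1e-10)

  # single-entry mixture: log(0.5 + 0.5 e^-1)
  d1 <- structure(list(log_l = 0, r = matrix(0, 1, 1),
                       log_mu = matrix(0, 1, 1), log_theta = NULL),
                  class = "zipo_distribution")
  expect_equal(zi_log_likelihood(matrix(0L, 1, 1), d1),
               log(0.5 + 0.5 * exp(-1)), tolerance = 1e-12)

  # random instances, ZIP and ZINB, against the naive oracle
  for (zinb in c(FALSE, TRUE)) {
    set.seed(6 + zinb)
    x <- random_counts(6, 5)
    dist <- random_dist(6, 5, zinb = zinb)
    log_m <- dist$log_l + dist$log_mu
    naive <- sum(naive_zi_loglik(x, dist$r, log_m, dist$log_theta)) / 6
    expect_equal(zi_log_likelihood(x, dist), naive, tolerance = 1e-8)
  }
})

test_that("stable form stays finite where the naive mixture underflows", {
  # positive counts with an extremely small rate: e^f underflows to 0 in the
  # naive mixture, giving log(0) = -Inf; the stable form is exact
  x <- matrix(c(200L, 300L), 1, 2)
  dist <- structure(list(
    log_l = 0, r = matrix(c(0, -5), 1, 2),
    log_mu = matrix(log(c(1e-3, 1e-4)), 1, 2), log_theta = NULL
  ), class = "zipo_distribution")
  log_m <- dist$log_l + dist$log_mu
  naive <- naive_zi_loglik(x, dist$r, log_m)
  expect_true(any(!is.finite(naive)))
  stable <- zi_log_likelihood(x, dist)
  expect_true(is.finite(stable))
  # exact value: log(1-z) + f per entry
  exact <- sum(log(1 - plogis(dist$r)) + dpois(x, exp(log_m), log = TRUE))
  expect_equal(stable, exact, tolerance = 1e-8)
})

test_that("scale-invariant penalty has the advertised values, bounds and invariance", {
  expect_equal(scale_invariant_weight_penalty(matrix(0.7, 5, 9)), 1)
  one_hot <- diag(3) %x% matrix(1, 1, 1)            # 3 x 3 identity
  one_hot <- cbind(one_hot, matrix(0, 3, 97))       # G = 100, single nonzero
  expect_equal(scale_invariant_weight_penalty(one_hot), 0.1)

  set.seed(7)
  W <- matrix(rnorm(6 * 40), 6, 40)
  p0 <- scale_invariant_weight_penalty(W)
  W2 <- W; W2[3, ] <- W2[3, ] * 1e6
  expect_lt(abs(scale_invariant_weight_penalty(W2) - p0) / p0, 1e-12)

  # per-row terms live in [1/sqrt(G), 1]
  G <- ncol(W)
  row_terms <- rowMeans(abs(W)) / sqrt(rowMeans(W^2))
  expect_true(all(row_terms >= 1 / sqrt(G) - 1e-12 & row_terms <= 1 + 1e-12))

  # appending zero columns pushes row terms down (sparsity-rewarding)
  W3 <- cbind(W, matrix(0, 6, 40))
  expect_lt(scale_invariant_weight_penalty(W3),
            scale_invariant_weight_penalty(W))

  expect_warning(p <- scale_invariant_weight_penalty(rbind(rep(0, 5), rep(1, 5))),
                 "all-zero")
  expect_equal(p, 0.5)
})

test_that("total loss decomposes additively, term by term", {
  set.seed(9)
  n <- 2; G <- 3
  x <- matrix(c(0L, 2L, 1L, 0L, 4L, 0L), n, G)
  dist <- random_dist(n, G, zinb = TRUE, r_range = c(-2, 2))
  W <- matrix(rnorm(4 * G), 4, G)
  spec <- model_spec(c(4, 2), n_genes = G, distribution = "zinb",
                     alpha_z = 0.3, alpha_w = 0.2, alpha_theta = 0.05)
  bl <- total_loss(x, dist, W, spec)

  # independent term-by-term recomputation
  log_m <- dist$log_l + dist$log_mu
  nll <- -sum(naive_zi_loglik(x, dist$r, log_m, dist$log_theta)) / n
  expect_equal(bl$nll, nll, tolerance = 1e-9)
  expect_equal(bl$zero_penalty, 0.3 * mean(plogis(dist$r)^2), tolerance = 1e-12)
  expect_equal(bl$weight_penalty,
               0.2 * mean(rowMeans(abs(W)) / sqrt(rowMeans(W^2))),
               tolerance = 1e-12)
  expect_equal(bl$theta_penalty, 0.05 * mean(exp(dist$log_theta)^2),
               tolerance = 1e-12)
  expect_equal(bl$rate_penalty,
               0.1 * mean((exp(dist$log_l) - rowSums(x))^2), tolerance = 1e-9)
  expect_equal(bl$total,
               bl$nll + bl$zero_penalty + bl$weight_penalty +
                 bl$theta_penalty + bl$rate_penalty, tolerance = 1e-9)

  # all-zero alphas under ZIP: total is exactly the NLL
  spec0 <- model_spec(c(4, 2), n_genes = G, alpha_z = 0, alpha_w = 0)
  dist0 <- dist; dist0$log_theta <- NULL
  bl0 <- total_loss(x, dist0, W, spec0)
  expect_identical(bl0$total, bl0$nll)
  expect_identical(bl0$zero_penalty, 0)
})

test_that("perfect rates never worsen the positive-entry likelihood term", {
  set.seed(10)
  n <- 5; G <- 8
  x <- random_counts(n, G, lambda = 5)
  dist <- random_dist(n, G)
  pos <- x > 0
  f_model <- poisson_log_pmf(x[pos], (dist$log_l + dist$log_mu)[pos])
  f_perfect <- poisson_log_pmf(x[pos], log(x[pos]))
  expect_true(all(f_perfect >= f_model - 1e-12))
})

test_that("analytic gradients agree with finite differences on a full model", {
  set.seed(42)
  n <- 6; G <- 7
  x <- random_counts(n, G, lambda = 3)
  xin <- x * 1.0
  covs <- matrix(rnorm(n * 2), n, 2)
  spec <- model_spec(c(6, 5, 4), n_genes = G, residuals = "full",
                     distribution = "zinb", n_covariates = 2,
                     lib_head_sizes = 3, alpha_z = 0.3, alpha_w = 0.2,
                     alpha_theta = 0.05)
  m <- build_model(spec, seed = 7)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    fwd <- zipo_forward(m2, xin, covs, train = TRUE)
    total_loss(x, fwd$dist, first_layer_weights(m2), spec)$total
  }
  step <- zipo:::.batch_step(m, x, xin, covs)
  eps <- 1e-6
  for (k in names(step$grads)) {
    g <- step$grads[[k]]
    idx <- seq_along(g)
    if (length(idx) > 8) idx <- sample(idx, 8)
    for (i in idx) {
      p1 <- m$params; p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- m$params; p2[[k]][i] <- p2[[k]][i] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-8), 1e-4)
    }
  }
})
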