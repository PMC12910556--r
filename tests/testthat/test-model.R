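test_that("geometric-mean middle layer size rounds to nearest integer", {
  expect_identical(middle_layer_size(4096, 64), 512L)
  expect_identical(middle_layer_size(64, 64), 64L)
  expect_identical(middle_layer_size(2048, 64), 362L)
})

test_that("structure strings parse and format in the s1-s2-... convention", {
  expect_identical(parse_structure("2048-1024-512-256-128"),
                   c(2048L, 1024L, 512L, 256L, 128L))
  expect_identical(format_structure(c(512, 256, 128)), "512-256-128")
  expect_error(parse_structure("512-abc"), "malformed",
               class = "zipo_validation_error")
})

test_that("model spec warns on non-decreasing sizes and checks residuals", {
  expect_warning(model_spec(c(128, 64, 128), n_genes = 10),
                 "strictly decreasing")
  expect_error(model_spec(c(64, 32), n_genes = 10, residuals = c(5)),
               class = "zipo_validation_error")
})

test_that("full residuals project interior block outputs into the latent layer", {
  spec <- model_spec(c(64, 48, 32, 16, 8), n_genes = 20, residuals = "full")
  expect_identical(spec$residual_idx, 2:4)
  m <- build_model(spec, seed = 1)
  expect_setequal(grep("^res", names(m$params), value = TRUE),
                  c("res2.W", "res2.b", "res3.W", "res3.b", "res4.W", "res4.b"))
  expect_identical(dim(m$params[["res2.W"]]), c(48L, 8L))

  # two-layer model: no interior blocks, "full" means none
  spec2 <- model_spec(c(16, 8), n_genes = 20, residuals = "full")
  expect_length(spec2$residual_idx, 0)
})

test_that("z head parameter count matches a dense V -> genes layer", {
  spec <- model_spec(c(32, 8), n_genes = 100, n_covariates = 2)
  m <- build_model(spec, seed = 2)
  # V has width latent 8 + 2 covariates = 10
  expect_identical(length(m$params[["z.W"]]) + length(m$params[["z.b"]]),
                   10L * 100L + 100L)
})

test_that("seeded builds are bit-reproducible", {
  spec <- model_spec(c(24, 12, 6), n_genes = 15, residuals = "full",
                     distribution = "zinb")
  a <- build_model(spec, seed = 99)
  b <- build_model(spec, seed = 99)
  expect_identical(a$params, b$params)
  c <- build_model(spec, seed = 100)
  expect_false(identical(a$params, c$params))
})

test_that("mean-head rows are exact probability vectors for random models", {
  set.seed(31)
  for (i in 1:100) {
    G <- sample(5:20, 1)
    sizes <- sort(sample(3:16, 2), decreasing = TRUE)
    m <- build_model(model_spec(sizes, n_genes = G), seed = i)
    x <- matrix(rexp(4 * G), 4, G)
    fwd <- zipo_forward(m, x)
    expect_true(all(abs(rowSums(exp(fwd$dist$log_mu)) - 1) < 1e-6))
  }
})

test_that("without residuals the forward pass equals straight-line composition", {
  G <- 4
  spec <- model_spec(c(3, 2), n_genes = G, residuals = "none")
  m <- build_model(spec, seed = 5)
  x <- matrix(runif(6 * G), 6, G)
  fwd <- zipo_forward(m, x, train = FALSE)

  # independent straight-line reimplementation (eval-mode batch norm)
  p <- m$params
  st <- m$bn_state
  blk <- function(h, key) {
    z <- h %*% p[[paste0(key, ".W")]] +
      matrix(p[[paste0(key, ".b")]], nrow(h), length(p[[paste0(key, ".b")]]),
             byrow = TRUE)
    a <- 1 / (1 + exp(-z))
    xhat <- sweep(sweep(a, 2, st[[key]]$rm), 2,
                  sqrt(st[[key]]$rv + 1e-5), "/")
    sweep(sweep(xhat, 2, p[[paste0(key, ".gamma")]], "*"), 2,
          p[[paste0(key, ".beta")]], "+")
  }
  u <- blk(blk(x, "enc1"), "enc2")
  expect_equal(unname(fwd$embedding$U), unname(u), tolerance = 1e-10)
  # heads are plain linear maps of V = U
  r <- u %*% p[["z.W"]] + matrix(p[["z.b"]], 6, G, byrow = TRUE)
  expect_equal(unname(fwd$dist$r), unname(r), tolerance = 1e-10)
})

test_that("evaluation mode is batch-size invariant and row-deterministic", {
  G <- 10
  m <- tiny_model(G = G, sizes = c(8, 4), seed = 3)
  set.seed(8)
  x <- matrix(rexp(64 * G), 64, G)
  fwd_all <- zipo_forward(m, x)
  fwd_one <- zipo_forward(m, x[1, , drop = FALSE])
  expect_equal(fwd_all$dist$log_mu[1, ], fwd_one$dist$log_mu[1, ],
               tolerance = 1e-6)
  expect_equal(fwd_all$dist$log_l[1], fwd_one$dist$log_l[1], tolerance = 1e-6)

  # duplicated cell gives identical rows
  x2 <- rbind(x[5, ], x[5, ])
  fwd_dup <- zipo_forward(m, x2)
  expect_identical(fwd_dup$dist$r[1, ], fwd_dup$dist$r[2, ])
})

test_that("forward validates shapes and finiteness", {
  m <- tiny_model(G = 6, sizes = c(4, 2))
  expect_error(zipo_forward(m, matrix(1, 2, 5)), "expects 6",
               class = "zipo_validation_error")
  expect_error(zipo_forward(m, matrix(c(1, NA), 1, 6)[rep(1, 2), ]),
               "non-finite", class = "zipo_validation_error")
  mc <- build_model(model_spec(c(4, 2), n_genes = 6, n_covariates = 1), seed = 1)
  expect_error(zipo_forward(mc, matrix(1, 2, 6)), "covariates",
               class = "zipo_validation_error")
})
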