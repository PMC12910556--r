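test_that("count container validates entries, identifiers and library sizes", {
  x <- zipo_counts(matrix(c(0, 2, 5, 1, 0, 3), 3, 2))
  expect_equal(unname(library_sizes(x)), c(1, 2, 8))

  expect_error(zipo_counts(matrix(c(1, -1, 0, 2), 2, 2)),
               "cell 2, gene 1", class = "zipo_validation_error")
  expect_error(zipo_counts(matrix(c(1, 1.5, 0, 2), 2, 2)),
               class = "zipo_validation_error")
  expect_error(zipo_counts(matrix(1, 2, 2), cell_ids = c("a", "a"),
                           gene_ids = c("g1", "g2")),
               "duplicate cell", class = "zipo_validation_error")
  expect_warning(
    x0 <- zipo_counts(rbind(c(1, 2), c(0, 0))),
    "zero library size"
  )
  expect_equal(nrow(x0$values), 1L)
})

test_that("dense and mtx round-trips preserve values and identifiers", {
  set.seed(11)
  v <- matrix(rpois(50 * 100, 0.4), 50, 100)
  v[1, ] <- v[1, ] + 1  # keep every cell nonzero
  diag_fill <- sample(100, 50, replace = TRUE)
  v[cbind(1:50, diag_fill)] <- v[cbind(1:50, diag_fill)] + 1
  x <- zipo_counts(v, cell_ids = sprintf("c%02d", 1:50),
                   gene_ids = sprintf("g%03d", 1:100))

  tsv <- tempfile(fileext = ".tsv")
  write_counts(x, tsv)
  y <- read_counts(tsv)
  expect_equal(y$values, x$values)
  expect_identical(y$cell_ids, x$cell_ids)
  expect_identical(y$gene_ids, x$gene_ids)

  mtx <- tempfile(fileext = ".mtx")
  write_counts(x, mtx)
  z <- read_counts(mtx)
  expect_equal(z$values, x$values)
  expect_identical(z$gene_ids, x$gene_ids)

  csv <- tempfile(fileext = ".csv")
  write_counts(x, csv, format = "dense", sep = ",")
  w <- read_counts(csv)  # separator sniffed
  expect_equal(w$values, x$values)
})

test_that("empty mtx matrix warns about zero library sizes on load", {
  mtx <- tempfile(fileext = ".mtx")
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(5, 4))
  Matrix::writeMM(m, mtx)
  writeLines(paste0("g", 1:5), paste0(mtx, ".rowids"))
  writeLines(paste0("c", 1:4), paste0(mtx, ".colids"))
  expect_warning(x <- read_counts(mtx), "4 cell")
  expect_equal(nrow(x$values), 0L)
})

test_that("missing files raise I/O errors", {
  expect_error(read_counts(tempfile()), "not found", class = "zipo_io_error")
  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(diag(3), sparse = TRUE), mtx)
  expect_error(read_counts(mtx), "sidecar", class = "zipo_io_error")
})

test_that("preprocessing composes normalize-then-log as documented", {
  x <- zipo_counts(matrix(c(2, 2, 4), 1, 3), drop_empty = FALSE)
  expect_equal(
    as.numeric(preprocess_counts(x, preprocess_spec(library_normalize = TRUE))),
    c(0.25, 0.25, 0.5)
  )
  y <- zipo_counts(matrix(c(0, 0, round(exp(1)) - 1), 1, 3), drop_empty = FALSE)
  expect_equal(
    as.numeric(preprocess_counts(y, preprocess_spec(log_transform = TRUE))),
    log1p(c(0, 0, round(exp(1)) - 1))
  )
  z <- zipo_counts(matrix(c(1, 3), 1, 2), drop_empty = FALSE)
  expect_equal(
    as.numeric(preprocess_counts(z, preprocess_spec(TRUE, TRUE))),
    c(log(1.25), log(1.75))
  )
  # both flags off: identity up to numeric cast
  expect_identical(preprocess_counts(z, preprocess_spec()),
                   z$values * 1.0)
  empty <- zipo_counts(rbind(c(1, 1), c(0, 0)), drop_empty = FALSE)
  expect_error(
    preprocess_counts(empty, preprocess_spec(library_normalize = TRUE)),
    "zero library", class = "zipo_validation_error"
  )
})

test_that("denoised export writes l * mu with identifiers preserved", {
  set.seed(4)
  n <- 5; G <- 8
  x <- zipo_counts(random_counts(n, G) + 1)
  dist <- random_dist(n, G)
  path <- tempfile(fileext = ".tsv")
  export_denoised(x, dist, path)
  m <- read_dense <- zipo:::read_dense_matrix(path)
  expect_equal(unname(m), unname(exp(dist$log_l + dist$log_mu)),
               tolerance = 1e-12)
  expect_identical(rownames(m), x$cell_ids)
  # mu rows sum to 1 => denoised row sums equal predicted library sizes
  expect_equal(unname(rowSums(m)), unname(exp(dist$log_l)), tolerance = 1e-8)
  z <- zipo:::read_dense_matrix(paste0(path, ".zero_prob"))
  expect_equal(unname(z), unname(plogis(dist$r)), tolerance = 1e-12)

  # explicit arithmetic case
  d2 <- dist
  d2$log_l <- rep(log(100), n)
  d2$log_mu <- matrix(log(c(0.1, 0.9)), n, 2, byrow = TRUE)
  d2$r <- d2$r[, 1:2]
  x2 <- zipo_counts(matrix(1, n, 2))
  p2 <- tempfile(fileext = ".tsv")
  export_denoised(x2, d2, p2, zero_path = NULL)
  expect_equal(unname(zipo:::read_dense_matrix(p2)[1, ]), c(10, 90))

  bad <- random_dist(n + 1, G)
  expect_error(export_denoised(x, bad, tempfile()),
               class = "zipo_validation_error")
})

test_that("latent export round-trips", {
  u <- matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), NULL))
  path <- tempfile(fileext = ".tsv")
  export_latents(u, path)
  back <- zipo:::read_dense_matrix(path)
  expect_equal(unname(back), unname(u), tolerance = 1e-12)
  expect_identical(rownames(back), c("a", "b"))
  expect_equal(ncol(back), 3L)
})
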