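# Count-matrix container and file plumbing.
#
# The container is deliberately light: a base integer-valued matrix with
# cells as rows plus id vectors, validated on construction. Sparse inputs
# (Matrix Market) are densified on load; the model consumes dense batches
# anyway and desk-scale matrices fit comfortably in memory.

#' Construct a validated cells x genes count matrix
#'
#' @param values numeric matrix of non-negative integer counts, cells as rows.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames, else `cell_1..n`).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   colnames, else `gene_1..G`).
#' @param drop_empty drop cells whose library size (row sum) is zero, with a
#'   warning. If `FALSE`, empty cells are kept (the simulator uses this so
#'   counts stay aligned with the generating truth).
#' @return An object of class `zipo_counts`: list with elements `values`
#'   (integer matrix with dimnames), `cell_ids`, `gene_ids`.
#' @export
zipo_counts <- function(values, cell_ids = NULL, gene_ids = NULL,
                        drop_empty = TRUE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  bad <- which(!is.finite(values) | values < 0 | values != round(values))
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(values))
    zipo_stop(sprintf(
      "counts must be finite non-negative integers; first offending entry at cell %d, gene %d (value %g)",
      ij[1], ij[2], values[bad[1]]
    ))
  }
  cell_ids <- as.character(cell_ids %||% rownames(values) %||%
    paste0("cell_", seq_len(nrow(values))))
  gene_ids <- as.character(gene_ids %||% colnames(values) %||%
    paste0("gene_", seq_len(ncol(values))))
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    zipo_stop("identifier lengths must match matrix dimensions")
  }
  if (anyDuplicated(cell_ids)) {
    zipo_stop(sprintf("duplicate cell identifier: '%s'",
                      cell_ids[duplicated(cell_ids)][1]))
  }
  if (anyDuplicated(gene_ids)) {
    zipo_stop(sprintf("duplicate gene identifier: '%s'",
                      gene_ids[duplicated(gene_ids)][1]))
  }
  libs <- rowSums(values)
  if (drop_empty && any(libs == 0)) {
    n0 <- sum(libs == 0)
    warning(sprintf("dropping %d cell(s) with zero library size", n0),
            call. = FALSE)
    keep <- libs > 0
    values <- values[keep, , drop = FALSE]
    cell_ids <- cell_ids[keep]
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "zipo_counts")
}

#' @export
print.zipo_counts <- function(x, ...) {
  cat(sprintf("<zipo_counts> %d cells x %d genes; %.1f%% nonzero\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$values > 0)))
  invisible(x)
}

#' Library sizes (per-cell total counts)
#' @param x a `zipo_counts` object.
#' @return numeric vector of row sums, named by cell id.
#' @export
library_sizes <- function(x) {
  stopifnot(inherits(x, "zipo_counts"))
  rowSums(x$values)
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

.mtx_sidecar <- function(path) {
  list(rows = paste0(path, ".rowids"), cols = paste0(path, ".colids"))
}

#' Read a count matrix from disk
#'
#' Two on-disk formats are supported. `"mtx"` is Matrix Market exchange
#' format with plain-text identifier sidecar files `<path>.rowids` and
#' `<path>.colids` (one id per line); by 10x convention the matrix is stored
#' genes x cells and transposed on load unless
#' `orientation = "cells-as-rows"`. `"dense"` is delimited text (tab or
#' comma, sniffed from the header): header row of gene ids, first column of
#' cell ids.
#'
#' @param path file path.
#' @param format `"mtx"` or `"dense"`. Default guesses from the extension.
#' @param orientation on-disk orientation, `"genes-as-rows"` (mtx default)
#'   or `"cells-as-rows"` (dense default).
#' @param drop_empty drop zero-library cells with a warning (default `TRUE`).
#' @return a [zipo_counts] object, cells as rows.
#' @export
read_counts <- function(path,
                        format = c("auto", "mtx", "dense"),
                        orientation = NULL,
                        drop_empty = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (!file.exists(path)) {
    zipo_stop(sprintf("file not found: %s", path), class = "zipo_io_error")
  }
  if (format == "mtx") {
    orientation <- orientation %||% "genes-as-rows"
    side <- .mtx_sidecar(path)
    if (!file.exists(side$rows) || !file.exists(side$cols)) {
      zipo_stop(sprintf(
        "mtx identifier sidecar files missing: expected %s and %s",
        side$rows, side$cols
      ), class = "zipo_io_error")
    }
    m <- as.matrix(Matrix::readMM(path))
    row_ids <- readLines(side$rows)
    col_ids <- readLines(side$cols)
    if (identical(orientation, "genes-as-rows")) {
      zipo_counts(t(m), cell_ids = col_ids, gene_ids = row_ids,
                  drop_empty = drop_empty)
    } else {
      zipo_counts(m, cell_ids = row_ids, gene_ids = col_ids,
                  drop_empty = drop_empty)
    }
  } else {
    sep <- .sniff_sep(path)
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    cell_ids <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    orientation <- orientation %||% "cells-as-rows"
    if (identical(orientation, "genes-as-rows")) {
      vals <- t(vals)
      zipo_counts(vals, cell_ids = colnames(dt)[-1], gene_ids = cell_ids,
                  drop_empty = drop_empty)
    } else {
      zipo_counts(vals, cell_ids = cell_ids, gene_ids = colnames(dt)[-1],
                  drop_empty = drop_empty)
    }
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: `"mtx"` writes Matrix Market (genes x cells
#' by default) plus `.rowids`/`.colids` sidecars; `"dense"` writes delimited
#' text with gene-id header and cell-id first column.
#'
#' @param x a `zipo_counts` object.
#' @param path output file path.
#' @param format `"mtx"` or `"dense"`.
#' @param sep field separator for dense output (default tab).
#' @param orientation on-disk orientation for mtx (default genes-as-rows).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "mtx", "dense"),
                         sep = "\t", orientation = NULL) {
  stopifnot(inherits(x, "zipo_counts"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    orientation <- orientation %||% "genes-as-rows"
    m <- if (identical(orientation, "genes-as-rows")) t(x$values) else x$values
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    side <- .mtx_sidecar(path)
    if (identical(orientation, "genes-as-rows")) {
      writeLines(x$gene_ids, side$rows)
      writeLines(x$cell_ids, side$cols)
    } else {
      writeLines(x$cell_ids, side$rows)
      writeLines(x$gene_ids, side$cols)
    }
  } else {
    write_dense_matrix(x$values, path, sep = sep, id_col = "cell_id")
  }
  invisible(path)
}

# Shared dense-dialect writer/reader for numeric matrices with row ids.
write_dense_matrix <- function(values, path, sep = "\t", id_col = "cell_id") {
  df <- data.frame(check.names = FALSE, row_id = rownames(values) %||%
    paste0("row_", seq_len(nrow(values))))
  names(df) <- id_col
  out <- cbind(df, as.data.frame(values, check.names = FALSE))
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

read_dense_matrix <- function(path) {
  sep <- .sniff_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Preprocessing flags for the encoder input
#'
#' The likelihood is always evaluated against raw counts; these flags only
#' transform the copy fed to the encoder. `library_normalize` divides each
#' cell's row by its library size; `log_transform` then applies
#' `log(1 + v)`. Order is fixed as normalize-then-log, matching the usual
#' counts-per-total-then-log convention.
#'
#' @param log_transform logical.
#' @param library_normalize logical.
#' @return object of class `zipo_preprocess`.
#' @export
preprocess_spec <- function(log_transform = FALSE, library_normalize = FALSE) {
  structure(list(log_transform = isTRUE(log_transform),
                 library_normalize = isTRUE(library_normalize)),
            class = "zipo_preprocess")
}

#' Apply input preprocessing to a count matrix
#'
#' @param x a `zipo_counts` object or numeric matrix (cells x genes).
#' @param spec a [preprocess_spec()].
#' @return dense numeric matrix, same shape and dimnames as the input counts.
#' @export
preprocess_counts <- function(x, spec = preprocess_spec()) {
  v <- if (inherits(x, "zipo_counts")) x$values else as.matrix(x)
  v <- v * 1.0
  if (spec$library_normalize) {
    libs <- rowSums(v)
    if (any(libs == 0)) {
      zipo_stop("cannot library-normalize cells with zero library size; filter them first")
    }
    v <- v / libs
  }
  if (spec$log_transform) v <- log1p(v)
  v
}

#' Export denoised rates and zero probabilities
#'
#' Writes the expected expression matrix `m_cg = l_c * mu_cg` (the model's
#' denoised counts) and, alongside it, the per-entry zero-inflation
#' probabilities, both in the dense delimited dialect with the original
#' identifiers.
#'
#' @param x a `zipo_counts` object the distribution was fitted to.
#' @param dist a `zipo_distribution` (see [zipo_impute()]).
#' @param path output path for the rate matrix.
#' @param zero_path output path for the zero-probability matrix; default
#'   `<path>.zero_prob`. `NULL` skips it.
#' @return `path`, invisibly.
#' @export
export_denoised <- function(x, dist, path,
                            zero_path = paste0(path, ".zero_prob")) {
  stopifnot(inherits(x, "zipo_counts"))
  m <- denoised_rates(dist)
  if (!identical(dim(m), dim(x$values))) {
    zipo_stop("distribution dimensions do not match the count matrix")
  }
  dimnames(m) <- dimnames(x$values)
  write_dense_matrix(m, path, id_col = "cell_id")
  if (!is.null(zero_path)) {
    z <- plogis(dist$r)
    dimnames(z) <- dimnames(x$values)
    write_dense_matrix(z, zero_path, id_col = "cell_id")
  }
  invisible(path)
}

#' Expected expression rates m = l * mu
#' @param dist a `zipo_distribution`.
#' @return cells x genes matrix of `exp(log_l + log_mu)`.
#' @export
denoised_rates <- function(dist) {
  exp(dist$log_l + dist$log_mu)
}

#' Export the latent embedding
#'
#' Writes the encoder output U (cells x latent variables) as dense delimited
#' text with cell ids, for downstream analyses such as clustering.
#'
#' @param embedding a `zipo_embedding` (from [zipo_forward()] /
#'   [zipo_impute()]) or a bare matrix with cell rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_latents <- function(embedding, path) {
  u <- if (is.list(embedding)) embedding$U else embedding
  if (is.null(colnames(u))) colnames(u) <- paste0("latent_", seq_len(ncol(u)))
  write_dense_matrix(u, path, id_col = "cell_id")
  invisible(path)
}

#' Per-cell covariate table
#'
#' @param values numeric matrix or data frame, cells x covariates; all
#'   entries must be finite.
#' @param names covariate names (defaults to colnames).
#' @return object of class `zipo_covariates`.
#' @export
covariate_table <- function(values, names = NULL) {
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  if (any(!is.finite(v))) zipo_stop("covariates must be finite")
  nm <- as.character(names %||% colnames(v) %||%
    paste0("covariate_", seq_len(ncol(v))))
  colnames(v) <- nm
  structure(list(values = v, names = nm), class = "zipo_covariates")
}
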