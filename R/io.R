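#' Read and write labeled matrices
#'
#' Matrices are exchanged as CSV/TSV with a header row of column labels
#' and a first column of row labels. The separator is inferred from the
#' file extension (`.tsv`/`.txt` tab, otherwise comma) unless given.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return `read_matrix()` returns a numeric matrix with dimnames;
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' @param x numeric matrix.
#' @rdname read_matrix
#' @export
write_matrix <- function(x, path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  x <- as_num_matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge list from TSV
#'
#' Expects columns `pre`, `post`, `connectivity` and (optionally)
#' `contact`; missing contact defaults to 1.
#'
#' @param path file path.
#' @return A data frame suitable for [kronecker_design()].
#' @export
read_edge_list <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("pre", "post", "connectivity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("edge list is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$contact)) df$contact <- 1
  df
}

#' Read a count matrix from an MTX triplet
#'
#' @param mtx path to the MatrixMarket file (cells x genes or
#'   genes x cells with `transpose = TRUE`).
#' @param cells,genes paths to plain-text label files (one id per line).
#' @param transpose set when the MTX stores genes on rows.
#' @return A dense integer matrix, cells on rows.
#' @export
read_count_mtx <- function(mtx, cells, genes, transpose = FALSE) {
  m <- as.matrix(Matrix::readMM(mtx))
  if (transpose) m <- t(m)
  cell_ids <- readLines(cells)
  gene_ids <- readLines(genes)
  check_dims(dim(m), c(length(cell_ids), length(gene_ids)),
             "count matrix", "label files")
  dimnames(m) <- list(cell_ids, gene_ids)
  m
}

#' Serialize a bilinear model fit to a directory
#'
#' Writes the factor matrices as labeled CSV (`A.csv`, `B.csv`) and the
#' run metadata (settings, iterations, final loss, convergence flag) as
#' `meta.json`. [read_bilm()] restores a lightweight factor bundle usable
#' with [rule_matrix()] and [latent_coordinates()].
#'
#' @param fit a [bilm()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bilm <- function(fit, dir) {
  if (!inherits(fit, "bilm")) stop("'fit' must be a bilm model",
                                   call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(fit$A, file.path(dir, "A.csv"))
  write_matrix(fit$B, file.path(dir, "B.csv"))
  meta <- list(d = fit$d, variant = fit$variant,
               lambda_A = fit$lambda_A, lambda_B = fit$lambda_B,
               rate = fit$rate, tol = fit$tol, max_iter = fit$max_iter,
               seed = fit$seed, n_iter = fit$n_iter,
               converged = fit$converged,
               final_loss = fit$loss[length(fit$loss)])
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @param dir directory written by [write_bilm()].
#' @rdname write_bilm
#' @export
read_bilm <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  A <- read_matrix(file.path(dir, "A.csv"))
  B <- read_matrix(file.path(dir, "B.csv"))
  structure(c(list(A = A, B = B), meta), class = "bilm_factors")
}

#' Write museum-style stratification records as JSON
#'
#' @param records list of records (see [parse_stratification()]).
#' @param path output path.
#' @export
write_museum_json <- function(records, path) {
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
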