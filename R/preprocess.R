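#' Median-normalize counts and log-transform
#'
#' Scales each cell's transcript counts so that its total matches the
#' median per-cell total, then applies `log(1 + x)`. This is the standard
#' first step for zero-inflated single-cell count matrices.
#'
#' @param counts nonnegative count matrix, cells on rows, genes on columns.
#' @return A numeric matrix of the same shape with dimnames preserved.
#' @examples
#' counts <- rbind(c1 = c(5, 5), c2 = c(10, 10), c3 = c(30, 10))
#' normalize_counts(counts)  # totals scaled to the median total (20)
#' @export
normalize_counts <- function(counts) {
  counts <- as_num_matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    ids <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
    stop("cells with zero total count: ",
         paste(head(ids[totals == 0], 5), collapse = ", "), call. = FALSE)
  }
  scaled <- counts * (median(totals) / totals)
  log1p(scaled)
}

#' Select highly variable genes from the mean-CV^2 relationship
#'
#' Regresses `log(CV^2)` on `log(mean)` across genes and retains genes
#' whose standardized residual exceeds `dispersion_z`, i.e. genes more
#' dispersed than expected at their expression level. Genes with zero
#' mean or zero variance can never be selected.
#'
#' @param expr normalized expression matrix (cells x genes).
#' @param dispersion_z standardized-residual threshold (default 1).
#' @return The column subset of `expr` with the selected genes; the
#'   logical selection vector over all genes is attached as attribute
#'   `"selected"`. Fewer than 10 retained genes triggers a warning.
#' @export
select_hvgs <- function(expr, dispersion_z = 1) {
  expr <- as_num_matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 cells", call. = FALSE)
  mu <- colMeans(expr)
  v <- apply(expr, 2, var)
  ok <- mu > 0 & v > 0
  resid_z <- rep(-Inf, ncol(expr))
  if (any(ok)) {
    cv2 <- v[ok] / mu[ok]^2
    fit <- lm(log(cv2) ~ log(mu[ok]))
    r <- residuals(fit)
    rs <- sd(r)
    resid_z[ok] <- if (rs > 0) r / rs else 0
  }
  selected <- resid_z > dispersion_z
  if (sum(selected) < 10)
    warning("fewer than 10 highly variable genes retained at z > ",
            dispersion_z)
  out <- expr[, selected, drop = FALSE]
  attr(out, "selected") <- selected
  out
}

#' PCA reduction to a cumulative explained-variance target
#'
#' Centers the columns, performs PCA, and keeps the smallest number of
#' leading components whose cumulative explained variance reaches
#' `variance_target` (default 95%).
#'
#' @param expr expression matrix (cells x features).
#' @param variance_target cumulative explained-variance fraction in
#'   `(0, 1]`.
#' @return A list of class `"pca_reduction"` with `scores` (cells x PCs),
#'   `loadings` (features x PCs, orthonormal columns), `explained`
#'   (variance fraction per retained PC) and `center` (column means, used
#'   to project new data consistently).
#' @export
pca_reduce <- function(expr, variance_target = 0.95) {
  expr <- as_num_matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 cells", call. = FALSE)
  if (!is.numeric(variance_target) || variance_target <= 0 ||
      variance_target > 1)
    stop("'variance_target' must lie in (0, 1]", call. = FALSE)
  pc <- prcomp(expr, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = frac[seq_len(k)],
                 center = pc$center),
            class = "pca_reduction")
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("PCA reduction: %d components, cumulative explained variance %.3f\n",
              ncol(x$scores), sum(x$explained)))
  invisible(x)
}

#' Type-wise means and pooled within-type standard deviation
#'
#' For each feature, computes the per-type mean and the pooled within-type
#' variance: the sum over types of the within-type mean squared deviation
#' (population form, divisor `n_i`), so each type contributes its own
#' variance regardless of size and singleton types contribute zero. The
#' pooled standard deviation is its square root. These are the diagonal
#' estimates of the within-type feature covariance used to normalize the
#' type-mean matrices before the type-level fit.
#'
#' @param expr feature matrix (cells x features).
#' @param types type label per row of `expr`.
#' @return A list of class `"typewise_stats"` with `type_means`
#'   (types x features) and `pooled_sd` (per feature).
#' @examples
#' expr <- rbind(c(0), c(2), c(1), c(3))
#' st <- typewise_stats(expr, c("t1", "t1", "t2", "t2"))
#' st$type_means   # 1 and 2
#' st$pooled_sd    # sqrt(1 + 1)
#' @export
typewise_stats <- function(expr, types) {
  expr <- as_num_matrix(expr)
  if (length(types) != nrow(expr))
    stop("'types' must label every row of 'expr'", call. = FALSE)
  if (anyNA(types)) stop("missing type labels", call. = FALSE)
  types <- as.character(types)
  lev <- unique(types)
  means <- matrix(0, length(lev), ncol(expr),
                  dimnames = list(lev, colnames(expr)))
  pooled_var <- numeric(ncol(expr))
  for (i in seq_along(lev)) {
    rows <- expr[types == lev[i], , drop = FALSE]
    m <- colMeans(rows)
    means[i, ] <- m
    pooled_var <- pooled_var +
      colMeans(sweep(rows, 2, m, "-")^2)  # population within-type variance
  }
  structure(list(type_means = means, pooled_sd = sqrt(pooled_var)),
            class = "typewise_stats")
}

#' @export
print.typewise_stats <- function(x, ...) {
  cat(sprintf("Type-wise statistics: %d types x %d features\n",
              nrow(x$type_means), ncol(x$type_means)))
  invisible(x)
}

#' Variance-normalized type-mean matrix
#'
#' Divides each type-mean feature by the pooled within-type standard
#' deviation of that feature, yielding the normalized matrix the
#' type-level bilinear fit operates on. Features with (near) zero pooled
#' sd are divided by `sd_floor` instead, keeping the output finite.
#'
#' @param stats a [typewise_stats()] result.
#' @param sd_floor lower bound applied to the pooled sd.
#' @return A types x features matrix; attribute `"scale_applied"` records
#'   the per-feature divisor.
#' @export
normalize_type_matrix <- function(stats, sd_floor = 1e-8) {
  if (!inherits(stats, "typewise_stats"))
    stop("'stats' must come from typewise_stats()", call. = FALSE)
  divisor <- pmax(stats$pooled_sd, sd_floor)
  out <- sweep(stats$type_means, 2, divisor, "/")
  attr(out, "scale_applied") <- divisor
  out
}

#' Map transcriptomic type names onto connectomic type names
#'
#' Type alignment between the two data sources is done through an
#' explicit two-column table (transcriptomic name, connectomic name), as
#' curated alignment tables provide; no fuzzy matching is attempted.
#' Labels absent from the table are returned as `NA` so callers can drop
#' unmatched cells.
#'
#' @param labels character vector of transcriptomic type labels.
#' @param map data frame whose first column holds transcriptomic names and
#'   second column the corresponding connectomic names.
#' @return Character vector of connectomic labels (`NA` where unmapped).
#' @export
align_types <- function(labels, map) {
  if (ncol(map) < 2) stop("'map' needs two columns", call. = FALSE)
  as.character(map[[2]])[match(as.character(labels),
                               as.character(map[[1]]))]
}
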