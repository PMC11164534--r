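#' Build an edge list from a connectivity matrix and contact mask
#'
#' The spatial connectome model is fit only on pairs of neurons in
#' physical contact. This helper flattens a connectivity matrix into the
#' edge-list form used by [kronecker_design()], keeping each unordered
#' pair once in the symmetric (gap-junction) case.
#'
#' @param Z observed connectivity matrix (`n x n` when symmetric).
#' @param contact optional binary contact mask of the same shape; pairs
#'   with `contact == 0` are dropped. `NULL` keeps all pairs.
#' @param symmetric treat connectivity as undirected: only pairs `i < j`
#'   are emitted and `Z` is expected square.
#' @param include_diag keep self pairs `i == j` (default `FALSE`).
#' @return A data frame with columns `pre`, `post` (row/column indices or
#'   labels), `connectivity` and `contact`.
#' @export
edge_list <- function(Z, contact = NULL, symmetric = TRUE,
                      include_diag = FALSE) {
  Z <- as_num_matrix(Z)
  if (symmetric && nrow(Z) != ncol(Z))
    stop("symmetric edge list requires a square connectivity matrix",
         call. = FALSE)
  if (!is.null(contact)) check_dims(dim(contact), dim(Z), "contact", "Z")
  idx <- which(matrix(TRUE, nrow(Z), ncol(Z)), arr.ind = TRUE)
  if (symmetric) {
    keep <- if (include_diag) idx[, 1] <= idx[, 2] else idx[, 1] < idx[, 2]
    idx <- idx[keep, , drop = FALSE]
  }
  ct <- if (is.null(contact)) rep(1, nrow(idx)) else contact[idx]
  pre_ids <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  post_ids <- colnames(Z) %||% as.character(seq_len(ncol(Z)))
  out <- data.frame(pre = pre_ids[idx[, 1]], post = post_ids[idx[, 2]],
                    connectivity = Z[idx], contact = as.numeric(ct > 0),
                    stringsAsFactors = FALSE)
  out[out$contact > 0, , drop = FALSE]
}

#' Kronecker-product design matrix for rule-matrix regression
#'
#' The SCM predicts connectivity as \eqn{x_i O x_j^T}; over an edge list
#' this is linear in `vec(O)`, so the rule matrix can be estimated by a
#' regression of the observed connectivity against the Kronecker product
#' of the expression vectors. Row `(i, j)` of the design satisfies
#' `design %*% as.vector(O) == x_i O x_j'` (column-major `vec`); in the
#' symmetric case the row is averaged with its transpose pairing,
#' `(x_i (x) x_j + x_j (x) x_i) / 2`, which constrains the fitted `O` to
#' be symmetric.
#'
#' @param X expression matrix (cells x features) whose rownames (or row
#'   indices) match the edge-list ids.
#' @param edges a data frame from [edge_list()] (columns `pre`, `post`,
#'   `connectivity`).
#' @param symmetric build symmetric design rows (undirected synapses).
#' @return A list with `design` (`n_edges x p^2` in the symmetric case,
#'   `p * q` generally) and `targets` (observed connectivity vector).
#' @export
kronecker_design <- function(X, edges, symmetric = TRUE) {
  X <- as_num_matrix(X)
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  i <- match(as.character(edges$pre), ids)
  j <- match(as.character(edges$post), ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(edges$pre[is.na(i)], edges$post[is.na(j)]))
    stop("edge list names cells absent from the expression matrix: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  design <- matrix(0, length(i), p * p)
  for (e in seq_along(i)) {
    xi <- X[i[e], ]; xj <- X[j[e], ]
    row <- kronecker(xj, xi)          # design %*% vec(O) = xi O xj'
    if (symmetric) row <- (row + kronecker(xi, xj)) / 2
    design[e, ] <- row
  }
  list(design = design, targets = edges$connectivity)
}

#' Ridge solution of the rule-matrix regression
#'
#' Solves the normal equations \eqn{(D^TD + \lambda I)\,vec(O) = D^T t}
#' for the rule matrix. Systems up to `p^2 <= 2500` unknowns are solved
#' directly; larger ones by conjugate gradients (tolerance 1e-10). The
#' symmetric case averages `O` with its transpose, removing numerical
#' asymmetry.
#'
#' @param design,targets from [kronecker_design()].
#' @param lambda nonnegative ridge strength.
#' @param p number of expression features (rows of `O`).
#' @param q number of features on the second axis (defaults to `p`).
#' @param symmetric symmetrize the solution.
#' @return The `p x q` rule matrix.
#' @export
scm_ridge <- function(design, targets, lambda, p, q = p, symmetric = TRUE) {
  if (lambda < 0) stop("'lambda' must be nonnegative", call. = FALSE)
  if (length(targets) != nrow(design))
    stop("'targets' length must equal the number of design rows",
         call. = FALSE)
  if (ncol(design) != p * q)
    stop("design has ", ncol(design), " columns but p * q = ", p * q,
         call. = FALSE)
  G <- crossprod(design)
  diag(G) <- diag(G) + lambda
  b <- crossprod(design, targets)
  v <- if (ncol(design) <= 2500) {
    tryCatch(solve(G, b), error = function(e)
      stop("rule-matrix system is singular; use lambda > 0 ",
           "(ridge regularization)", call. = FALSE))
  } else {
    cg_solve(G, b, tol = 1e-10)
  }
  O <- matrix(v, p, q)
  if (symmetric) {
    if (p != q) stop("symmetric rule matrix requires p == q", call. = FALSE)
    O <- (O + t(O)) / 2
  }
  O
}

# Conjugate gradients for the SPD ridge system.
cg_solve <- function(G, b, tol = 1e-10, max_iter = 10 * length(b)) {
  x <- numeric(length(b))
  r <- as.numeric(b)
  pdir <- r
  rs <- sum(r^2)
  b2 <- max(sum(as.numeric(b)^2), .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    Gp <- as.numeric(G %*% pdir)
    alpha <- rs / sum(pdir * Gp)
    x <- x + alpha * pdir
    r <- r - alpha * Gp
    rs_new <- sum(r^2)
    if (sqrt(rs_new / b2) < tol) break
    pdir <- r + (rs_new / rs) * pdir
    rs <- rs_new
  }
  x
}

#' Fit the spatial connectome model baseline
#'
#' Estimates the feature-interaction rule matrix `O` such that predicted
#' connectivity is \eqn{XOX^T}, by ridge regression over the pairs in
#' physical contact (the Kronecker-design formulation of Kovács-style
#' rule-matrix models). This is the full-rank baseline against which the
#' bilinear factorization \eqn{\hat O = AB^T} is compared.
#'
#' @param Z observed connectivity matrix.
#' @param X expression matrix, rows aligned with `Z`'s axes.
#' @param contact optional binary contact mask (pairs without contact are
#'   excluded from the regression).
#' @param lambda ridge strength.
#' @param symmetric undirected synapse class (gap junctions): fit on
#'   unordered pairs and constrain `O` symmetric.
#' @param include_diag include self pairs.
#' @return An object of class `"scm"` with components `O` (rule matrix,
#'   feature labels on both axes), `lambda`, `n_edges` and the call.
#'   Methods: [predict.scm()], `print`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(48), 12, 4)
#' O_true <- crossprod(matrix(rnorm(16), 4, 4)) - 1
#' Z <- X %*% O_true %*% t(X)
#' fit <- scm(Z, X, lambda = 1e-8)
#' max(abs(fit$O - O_true)) < 1e-6
#' @export
scm <- function(Z, X, contact = NULL, lambda = 1e-6, symmetric = TRUE,
                include_diag = FALSE) {
  X <- as_num_matrix(X)
  edges <- edge_list(Z, contact, symmetric = symmetric,
                     include_diag = include_diag)
  if (nrow(edges) < 1)
    stop("no edges left after contact filtering", call. = FALSE)
  kd <- kronecker_design(X, edges, symmetric = symmetric)
  O <- scm_ridge(kd$design, kd$targets, lambda, p = ncol(X),
                 symmetric = symmetric)
  fn <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  dimnames(O) <- list(fn, fn)
  structure(list(O = O, lambda = lambda, symmetric = symmetric,
                 n_edges = nrow(edges), call = match.call()),
            class = "scm")
}

#' Cross-validate the SCM ridge strength
#'
#' Selects the rule-matrix regularization by the same five-fold
#' entry-level cross-validation used for the bilinear model, for parity
#' in comparisons: contact edges are partitioned into `k` folds by a
#' seeded shuffle, the ridge solution is fit on `k - 1` folds, and the
#' held-out squared prediction error is averaged.
#'
#' @inheritParams scm
#' @param lambda_grid candidate ridge strengths.
#' @param k number of folds.
#' @param seed fold-shuffle seed.
#' @return A list with `grid` (data frame of `lambda`, `mean_val_loss`),
#'   `selected` (the minimizing `lambda`, ties toward smaller values)
#'   and `fold_seed`.
#' @export
cv_scm <- function(Z, X, contact = NULL,
                   lambda_grid = c(0.01, 0.1, 1, 10, 100), k = 5,
                   seed = 1, symmetric = TRUE, include_diag = FALSE) {
  edges <- edge_list(Z, contact, symmetric = symmetric,
                     include_diag = include_diag)
  if (nrow(edges) < k)
    stop("only ", nrow(edges), " edges; reduce k", call. = FALSE)
  kd <- kronecker_design(X, edges, symmetric = symmetric)
  perm <- with_seed(seed, sample(nrow(edges)))
  fold_of <- rep_len(seq_len(k), length(perm))
  lambda_grid <- sort(lambda_grid)
  val <- vapply(lambda_grid, function(l) {
    mean(vapply(seq_len(k), function(f) {
      held <- perm[fold_of == f]
      O <- scm_ridge(kd$design[-held, , drop = FALSE],
                     kd$targets[-held], l, p = ncol(X),
                     symmetric = symmetric)
      sum((kd$design[held, , drop = FALSE] %*% as.vector(O) -
             kd$targets[held])^2)
    }, 0))
  }, 0)
  list(grid = data.frame(lambda = lambda_grid, mean_val_loss = val),
       selected = list(lambda = lambda_grid[which.min(val)]),
       fold_seed = seed)
}

#' Predict connectivity from a fitted SCM
#'
#' @param object an `"scm"` fit (or any list with a rule matrix `O`).
#' @param X expression matrix.
#' @param ... unused.
#' @return The matrix \eqn{XOX^T} with row labels propagated.
#' @export
predict.scm <- function(object, X, ...) {
  X <- as_num_matrix(X)
  check_dims(ncol(X), nrow(object$O), "feature columns of X",
             "rows of the rule matrix O")
  out <- X %*% object$O %*% t(X)
  dimnames(out) <- list(rownames(X), rownames(X))
  out
}

#' @export
print.scm <- function(x, ...) {
  cat(sprintf("Spatial connectome model: %d x %d rule matrix, lambda = %g, %d edges\n",
              nrow(x$O), ncol(x$O), x$lambda, x$n_edges))
  invisible(x)
}

#' Discrepancy score between corresponding entries
#'
#' The scale-invariant measure \eqn{DS = |\hat o - o| / (|\hat o| + |o|)},
#' bounded in \[0, 1\]: 0 means the two values agree, 1 means maximal
#' disagreement (e.g. opposite signs). `DS(0, 0)` is defined as 0, the
#' limit of no discrepancy. Vectorized over its arguments.
#'
#' @param o_hat,o numeric vectors or matrices of corresponding entries.
#' @return Values in `[0, 1]`, same shape as the inputs.
#' @examples
#' discrepancy_score(c(1, 1, 0.3), c(1, -1, 0.1))  # 0, 1, 0.5
#' @export
discrepancy_score <- function(o_hat, o) {
  denom <- abs(o_hat) + abs(o)
  out <- ifelse(denom == 0, 0, abs(o_hat - o) / denom)
  if (is.matrix(o_hat)) dim(out) <- dim(o_hat)
  out
}

#' Flag entries where two rule matrices disagree substantially
#'
#' An entry pair is flagged when its discrepancy score reaches
#' `ds_threshold` *and* at least one of the two values has magnitude at
#' or above `magnitude_floor`; pairs where both values are small are
#' filtered out because regularization pushes unimportant coefficients
#' toward zero, where the DS is dominated by noise.
#'
#' @param O_hat,O matrices of matching shape (typically the bilinear
#'   product \eqn{AB^T} and the SCM rule matrix).
#' @param ds_threshold DS level from which a pair counts as divergent.
#' @param magnitude_floor both-below-this pairs are never flagged.
#' @return An object of class `"discrepancy_report"`: list with `ds`
#'   (score matrix), `flagged` (logical matrix) and `thresholds`.
#' @export
discrepancy_report <- function(O_hat, O, ds_threshold = 0.5,
                               magnitude_floor = 0.1) {
  O_hat <- as_num_matrix(O_hat); O <- as_num_matrix(O)
  check_dims(dim(O), dim(O_hat), "O", "O_hat")
  ds <- discrepancy_score(O_hat, O)
  small <- abs(O_hat) < magnitude_floor & abs(O) < magnitude_floor
  flagged <- ds >= ds_threshold & !small
  dimnames(ds) <- dimnames(flagged) <- dimnames(O_hat)
  structure(list(ds = ds, flagged = flagged,
                 thresholds = c(ds_threshold = ds_threshold,
                                magnitude_floor = magnitude_floor)),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("Discrepancy report: %d of %d entries flagged (DS >= %g, floor %g)\n",
              sum(x$flagged), length(x$flagged),
              x$thresholds["ds_threshold"], x$thresholds["magnitude_floor"]))
  invisible(x)
}

#' Compare two rule matrices
#'
#' Computes the Pearson correlation over all corresponding entries of the
#' bilinear product \eqn{\hat O = AB^T} and the SCM rule matrix `O`,
#' together with a [discrepancy_report()] highlighting the entries each
#' model captures differently.
#'
#' @inheritParams discrepancy_report
#' @return A list with `pearson` and `report`.
#' @export
compare_rule_matrices <- function(O_hat, O, ds_threshold = 0.5,
                                  magnitude_floor = 0.1) {
  O_hat <- as_num_matrix(O_hat); O <- as_num_matrix(O)
  check_dims(dim(O), dim(O_hat), "O", "O_hat")
  if (pop_sd(as.numeric(O_hat)) == 0 || pop_sd(as.numeric(O)) == 0)
    stop("correlation undefined: a rule matrix has zero variance",
         call. = FALSE)
  list(pearson = cor(as.numeric(O_hat), as.numeric(O)),
       report = discrepancy_report(O_hat, O, ds_threshold, magnitude_floor))
}
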