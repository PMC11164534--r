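#' ROC analysis of a continuous connectivity reconstruction
#'
#' Varies a threshold binarizing the continuous predictions and reports
#' the full ROC curve and its area. The AUC uses the rank-based
#' equivalence \eqn{AUC = P(s_+ > s_-) + \frac{1}{2} P(s_+ = s_-)}, so
#' tied scores contribute half a concordance.
#'
#' @param scores predicted connectivity (matrix or vector).
#' @param truth binary ground-truth connectivity, same shape.
#' @param mask optional nonnegative weight/contact matrix; only entries
#'   with `mask > 0` are evaluated (the model is typically fit on contact
#'   pairs only).
#' @return A list with `auc` and `curve` (data frame of `fpr`, `tpr` at
#'   each threshold).
#' @export
roc_auc <- function(scores, truth, mask = NULL) {
  s <- as.numeric(scores)
  y <- as.numeric(truth)
  if (length(s) != length(y))
    stop("scores and truth must have the same shape", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("truth must be binary (0/1)", call. = FALSE)
  if (!is.null(mask)) {
    m <- as.numeric(mask) > 0
    if (length(m) != length(s))
      stop("mask must have the same shape as scores", call. = FALSE)
    s <- s[m]; y <- y[m]
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: only one class present among evaluated entries",
         call. = FALSE)
  r <- rank(s)  # average ranks handle ties
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)  # one point per threshold
  curve <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(auc = auc, curve = curve)
}

#' Pearson correlation between corresponding matrix entries
#'
#' @param Mhat,M matrices of matching shape.
#' @param mask optional matrix; only entries with `mask > 0` enter.
#' @return The Pearson correlation coefficient.
#' @export
matrix_pearson <- function(Mhat, M, mask = NULL) {
  a <- as.numeric(Mhat); b <- as.numeric(M)
  if (length(a) != length(b))
    stop("matrices must have the same shape", call. = FALSE)
  if (!is.null(mask)) {
    keep <- as.numeric(mask) > 0
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 2)
    stop("need at least 2 entries to correlate", call. = FALSE)
  if (pop_sd(a) == 0 || pop_sd(b) == 0)
    stop("correlation undefined for a constant matrix", call. = FALSE)
  cor(a, b)
}

#' Cross-validate the bilinear model over (lambda, d)
#'
#' Five-fold (by default) cross-validation with observed connectivity
#' entries as the fold unit: the entries with positive weight (all
#' entries when `W` is absent) are partitioned into `k` folds by a seeded
#' shuffle; for every grid point the model is trained with the held-out
#' entries' weights set to zero and scored by the unregularized weighted
#' data term on the held-out entries. The selected pair minimizes the
#' mean validation loss, with ties broken toward smaller `d`, then
#' smaller `lambda`. A fit that diverges at a grid point contributes an
#' infinite validation loss (with a warning) rather than aborting the
#' search.
#'
#' @inheritParams bilm
#' @param lambda_grid,d_grid candidate values.
#' @param k number of folds.
#' @param seed seed used both for the fold shuffle and for every fit's
#'   factor initialization, making the whole search deterministic.
#' @return An object of class `"bilm_cv"`: list with `grid` (data frame
#'   of `lambda`, `d`, `mean_val_loss`), `fold_losses` (grid points x
#'   folds), `selected` (list with `lambda`, `d`) and `fold_seed`.
#' @export
cv_bilm <- function(Z, X, Y = X,
                    lambda_grid = c(0.01, 0.1, 1, 10, 100),
                    d_grid = 1:5, k = 5, seed = 1,
                    W = NULL, variant = c("cell", "type"),
                    rate = 1e-4, tol = 1e-6, max_iter = 1e6,
                    step = c("bb", "fixed")) {
  variant <- match.arg(variant)
  step <- match.arg(step)
  Z <- as_num_matrix(Z)
  W0 <- W %||% matrix(1, nrow(Z), ncol(Z))
  obs <- which(W0 > 0)
  if (length(obs) < k)
    stop("only ", length(obs), " observed entries; reduce k", call. = FALSE)
  perm <- with_seed(seed, sample(obs))
  fold_of <- rep_len(seq_len(k), length(perm))

  grid <- expand.grid(lambda = lambda_grid, d = d_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$d, grid$lambda), , drop = FALSE]
  rownames(grid) <- NULL
  fold_losses <- matrix(NA_real_, nrow(grid), k)

  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(k)) {
      held <- perm[fold_of == f]
      W_train <- W0
      W_train[held] <- 0
      fit <- tryCatch(
        bilm(Z, X, Y, d = grid$d[g], lambda = grid$lambda[g],
             W = W_train, variant = variant, rate = rate, tol = tol,
             max_iter = max_iter, seed = seed, step = step),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("fit failed at lambda = ", grid$lambda[g], ", d = ",
                grid$d[g], " (fold ", f, "): ", conditionMessage(fit))
        fold_losses[g, f] <- Inf
      } else {
        zh <- fitted(fit)
        fold_losses[g, f] <- sum((W0[held] * (Z[held] - zh[held]))^2)
      }
    }
  }
  grid$mean_val_loss <- rowMeans(fold_losses)
  best <- which.min(grid$mean_val_loss)  # grid pre-sorted by (d, lambda)
  structure(list(grid = grid, fold_losses = fold_losses,
                 selected = list(lambda = grid$lambda[best],
                                 d = grid$d[best]),
                 k = k, fold_seed = seed, variant = variant),
            class = "bilm_cv")
}

#' @export
print.bilm_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d grid points (%s-level)\n",
              x$k, nrow(x$grid), x$variant))
  cat(sprintf("  selected: lambda = %g, d = %d\n",
              x$selected$lambda, x$selected$d))
  invisible(x)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) out[[length(out) + 1L]] <-
        c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

#' Consistency of bilinear solutions across repeated fits
#'
#' The factorization is identifiable only up to a signed permutation of
#' the latent columns: negating a column in both factors, or swapping two
#' columns consistently, yields an equivalent solution. For each pair of
#' runs, every candidate column pairing (all `d!` permutations for
#' `d <= 4`, greedy matching beyond) is scored by the mean over latent
#' dimensions of the absolute cosine similarity of the paired coefficient
#' vectors, averaged over the pre- (`A`) and post- (`B`) side; the
#' pair's consistency is the maximum over pairings.
#'
#' @param runs a list of [bilm()] fits (or lists with factors `A`, `B`)
#'   sharing the same latent dimension.
#' @return An object of class `"consistency_score"`: list with
#'   `pairwise` (symmetric matrix over runs, unit diagonal), `min` and
#'   `mean` (over distinct pairs).
#' @export
consistency_across_runs <- function(runs) {
  if (length(runs) < 2) stop("need at least 2 runs", call. = FALSE)
  ds <- vapply(runs, function(r) ncol(r$A), 0L)
  if (length(unique(ds)) != 1)
    stop("runs disagree on the latent dimension d", call. = FALSE)
  d <- ds[1]
  n <- length(runs)
  pair_score <- function(r1, r2) {
    # |cos| between column k of run 1 and column perm[k] of run 2,
    # averaged over the A and B side
    sim <- function(M1, M2)
      abs(crossprod(sweep(M1, 2, sqrt(colSums(M1^2)), "/"),
                    sweep(M2, 2, sqrt(colSums(M2^2)), "/")))
    SA <- sim(r1$A, r2$A); SB <- sim(r1$B, r2$B)
    S <- (SA + SB) / 2
    if (d <= 4) {
      max(vapply(all_perms(d), function(p)
        mean(S[cbind(seq_len(d), p)]), 0))
    } else {
      # greedy matching for larger d
      total <- 0; used <- integer()
      for (k in order(apply(S, 1, max), decreasing = TRUE)) {
        j <- setdiff(order(S[k, ], decreasing = TRUE), used)[1]
        used <- c(used, j); total <- total + S[k, j]
      }
      total / d
    }
  }
  M <- diag(1, n)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      M[i, j] <- M[j, i] <- pair_score(runs[[i]], runs[[j]])
  up <- M[upper.tri(M)]
  structure(list(pairwise = M, min = min(up), mean = mean(up)),
            class = "consistency_score")
}

#' @export
print.consistency_score <- function(x, ...) {
  cat(sprintf("Run-to-run consistency over %d runs: mean %.4f, min %.4f\n",
              nrow(x$pairwise), x$mean, x$min))
  invisible(x)
}

#' Connections missed by a reconstruction
#'
#' Counts the positive entries of the target matrix (connections) whose
#' reconstructed value is nonpositive (missed), and returns the
#' entrywise discrepancy-score map.
#'
#' @param Zhat reconstructed connectivity matrix.
#' @param Z target connectivity matrix, same shape.
#' @return A list with `n_missed`, `n_positive` and `ds_map`.
#' @export
missed_connections <- function(Zhat, Z) {
  Zhat <- as_num_matrix(Zhat); Z <- as_num_matrix(Z)
  check_dims(dim(Zhat), dim(Z), "Zhat", "Z")
  pos <- Z > 0
  list(n_missed = sum(pos & Zhat <= 0),
       n_positive = sum(pos),
       ds_map = discrepancy_score(Zhat, Z))
}
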