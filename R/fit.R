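#' Fit a bilinear connectivity model by alternating gradient descent
#'
#' `bilm()` estimates the two transformation matrices `A` (`p x d`) and `B`
#' (`q x d`) that map pre- and post-synaptic expression features into a
#' shared `d`-dimensional latent space such that the predicted connectivity
#' \eqn{\hat Z = XA(YB)^T} approximates the observed matrix `Z`. The
#' architecture follows collaborative filtering: presynaptic neurons play
#' the role of users, postsynaptic neurons of items, and connectivity of
#' ratings.
#'
#' Two data regimes are supported through `variant`:
#'
#' * `"cell"` — expression and connectivity are observed on the same
#'   cells. The loss is the weighted squared reconstruction error with an
#'   L2 (ridge) penalty on each factor; `W` carries either binary physical
#'   contact indicators or the type-balancing weights `1/(n_i n_j)` (see
#'   [weight_matrix()]).
#' * `"type"` — expression and connectivity come from different sources
#'   and are aligned at the level of neuronal types. `X` and `Y` are then
#'   variance-normalized type-mean matrices (see [normalize_type_matrix()])
#'   and the penalty is on the factor Gram matrices, the surrogate of the
#'   constraint that within-type variance in latent space stays small.
#'
#' Optimization alternates gradient updates of `A` and `B`: at each
#' iteration the prediction is formed once, both gradients are computed
#' from it, and `A` is updated before `B`. Factors are initialized with
#' standard-normal draws under `seed`, so a fit is a pure function of
#' `(data, arguments)`. Iteration stops when the absolute loss change
#' drops below `tol` or after `max_iter` iterations; a non-finite loss
#' aborts with an error suggesting a smaller `rate`.
#'
#' Two step-size rules are available. `step = "bb"` (the default) uses
#' the Barzilai-Borwein spectral step on the joint `(A, B)` gradient
#' with a nonmonotone safeguard (a trial step whose loss exceeds the
#' maximum of the last 20 losses is halved until accepted). The
#' variance-normalized type matrices are badly scaled, and a constant
#' rate needs millions of iterations there; the spectral step follows
#' the same gradient directions with a data-driven magnitude and
#' typically converges orders of magnitude faster. `step = "fixed"`
#' runs the plain constant-rate loop, whose loss trajectory is
#' monotone whenever `rate` is small enough.
#'
#' @param Z observed connectivity matrix (`n_pre x n_post`), cells or types
#'   on the rows/columns depending on `variant`.
#' @param X,Y pre- and post-synaptic feature matrices whose rows align with
#'   the rows/columns of `Z`. `Y` defaults to `X` (e.g. gap junctions,
#'   where the two sides share one expression matrix).
#' @param d latent space dimension.
#' @param lambda regularization strength applied to both factors; the
#'   common single-knob setting. Use `lambda_A`/`lambda_B` to set the two
#'   penalties independently.
#' @param lambda_A,lambda_B side-specific regularization strengths.
#' @param W optional nonnegative weight matrix (same shape as `Z`); zero
#'   entries exclude a pair from the fit.
#' @param variant `"cell"` or `"type"` (see Details).
#' @param rate learning rate of the gradient updates (the initial rate
#'   under `step = "bb"`, the constant rate under `step = "fixed"`).
#' @param step step-size rule, `"bb"` or `"fixed"`; see Details.
#' @param tol convergence threshold on the absolute loss change.
#' @param max_iter maximum number of iterations.
#' @param seed integer seed for the standard-normal factor initialization.
#' @param init optional list with matrices `A` and `B` overriding the
#'   random initialization.
#' @return An object of class `"bilm"`: a list with components `A`, `B`
#'   (estimated factors, feature ids on rows), `d`, `variant`, `loss`
#'   (per-iteration trajectory), `converged`, `n_iter`, the data
#'   (`Z`, `X`, `Y`, `W`) and the call/settings. Methods include
#'   [predict.bilm()], [coef.bilm()], [residuals.bilm()], [plot.bilm()],
#'   [simulate.bilm()], [summary.bilm()] and [rule_matrix()].
#' @examples
#' sim <- simulate_bilinear(bilinear_scenario(
#'   a = 4, b = 3, cells_per_type = 5, p = 4, q = 4, d_true = 2,
#'   within_type_sd = 0, connectivity_noise_sd = 0, seed = 1))
#' fit <- bilm(sim$Z, sim$X, sim$Y, d = 2, lambda = 0, rate = 1e-4,
#'             seed = 1)
#' fit
#' matrix_pearson(fitted(fit), sim$Z)
#' @export
bilm <- function(Z, X, Y = X, d = 2,
                 lambda = 0, lambda_A = lambda, lambda_B = lambda,
                 W = NULL, variant = c("cell", "type"),
                 rate = 1e-4, tol = 1e-6, max_iter = 1e6,
                 seed = NULL, init = NULL, step = c("bb", "fixed")) {
  variant <- match.arg(variant)
  step <- match.arg(step)
  Z <- as_num_matrix(Z); X <- as_num_matrix(X); Y <- as_num_matrix(Y)
  check_finite(Z); check_finite(X); check_finite(Y)
  if (d < 1) stop("'d' must be at least 1", call. = FALSE)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be at least 1", call. = FALSE)
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  if (lambda_A < 0 || lambda_B < 0)
    stop("regularization strengths must be nonnegative", call. = FALSE)
  check_dims(nrow(X), nrow(Z), "rows of X", "rows of Z")
  check_dims(nrow(Y), ncol(Z), "rows of Y", "columns of Z")
  p <- ncol(X); q <- ncol(Y)
  if (is.null(W)) {
    W <- matrix(1, nrow(Z), ncol(Z))
  } else {
    W <- as_num_matrix(W)
    check_dims(dim(W), dim(Z), "W", "Z")
    if (any(W < 0)) stop("'W' must be nonnegative", call. = FALSE)
  }

  if (is.null(init)) {
    init <- with_seed(seed, list(A = matrix(rnorm(p * d), p, d),
                                 B = matrix(rnorm(q * d), q, d)))
  } else {
    check_dims(dim(init$A), c(p, d), "init$A", "X features x d")
    check_dims(dim(init$B), c(q, d), "init$B", "Y features x d")
  }

  res <- agd_fit_cpp(X, Y, Z, W, init$A, init$B,
                     lambda_A, lambda_B, rate, tol,
                     as.integer(max_iter),
                     gram_penalty = (variant == "type"),
                     bb_step = (step == "bb"))
  if (res$diverged)
    stop("bilinear fit diverged (loss became non-finite); ",
         "try a smaller learning rate 'rate'", call. = FALSE)

  dn <- list(colnames(X) %||% paste0("f", seq_len(p)),
             paste0("dim", seq_len(d)))
  A <- structure(res$A, dimnames = dn)
  B <- structure(res$B,
                 dimnames = list(colnames(Y) %||% paste0("f", seq_len(q)),
                                 dn[[2]]))
  structure(list(
    A = A, B = B, d = d, variant = variant,
    lambda_A = lambda_A, lambda_B = lambda_B,
    loss = res$loss, converged = res$converged, n_iter = res$n_iter,
    rate = rate, tol = tol, max_iter = max_iter, seed = seed,
    step = step,
    Z = Z, X = X, Y = Y, W = W, call = match.call()),
    class = "bilm")
}

#' Predict connectivity from a fitted bilinear model
#'
#' Computes \eqn{XA(YB)^T} for new (or the training) feature matrices. The
#' numerical rank of the prediction is at most `d`.
#'
#' @param object a fitted [bilm()] model.
#' @param X,Y feature matrices; default to the training matrices. Their
#'   feature dimension must match the fitted factors.
#' @param ... unused.
#' @return A connectivity matrix with row/column labels propagated from
#'   `X`/`Y`.
#' @export
predict.bilm <- function(object, X = object$X, Y = object$Y, ...) {
  X <- as_num_matrix(X); Y <- as_num_matrix(Y)
  check_dims(ncol(X), nrow(object$A), "feature columns of X",
             "rows of fitted A")
  check_dims(ncol(Y), nrow(object$B), "feature columns of Y",
             "rows of fitted B")
  out <- (X %*% object$A) %*% t(Y %*% object$B)
  dimnames(out) <- list(rownames(X), rownames(Y))
  out
}

#' @export
fitted.bilm <- function(object, ...) predict(object)

#' Residual connectivity of a bilinear model fit
#'
#' @param object a fitted [bilm()] model.
#' @param masked how to treat pairs with zero weight: `"na"` (default)
#'   marks them `NA` since they never entered the fit, `"keep"` returns raw
#'   differences everywhere.
#' @param ... unused.
#' @return Matrix of `Z - fitted(object)`.
#' @export
residuals.bilm <- function(object, masked = c("na", "keep"), ...) {
  masked <- match.arg(masked)
  r <- object$Z - fitted(object)
  if (masked == "na") r[object$W == 0] <- NA_real_
  r
}

#' Extract the fitted transformation matrices
#'
#' @param object a fitted [bilm()] model.
#' @param side `"both"` (a list), `"pre"` (`A`) or `"post"` (`B`).
#' @param ... unused.
#' @export
coef.bilm <- function(object, side = c("both", "pre", "post"), ...) {
  side <- match.arg(side)
  switch(side, both = list(A = object$A, B = object$B),
         pre = object$A, post = object$B)
}

#' Rule matrix implied by the bilinear factors
#'
#' The product \eqn{\hat O = AB^T} is the low-rank reconstruction of the
#' feature-interaction rule matrix used by the spatial connectome model:
#' predictions satisfy \eqn{XA(YB)^T = X \hat O Y^T}. Comparing it with an
#' SCM rule matrix (see [compare_rule_matrices()]) reveals which
#' feature-pair interactions each model captures.
#'
#' @param object a fitted [bilm()] model, or a list with factors `A`, `B`.
#' @return A `p x q` matrix with feature labels on both axes.
#' @export
rule_matrix <- function(object) {
  A <- object$A; B <- object$B
  check_dims(ncol(B), ncol(A), "latent columns of B", "latent columns of A")
  tcrossprod(A, B)
}

#' @export
print.bilm <- function(x, ...) {
  cat(sprintf("Bilinear connectivity model (%s-level)\n", x$variant))
  cat(sprintf("  %d x %d connectivity, %d x %d pre-features, %d x %d post-features\n",
              nrow(x$Z), ncol(x$Z), nrow(x$X), ncol(x$X),
              nrow(x$Y), ncol(x$Y)))
  cat(sprintf("  latent dimension d = %d, lambda_A = %g, lambda_B = %g\n",
              x$d, x$lambda_A, x$lambda_B))
  cat(sprintf("  %s after %d iterations, final loss %.6g\n",
              if (x$converged) "converged" else "iteration cap reached",
              x$n_iter, x$loss[length(x$loss)]))
  invisible(x)
}

#' Summarize a bilinear connectivity model fit
#'
#' Reports the optimization outcome, the unregularized weighted data term,
#' the Pearson correlation between fitted and observed connectivity over
#' pairs with positive weight, and per-dimension factor norms.
#'
#' @param object a fitted [bilm()] model.
#' @param ... unused.
#' @export
summary.bilm <- function(object, ...) {
  zh <- fitted(object)
  keep <- object$W > 0
  r <- if (sum(keep) >= 2 && pop_sd(object$Z[keep]) > 0 &&
           pop_sd(zh[keep]) > 0)
    cor(zh[keep], object$Z[keep]) else NA_real_
  data_term <- sum((object$W * (zh - object$Z))^2)
  out <- list(
    variant = object$variant, d = object$d,
    lambda_A = object$lambda_A, lambda_B = object$lambda_B,
    converged = object$converged, n_iter = object$n_iter,
    final_loss = object$loss[length(object$loss)],
    data_term = data_term, pearson = r,
    dim_norms = cbind(A = sqrt(colSums(object$A^2)),
                      B = sqrt(colSums(object$B^2))),
    n_obs = sum(keep))
  class(out) <- "summary.bilm"
  out
}

#' @export
print.summary.bilm <- function(x, ...) {
  cat(sprintf("Bilinear connectivity model (%s-level), d = %d\n",
              x$variant, x$d))
  cat(sprintf("  lambda_A = %g, lambda_B = %g\n", x$lambda_A, x$lambda_B))
  cat(sprintf("  %s after %d iterations\n",
              if (x$converged) "converged" else "iteration cap reached",
              x$n_iter))
  cat(sprintf("  final loss %.6g (data term %.6g over %d weighted pairs)\n",
              x$final_loss, x$data_term, x$n_obs))
  cat(sprintf("  Pearson r (fitted vs observed): %.4f\n", x$pearson))
  cat("  per-dimension factor norms:\n")
  print(round(x$dim_norms, 4))
  invisible(x)
}

#' Plot the loss trajectory of a bilinear model fit
#'
#' @param x a fitted [bilm()] model.
#' @param log plot the loss on a log axis (default).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bilm <- function(x, log = "y", ...) {
  plot(seq_along(x$loss), x$loss, type = "l", log = log,
       xlab = "iteration", ylab = "loss", ...)
  invisible(x)
}

#' Simulate connectivity matrices from a fitted bilinear model
#'
#' Draws `nsim` matrices as `fitted(object)` plus i.i.d. Gaussian noise
#' whose standard deviation is estimated from the weighted residuals of
#' the fit (pairs with zero weight keep the fitted value).
#'
#' @param object a fitted [bilm()] model.
#' @param nsim number of matrices to draw.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` matrices.
#' @export
simulate.bilm <- function(object, nsim = 1, seed = NULL, ...) {
  zh <- fitted(object)
  keep <- object$W > 0
  s <- if (sum(keep) >= 2) pop_sd((object$Z - zh)[keep]) else 0
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    noise <- matrix(rnorm(length(zh), sd = s), nrow(zh), ncol(zh))
    noise[!keep] <- 0
    zh + noise
  }))
}
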