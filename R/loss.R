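#' Bilinear model loss function
#'
#' Evaluates the regularized reconstruction loss of the bilinear
#' connectivity model for a given pair of transformation matrices. Two
#' penalty forms are supported, matching the two data regimes:
#'
#' * `penalty = "ridge"` (cell level, expression and connectivity observed
#'   on the same cells):
#'   \deqn{L = \|W \odot (Z - XA(YB)^T)\|_F^2 +
#'         \frac{\lambda_A}{2}\|A\|_F^2 + \frac{\lambda_B}{2}\|B\|_F^2}
#' * `penalty = "gram"` (type level, expression and connectivity aligned
#'   only at the level of neuronal types; `X`, `Y` are variance-normalized
#'   type-mean matrices):
#'   \deqn{L = \|W \odot (\bar Z - \hat X\hat A(\hat Y\hat B)^T)\|_F^2 +
#'         \frac{\lambda_A}{2}\|\hat A^T\hat A\|_F^2 +
#'         \frac{\lambda_B}{2}\|\hat B^T\hat B\|_F^2}
#'
#' The Gram-matrix penalty is the Lagrangian surrogate of the constraint
#' that the within-type variance of the latent features stays small after
#' the per-feature 1/sd normalization of the type means.
#'
#' Entries of `Z` where `W == 0` do not contribute to the loss; `W`
#' defaults to all ones (the type-level regime normally has no weights, but
#' a binary `W` is used to hold entries out during cross-validation).
#'
#' @param Z numeric connectivity matrix (`n_pre x n_post`).
#' @param X,Y numeric feature matrices for the pre- and post-synaptic side
#'   (`n_pre x p`, `n_post x q`).
#' @param A,B transformation matrices (`p x d`, `q x d`).
#' @param W optional nonnegative weight matrix, same shape as `Z`.
#' @param lambda_A,lambda_B nonnegative regularization strengths.
#' @param penalty `"ridge"` (cell-level) or `"gram"` (type-level).
#' @return A single nonnegative number.
#' @seealso [bilinear_grad()], [bilm()]
#' @examples
#' X <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(6), 2, 3)
#' A <- matrix(rnorm(6), 3, 2); B <- matrix(rnorm(6), 3, 2)
#' Z <- (X %*% A) %*% t(Y %*% B)
#' bilinear_loss(Z, X, Y, A, B)  # exactly representable: 0
#' @export
bilinear_loss <- function(Z, X, Y, A, B, W = NULL,
                          lambda_A = 0, lambda_B = 0,
                          penalty = c("ridge", "gram")) {
  penalty <- match.arg(penalty)
  d <- check_bilinear_shapes(Z, X, Y, A, B, W)
  W <- W %||% matrix(1, nrow(Z), ncol(Z))
  R <- (X %*% A) %*% t(Y %*% B) - Z
  data_term <- sum((W * R)^2)
  pen <- if (penalty == "gram") {
    0.5 * lambda_A * sum((crossprod(A))^2) +
      0.5 * lambda_B * sum((crossprod(B))^2)
  } else {
    0.5 * lambda_A * sum(A^2) + 0.5 * lambda_B * sum(B^2)
  }
  data_term + pen
}

#' Analytic gradients of the bilinear model loss
#'
#' Returns the exact gradients of [bilinear_loss()] with respect to the two
#' transformation matrices. With residual \eqn{R = XA(YB)^T - Z}:
#' \deqn{\nabla_A = 2 X^T (W \odot W \odot R) YB + \lambda_A A}
#' \deqn{\nabla_B = 2 Y^T (W \odot W \odot R)^T XA + \lambda_B B}
#' for the ridge penalty; the Gram penalty contributes
#' \eqn{2\lambda_A A(A^TA)} and \eqn{2\lambda_B B(B^TB)} instead. Because
#' the weights enter the loss inside the squared Frobenius norm, the true
#' derivative carries the elementwise square of `W`; for the binary contact
#' masks used in practice this is identical to weighting by `W` itself.
#'
#' @inheritParams bilinear_loss
#' @return A list with components `A` (`p x d`) and `B` (`q x d`).
#' @export
bilinear_grad <- function(Z, X, Y, A, B, W = NULL,
                          lambda_A = 0, lambda_B = 0,
                          penalty = c("ridge", "gram")) {
  penalty <- match.arg(penalty)
  check_bilinear_shapes(Z, X, Y, A, B, W)
  W <- W %||% matrix(1, nrow(Z), ncol(Z))
  P <- X %*% A
  Q <- Y %*% B
  M <- (W * W) * (P %*% t(Q) - Z)
  Agrad <- 2 * crossprod(X, M %*% Q)
  Bgrad <- 2 * crossprod(Y, crossprod(M, P))
  if (penalty == "gram") {
    Agrad <- Agrad + 2 * lambda_A * A %*% crossprod(A)
    Bgrad <- Bgrad + 2 * lambda_B * B %*% crossprod(B)
  } else {
    Agrad <- Agrad + lambda_A * A
    Bgrad <- Bgrad + lambda_B * B
  }
  list(A = Agrad, B = Bgrad)
}

# Shared conformance checks; returns the latent dimension d.
check_bilinear_shapes <- function(Z, X, Y, A, B, W = NULL) {
  Z <- as_num_matrix(Z); X <- as_num_matrix(X); Y <- as_num_matrix(Y)
  A <- as_num_matrix(A); B <- as_num_matrix(B)
  check_dims(nrow(X), nrow(Z), "rows of X (pre-synaptic cells)",
             "rows of Z")
  check_dims(nrow(Y), ncol(Z), "rows of Y (post-synaptic cells)",
             "columns of Z")
  check_dims(nrow(A), ncol(X), "rows of A", "feature columns of X")
  check_dims(nrow(B), ncol(Y), "rows of B", "feature columns of Y")
  check_dims(ncol(B), ncol(A), "latent columns of B", "latent columns of A")
  if (!is.null(W)) {
    check_dims(dim(W), dim(Z), "W", "Z")
    if (any(W < 0)) stop("'W' must be nonnegative", call. = FALSE)
  }
  ncol(A)
}
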