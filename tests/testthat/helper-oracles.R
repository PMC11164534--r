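# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: losses are elementwise double sums,
# predictions are triple loops, gradients are central finite differences.

rel_err <- function(a, b) {
  denom <- sqrt(sum(b^2))
  sqrt(sum((a - b)^2)) / max(denom, .Machine$double.xmin)
}

# Elementwise double-sum of the cell-level loss.
brute_loss_cell <- function(Z, X, Y, A, B, W, lambda_A, lambda_B) {
  total <- 0
  for (i in seq_len(nrow(Z))) {
    for (j in seq_len(ncol(Z))) {
      pred <- sum((X[i, ] %*% A) * (Y[j, ] %*% B))
      total <- total + (W[i, j] * (Z[i, j] - pred))^2
    }
  }
  total + lambda_A / 2 * sum(A^2) + lambda_B / 2 * sum(B^2)
}

# Elementwise type-level loss with Gram penalties.
brute_loss_type <- function(Zbar, Xh, Yh, A, B, lambda_A, lambda_B) {
  total <- 0
  for (i in seq_len(nrow(Zbar))) {
    for (j in seq_len(ncol(Zbar))) {
      pred <- sum((Xh[i, ] %*% A) * (Yh[j, ] %*% B))
      total <- total + (Zbar[i, j] - pred)^2
    }
  }
  GA <- t(A) %*% A; GB <- t(B) %*% B
  total + lambda_A / 2 * sum(GA^2) + lambda_B / 2 * sum(GB^2)
}

# Triple-loop bilinear prediction.
brute_predict <- function(X, Y, A, B) {
  out <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(nrow(Y)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + sum(X[i, ] * A[, k]) * sum(Y[j, ] * B[, k])
  out
}

# Central finite differences of a scalar function of (A, B).
fd_grad <- function(f, A, B, eps = 1e-6) {
  gA <- A * 0; gB <- B * 0
  for (i in seq_along(A)) {
    Ap <- A; Am <- A
    Ap[i] <- Ap[i] + eps; Am[i] <- Am[i] - eps
    gA[i] <- (f(Ap, B) - f(Am, B)) / (2 * eps)
  }
  for (i in seq_along(B)) {
    Bp <- B; Bm <- B
    Bp[i] <- Bp[i] + eps; Bm[i] <- Bm[i] - eps
    gB[i] <- (f(A, Bp) - f(A, Bm)) / (2 * eps)
  }
  list(A = gA, B = gB)
}

# Small random instance shared by loss/gradient tests.
rand_instance <- function(n = 4, m = 3, p = 3, q = 2, d = 2, seed = 1,
                          weights = c("ones", "random", "binary")) {
  weights <- match.arg(weights)
  set.seed(seed)
  W <- switch(weights,
              ones = matrix(1, n, m),
              random = matrix(runif(n * m, 0.2, 2), n, m),
              binary = matrix(rbinom(n * m, 1, 0.7), n, m))
  list(X = matrix(rnorm(n * p), n, p), Y = matrix(rnorm(m * q), m, q),
       Z = matrix(rnorm(n * m), n, m), W = W,
       A = matrix(rnorm(p * d), p, d), B = matrix(rnorm(q * d), q, d))
}
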