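sym_instance <- function(n = 10, p = 3, seed = 1, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("n", seq_len(n)), paste0("g", seq_len(p))))
  M <- matrix(rnorm(p * p), p, p)
  O <- (M + t(M)) / 2
  Z <- X %*% O %*% t(X)
  if (noise > 0) {
    E <- matrix(rnorm(n * n, sd = noise), n, n)
    Z <- Z + (E + t(E)) / 2
  }
  list(X = X, O = O, Z = Z)
}

test_that("Kronecker design rows reproduce x_i O x_j'", {
  # basis-vector hand case: symmetric row (0, 1/2, 1/2, 0)
  X <- rbind(a = c(1, 0), b = c(0, 1))
  edges <- data.frame(pre = "a", post = "b", connectivity = 1)
  kd <- kronecker_design(X, edges, symmetric = TRUE)
  expect_equal(as.numeric(kd$design), c(0, 0.5, 0.5, 0))

  # all-ones features give an all-ones row
  X1 <- rbind(a = c(1, 1), b = c(1, 1))
  kd1 <- kronecker_design(X1, edges, symmetric = TRUE)
  expect_equal(as.numeric(kd1$design), rep(1, 4))

  # random p = 3: design %*% vec(O) equals the loop-computed quadratic form
  inst <- sym_instance(n = 6, p = 3, seed = 2)
  e <- edge_list(inst$Z, symmetric = FALSE)
  kd <- kronecker_design(inst$X, e, symmetric = FALSE)
  O <- matrix(rnorm(9), 3, 3)
  loop <- vapply(seq_len(nrow(e)), function(r) {
    i <- match(e$pre[r], rownames(inst$X))
    j <- match(e$post[r], rownames(inst$X))
    as.numeric(inst$X[i, ] %*% O %*% inst$X[j, ])
  }, 0)
  expect_equal(as.numeric(kd$design %*% as.vector(O)), loop,
               tolerance = 1e-12)

  expect_error(
    kronecker_design(inst$X, data.frame(pre = "zz", post = "n1",
                                        connectivity = 0)),
    "absent")
})

test_that("ridge regression recovers a realizable rule matrix", {
  inst <- sym_instance(n = 12, p = 4, seed = 3)
  fit <- scm(inst$Z, inst$X, lambda = 1e-10)
  expect_lt(rel_err(fit$O, inst$O), 1e-6)
  expect_equal(fit$O, t(fit$O))  # constrained symmetric

  # penalty domination: entries shrink to zero as lambda grows
  big <- scm(inst$Z, inst$X, lambda = 1e10)
  expect_lt(max(abs(big$O)), 1e-4)

  # ||O(lambda)||_F is non-increasing in lambda
  norms <- vapply(c(0.01, 0.1, 1, 10, 100),
                  function(l) norm(scm(inst$Z, inst$X, lambda = l)$O, "F"),
                  0)
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("ridge solution matches the augmented least-squares oracle", {
  inst <- sym_instance(n = 8, p = 3, seed = 4, noise = 0.3)
  e <- edge_list(inst$Z, symmetric = TRUE)
  kd <- kronecker_design(inst$X, e, symmetric = TRUE)
  lambda <- 0.7
  # oracle: ordinary least squares on the ridge-augmented system
  Daug <- rbind(kd$design, sqrt(lambda) * diag(ncol(kd$design)))
  taug <- c(kd$targets, rep(0, ncol(kd$design)))
  v <- qr.solve(Daug, taug)
  O_oracle <- matrix(v, 3, 3)
  O_oracle <- (O_oracle + t(O_oracle)) / 2
  O_fit <- scm_ridge(kd$design, kd$targets, lambda, p = 3)
  expect_lt(rel_err(O_fit, O_oracle), 1e-8)
})

test_that("a singular system at lambda = 0 points the user at ridge", {
  # 2 edges cannot identify 9 rule coefficients
  inst <- sym_instance(n = 3, p = 3, seed = 5)
  contact <- matrix(0, 3, 3)
  contact[1, 2] <- contact[2, 1] <- contact[1, 3] <- contact[3, 1] <- 1
  expect_error(scm(inst$Z, inst$X, contact = contact, lambda = 0),
               "lambda > 0")
})

test_that("discrepancy score identities and properties hold", {
  expect_equal(discrepancy_score(1, 1), 0)
  expect_equal(discrepancy_score(1, -1), 1)
  expect_equal(discrepancy_score(0.3, 0.1), 0.5)
  expect_equal(discrepancy_score(0, 0), 0)

  set.seed(6)
  x <- rnorm(200); y <- rnorm(200)
  ds <- discrepancy_score(x, y)
  expect_true(all(ds >= 0 & ds <= 1))
  expect_equal(ds, discrepancy_score(y, x))           # symmetry
  expect_equal(ds, discrepancy_score(3 * x, 3 * y))   # scale invariance
})

test_that("divergent entries are flagged above threshold and floor", {
  # both magnitudes below the floor: high DS but filtered out
  rep1 <- discrepancy_report(matrix(0.05), matrix(0.01))
  expect_false(rep1$flagged[1, 1])
  # equal entries: DS = 0, never flagged
  rep2 <- discrepancy_report(matrix(0.5), matrix(0.5))
  expect_false(rep2$flagged[1, 1])
  # DS = 0.45/0.55 ~ 0.818 with one magnitude above floor: flagged
  rep3 <- discrepancy_report(matrix(0.5), matrix(0.05))
  expect_equal(rep3$ds[1, 1], 0.45 / 0.55, tolerance = 1e-12)
  expect_true(rep3$flagged[1, 1])
  expect_output(print(rep3), "flagged")
})

test_that("rule-matrix comparison reports Pearson r and the flag report", {
  set.seed(7)
  O <- matrix(rnorm(16), 4, 4)
  expect_equal(compare_rule_matrices(O, O)$pearson, 1)
  expect_equal(compare_rule_matrices(-O, O)$pearson, -1)
  O2 <- matrix(rnorm(16), 4, 4)
  direct <- sum((O - mean(O)) * (O2 - mean(O2))) /
    sqrt(sum((O - mean(O))^2) * sum((O2 - mean(O2))^2))
  expect_equal(compare_rule_matrices(O, O2)$pearson, direct,
               tolerance = 1e-12)
  expect_error(compare_rule_matrices(matrix(1, 2, 2), O[1:2, 1:2]),
               "zero variance")
})

test_that("SCM ridge strength is selected by entry-level cross-validation", {
  inst <- sym_instance(n = 12, p = 3, seed = 9)
  cv1 <- cv_scm(inst$Z, inst$X, lambda_grid = c(0.01, 1, 100), k = 5,
                seed = 2)
  cv2 <- cv_scm(inst$Z, inst$X, lambda_grid = c(0.01, 1, 100), k = 5,
                seed = 2)
  expect_identical(cv1, cv2)
  # noise-free realizable targets: the weakest ridge generalizes best
  expect_equal(cv1$selected$lambda, 0.01)
  expect_true(all(diff(cv1$grid$mean_val_loss) >= 0))
})

test_that("bilinear fit at full latent dimension matches the SCM", {
  inst <- sym_instance(n = 12, p = 4, seed = 8)
  sf <- scm(inst$Z, inst$X, lambda = 1e-8)
  bf <- bilm(inst$Z, inst$X, inst$X, d = 4, lambda = 1e-8, rate = 1e-6,
             tol = 1e-14, max_iter = 2e5, seed = 1)
  expect_lt(rel_err(fitted(bf), predict(sf, inst$X)), 1e-3)
  expect_gt(matrix_pearson(rule_matrix(bf), sf$O), 0.99)
})
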