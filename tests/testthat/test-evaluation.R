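test_that("ROC-AUC handles perfect, inverted and tied rankings", {
  truth <- c(1, 1, 1, 0, 0, 0)
  perfect <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  expect_equal(roc_auc(perfect, truth)$auc, 1)
  expect_equal(roc_auc(perfect, 1 - truth)$auc, 0)

  # hand case with one tie, against exhaustive pair enumeration
  scores <- c(0.9, 0.5, 0.5, 0.5, 0.2, 0.1)
  truth2 <- c(1, 1, 0, 0, 1, 0)
  pairs <- expand.grid(p = which(truth2 == 1), n = which(truth2 == 0))
  brute <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                       ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(scores, truth2)$auc, brute)

  # invariance under strictly increasing transforms
  set.seed(1)
  s <- rnorm(60); y <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(exp(2 * s) + 5, y)$auc, roc_auc(s, y)$auc)

  # the curve starts at (0, 0) and ends at (1, 1)
  cv <- roc_auc(s, y)$curve
  expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))

  # masked entries are excluded
  m <- c(rep(1, 40), rep(0, 20))
  expect_equal(roc_auc(s, y, mask = m)$auc, roc_auc(s[1:40], y[1:40])$auc)

  expect_error(roc_auc(s, rep(1, 60)), "one class")
})

test_that("ROC-AUC agrees with the pROC reference implementation", {
  set.seed(2)
  s <- round(rnorm(80), 1)  # rounding forces ties
  y <- rbinom(80, 1, 0.5)
  ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("matrix Pearson correlation is affine invariant and exact", {
  set.seed(3)
  M <- matrix(rnorm(24), 4, 6)
  expect_equal(matrix_pearson(M, M), 1)
  expect_equal(matrix_pearson(2 * M + 3, M), 1)
  M2 <- matrix(rnorm(24), 4, 6)
  direct <- sum((M - mean(M)) * (M2 - mean(M2))) /
    sqrt(sum((M - mean(M))^2) * sum((M2 - mean(M2))^2))
  expect_equal(matrix_pearson(M, M2), direct, tolerance = 1e-12)
  expect_error(matrix_pearson(matrix(1, 2, 2), M[1:2, 1:2]), "constant")
  # masked version drops excluded entries
  mask <- matrix(rbinom(24, 1, 0.6), 4, 6)
  expect_equal(matrix_pearson(M, M2, mask),
               cor(M[mask > 0], M2[mask > 0]))
})

test_that("cross-validation is deterministic and penalizes misfit", {
  sim <- simulate_bilinear(bilinear_scenario(
    a = 10, b = 8, cells_per_type = 1, p = 4, q = 4, d_true = 2,
    within_type_sd = 0, connectivity_noise_sd = 0.1, seed = 21))
  run <- function()
    cv_bilm(sim$Z, sim$X, sim$Y, lambda_grid = c(0.001, 1), d_grid = 1:3,
            k = 4, seed = 5, variant = "cell", rate = 1e-5, tol = 1e-9,
            max_iter = 2e4)
  cv1 <- run(); cv2 <- run()
  expect_identical(cv1$grid, cv2$grid)
  expect_identical(cv1$selected, cv2$selected)
  expect_identical(nrow(cv1$grid), 6L)

  # an enormous penalty drives the fit toward the zero predictor
  cv_big <- cv_bilm(sim$Z, sim$X, sim$Y, lambda_grid = 1e8, d_grid = 2,
                    k = 4, seed = 5, variant = "cell", rate = 1e-6,
                    tol = 1e-9, max_iter = 5e3)
  zero_loss <- sum(sim$Z^2) / 4  # zero-predictor loss per fold
  expect_gt(cv_big$grid$mean_val_loss, 0.5 * zero_loss)
  expect_lt(cv_big$grid$mean_val_loss, 2 * zero_loss)

  expect_error(cv_bilm(sim$Z[1:2, 1:2, drop = FALSE], sim$X[1:2, ],
                       sim$Y[1:2, ], lambda_grid = 1, d_grid = 1,
                       k = 50), "reduce k")
})

test_that("cross-validation recovers the generating latent dimension", {
  hits <- 0L
  for (r in 1:3) {
    sim <- simulate_bilinear(bilinear_scenario(
      a = 15, b = 12, cells_per_type = 1, p = 6, q = 6, d_true = 2,
      within_type_sd = 0, connectivity_noise_sd = 0.1, seed = 300 + r))
    cv <- suppressWarnings(
      cv_bilm(sim$Z, sim$X, sim$Y, lambda_grid = 1e-3, d_grid = 1:4,
              k = 5, seed = r, variant = "cell", rate = 1e-6,
              tol = 1e-9, max_iter = 2e4))
    if (cv$selected$d == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("consistency scoring is invariant to signed column permutations", {
  set.seed(4)
  base <- list(A = matrix(rnorm(12), 6, 2), B = matrix(rnorm(10), 5, 2))
  expect_equal(consistency_across_runs(list(base, base))$min, 1)

  flipped <- list(A = -base$A, B = -base$B)
  expect_equal(consistency_across_runs(list(base, flipped))$min, 1)

  swapped <- list(A = base$A[, 2:1], B = base$B[, 2:1])
  expect_equal(consistency_across_runs(list(base, swapped))$min, 1)

  # general signed permutation applied to both factors, d = 3
  b3 <- list(A = matrix(rnorm(18), 6, 3), B = matrix(rnorm(15), 5, 3))
  P <- diag(c(1, -1, -1))[, c(3, 1, 2)]
  tr <- list(A = b3$A %*% P, B = b3$B %*% P)
  cs <- consistency_across_runs(list(b3, tr, b3))
  expect_equal(cs$min, 1, tolerance = 1e-12)
  expect_equal(cs$pairwise, t(cs$pairwise))
  expect_equal(diag(cs$pairwise), rep(1, 3))

  expect_error(consistency_across_runs(list(base, b3)), "disagree")
})

test_that("missed connections count sign disagreements on positives", {
  set.seed(5)
  Z <- matrix(rnorm(9), 3, 3)
  expect_equal(missed_connections(Z, Z)$n_missed, 0)

  Zpos <- abs(Z)
  mc <- missed_connections(-Zpos, Zpos)
  expect_equal(mc$n_missed, mc$n_positive)

  # hand case: 5 positives, 2 of them reconstructed nonpositive
  Zt <- matrix(c(1, 1, 1, 1, 1, -2, -2, 0, -1), 3, 3)
  Zh <- matrix(c(-1, 1, 1, 1, -0.5, 1, 1, 1, 1), 3, 3)
  mc2 <- missed_connections(Zh, Zt)
  expect_equal(mc2$n_positive, 5)
  expect_equal(mc2$n_missed, 2)
  expect_equal(mc2$ds_map, discrepancy_score(Zh, Zt))
})
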