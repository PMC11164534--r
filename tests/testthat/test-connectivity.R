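test_that("profile cosine matches hand values and is scale invariant", {
  expect_equal(profile_cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(profile_cosine(c(1, 0, 0), c(0, 0, 2)), 0)
  expect_equal(profile_cosine(c(1, 0, 1), c(1, 1, 0)), 0.5)
  u <- c(0.2, 0.5, 0.1); v <- c(0.4, 0.1, 0.6)
  expect_equal(profile_cosine(7 * u, v), profile_cosine(u, v))
  expect_error(profile_cosine(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(profile_cosine(c(1, 1), c(1, 1, 1)), "grid")
})

test_that("cell connectivity matrix holds pairwise cosines in [0, 1]", {
  pre <- rbind(p1 = c(1, 0, 1), p2 = c(2, 0, 2))
  post <- rbind(q1 = c(1, 1, 0), q2 = c(1, 0, 1))
  Z <- build_cell_connectivity(pre, post)
  expect_equal(Z["p1", "q1"], 0.5)
  expect_equal(Z["p1", "q2"], 1)
  expect_equal(Z["p2", "q1"], 0.5)  # scaling a profile changes nothing
  expect_true(all(Z >= 0 & Z <= 1))

  # identical profiles everywhere give the all-ones matrix
  same <- rbind(a = c(1, 2), b = c(2, 4))
  expect_true(all(abs(build_cell_connectivity(same, same) - 1) < 1e-12))

  bad <- rbind(ok = c(1, 1), dead = c(0, 0))
  expect_error(build_cell_connectivity(bad, same), "dead")
})

test_that("standardization centers and scales; degenerate input errors", {
  Z <- matrix(c(0, 2), 2, 1)
  expect_equal(standardize_connectivity(Z), matrix(c(-1, 1), 2, 1))
  set.seed(1)
  Z2 <- matrix(rnorm(20, 5, 3), 4, 5)
  S <- standardize_connectivity(Z2)
  expect_equal(mean(S), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((S - mean(S))^2)), 1, tolerance = 1e-12)
  expect_equal(standardize_connectivity(S), S, tolerance = 1e-12)
  expect_error(standardize_connectivity(matrix(3, 2, 2)), "constant")
})

test_that("type averaging reduces to grouped means", {
  # one cell per type: output equals input
  Z <- matrix(1:6, 2, 3)
  out <- average_by_type(Z, c("a", "b"), c("x", "y", "z"))
  expect_equal(unname(out), Z)

  # two pre cells (0, 2) onto one post cell average to 1
  expect_equal(as.numeric(average_by_type(matrix(c(0, 2), 2, 1),
                                          c("t", "t"), "u")), 1)

  # nested-loop oracle on a random instance
  set.seed(2)
  Z3 <- matrix(rnorm(35), 5, 7)
  pre <- sample(c("p1", "p2"), 5, replace = TRUE)
  post <- sample(c("q1", "q2", "q3"), 7, replace = TRUE)
  out <- average_by_type(Z3, pre, post)
  for (i in unique(pre))
    for (j in unique(post))
      expect_equal(out[i, j], mean(Z3[pre == i, post == j]),
                   tolerance = 1e-12)
})

test_that("weight matrices implement contact and type-balance modes", {
  mask <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_identical(weight_matrix("contact", contact = mask), mask)
  expect_error(weight_matrix("contact"), "contact")
  expect_error(weight_matrix("contact", contact = matrix(0.5, 2, 2)),
               "binary")

  # all singleton types: every weight is 1
  W <- weight_matrix("type_balance", pre_types = c("a", "b"),
                     post_types = c("x", "y", "z"))
  expect_true(all(W == 1))

  # n_i = 2, n_j = 5: weights 1/10
  W2 <- weight_matrix("type_balance", pre_types = rep("a", 2),
                      post_types = rep("x", 5))
  expect_true(all(abs(W2 - 0.1) < 1e-15))

  # each cell-pair weight is 1/(n_i n_j), so every row of a type-i cell
  # sums to (number of post types) / n_i
  pre <- rep(c("a", "b"), c(2, 3))
  post <- rep(c("x", "y"), c(1, 4))
  W3 <- weight_matrix("type_balance", pre_types = pre, post_types = post)
  for (r in seq_along(pre)) {
    n_i <- sum(pre == pre[r])
    expect_equal(sum(W3[r, ]), 2 / n_i, tolerance = 1e-12)
  }
  # and the total weight equals a * b over the whole matrix
  expect_equal(sum(W3), 2 * 2, tolerance = 1e-12)
})

test_that("museum-style records parse, resample and round-trip", {
  grid <- ipl_depth_grid(5)  # 0, .25, .5, .75, 1
  rec_exact <- list(
    `cell id` = "c1", `cell type` = "T1", `cell class` = "pre",
    stratification = lapply(seq_along(grid), function(g)
      list(depth = grid[g], value = g)))
  out <- parse_stratification(list(rec_exact), grid = grid)
  expect_equal(as.numeric(out$density), 1:5)  # on-grid values unchanged

  # coarser grid: linear interpolation, hand-checked at 3 points
  rec_coarse <- list(
    `cell id` = "c2", `cell type` = "T2", `cell class` = "pre",
    stratification = list(list(depth = 0, value = 0),
                          list(depth = 0.5, value = 2),
                          list(depth = 1, value = 1)))
  out2 <- parse_stratification(list(rec_coarse), grid = grid)
  expect_equal(as.numeric(out2$density), c(0, 1, 2, 1.5, 1))

  # a record without stratification is skipped with a warning
  rec_empty <- list(`cell id` = "c3", `cell type` = "T3",
                    `cell class` = "pre", stratification = list())
  expect_warning(
    out3 <- parse_stratification(list(rec_exact, rec_empty), grid = grid),
    "skipped")
  expect_identical(out3$n_skipped, 1L)
  expect_identical(out3$cell_ids, "c1")

  expect_error(parse_stratification(list(list(`cell id` = "x"))),
               "index 1")

  # JSON round trip through the writer and reader
  tmp <- tempfile(fileext = ".json")
  write_museum_json(list(rec_exact, rec_coarse), tmp)
  back <- read_museum_json(tmp, grid = grid)
  expect_equal(as.numeric(back$density[1, ]), 1:5, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(back$density[2, ]), c(0, 1, 2, 1.5, 1),
               tolerance = 1e-12)
  expect_identical(back$cell_ids, c("c1", "c2"))
})

test_that("generated Gaussian bumps match a quadrature oracle", {
  grid <- ipl_depth_grid(120)
  sim <- simulate_stratification(n_types_pre = 2, n_types_post = 1,
                                 cells_per_type = 1, grid = grid,
                                 centers = list(pre = c(0.35, 0.45),
                                                post = 0.35),
                                 width = 0.05, jitter_sd = 0, seed = 1)
  prof <- parse_stratification(sim$records, grid = grid)
  Z <- build_cell_connectivity(prof$density[1:2, ],
                               prof$density[3, , drop = FALSE])
  # continuous-overlap oracle for two Gaussian bumps
  overlap <- function(m1, m2, s) {
    num <- integrate(function(x) dnorm(x, m1, s) * dnorm(x, m2, s),
                     -Inf, Inf)$value
    den <- integrate(function(x) dnorm(x, m1, s)^2, -Inf, Inf)$value
    num / den
  }
  expect_equal(Z[1, 1], 1, tolerance = 1e-6)   # identical bumps
  expect_equal(Z[2, 1], overlap(0.45, 0.35, 0.05), tolerance = 1e-3)

  # well-separated bumps are near orthogonal
  far <- simulate_stratification(n_types_pre = 1, n_types_post = 1,
                                 cells_per_type = 1, grid = grid,
                                 centers = list(pre = 0.15, post = 0.85),
                                 width = 0.04, jitter_sd = 0, seed = 2)
  pf <- parse_stratification(far$records, grid = grid)
  Zf <- build_cell_connectivity(pf$density[1, , drop = FALSE],
                                pf$density[2, , drop = FALSE])
  expect_lt(Zf[1, 1], 1e-6)
})
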