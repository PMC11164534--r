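#' Define a synthetic bilinear connectivity scenario
#'
#' Bundles the parameters of the ground-truth generative model used for
#' recovery tests. Defaults mirror the shape of the retina problem
#' (25 presynaptic x 12 postsynaptic types) with mild within-type
#' expression noise and connectivity noise.
#'
#' @param a,b numbers of pre- and post-synaptic types.
#' @param cells_per_type cells per type (scalar, or list with `pre` and
#'   `post` vectors of per-type counts).
#' @param p,q feature counts per side.
#' @param d_true latent dimension of the generating rule
#'   (`d_true <= min(p, q)`).
#' @param within_type_sd sd of the Gaussian cell-level deviation around
#'   the type-mean features.
#' @param connectivity_noise_sd sd of the additive Gaussian noise on the
#'   cell-level connectivity.
#' @param contact_density probability in `(0, 1]` that a cell pair is in
#'   physical contact (Bernoulli mask).
#' @param seed integer seed; all generator output is a pure function of
#'   the scenario.
#' @return An object of class `"bilinear_scenario"`.
#' @export
bilinear_scenario <- function(a = 25, b = 12, cells_per_type = 20,
                              p = 30, q = 30, d_true = 2,
                              within_type_sd = 0.05,
                              connectivity_noise_sd = 0.05,
                              contact_density = 1, seed = 1) {
  if (a < 1 || b < 1 || p < 1 || q < 1 || d_true < 1)
    stop("all counts must be at least 1", call. = FALSE)
  if (d_true > min(p, q))
    stop("'d_true' cannot exceed min(p, q)", call. = FALSE)
  if (contact_density <= 0 || contact_density > 1)
    stop("'contact_density' must lie in (0, 1]", call. = FALSE)
  cpt <- if (is.list(cells_per_type)) cells_per_type else
    list(pre = rep(cells_per_type, a), post = rep(cells_per_type, b))
  if (length(cpt$pre) != a || length(cpt$post) != b ||
      any(c(cpt$pre, cpt$post) < 1))
    stop("'cells_per_type' must give >= 1 cells for every type",
         call. = FALSE)
  structure(list(a = a, b = b, cells_per_type = cpt, p = p, q = q,
                 d_true = d_true, within_type_sd = within_type_sd,
                 connectivity_noise_sd = connectivity_noise_sd,
                 contact_density = contact_density, seed = seed),
            class = "bilinear_scenario")
}

#' @export
print.bilinear_scenario <- function(x, ...) {
  cat(sprintf("Bilinear scenario: %d x %d types, %d/%d features, d_true = %d, seed = %d\n",
              x$a, x$b, x$p, x$q, x$d_true, x$seed))
  invisible(x)
}

#' Generate a synthetic bilinear connectivity instance
#'
#' Draws a full ground-truth instance of the generative model the
#' bilinear fit assumes: type-mean features are standard normal, cell
#' features are the type mean plus Gaussian within-type noise, the true
#' transformation matrices are standard normal, and the cell-level
#' connectivity is \eqn{XA^*(YB^*)^T} plus Gaussian noise. A Bernoulli
#' contact mask with the scenario's density provides the weight matrix.
#'
#' @param scenario a [bilinear_scenario()].
#' @return A list with cell matrices `X` (`sum(n_i) x p`), `Y`, type
#'   labels `pre_types`, `post_types`, true factors `A_true`, `B_true`,
#'   cell-level connectivity `Z` (noisy) and `W` (contact mask), the
#'   noise-free type-mean matrices `X_type`, `Y_type`, and the
#'   ground-truth type-level connectivity
#'   `Z_type_true = X_type A* (Y_type B*)^T`.
#' @export
simulate_bilinear <- function(scenario) {
  if (!inherits(scenario, "bilinear_scenario"))
    stop("'scenario' must come from bilinear_scenario()", call. = FALSE)
  s <- scenario
  with_seed(s$seed, {
    X_type <- matrix(rnorm(s$a * s$p), s$a, s$p,
                     dimnames = list(paste0("preT", seq_len(s$a)), NULL))
    Y_type <- matrix(rnorm(s$b * s$q), s$b, s$q,
                     dimnames = list(paste0("postT", seq_len(s$b)), NULL))
    A_true <- matrix(rnorm(s$p * s$d_true), s$p, s$d_true)
    B_true <- matrix(rnorm(s$q * s$d_true), s$q, s$d_true)
    pre_types <- rep(rownames(X_type), s$cells_per_type$pre)
    post_types <- rep(rownames(Y_type), s$cells_per_type$post)
    X <- X_type[pre_types, , drop = FALSE] +
      matrix(rnorm(length(pre_types) * s$p, sd = s$within_type_sd),
             length(pre_types), s$p)
    Y <- Y_type[post_types, , drop = FALSE] +
      matrix(rnorm(length(post_types) * s$q, sd = s$within_type_sd),
             length(post_types), s$q)
    rownames(X) <- paste0("pre", seq_along(pre_types))
    rownames(Y) <- paste0("post", seq_along(post_types))
    Z <- (X %*% A_true) %*% t(Y %*% B_true)
    if (s$connectivity_noise_sd > 0)
      Z <- Z + matrix(rnorm(length(Z), sd = s$connectivity_noise_sd),
                      nrow(Z), ncol(Z))
    W <- if (s$contact_density < 1)
      matrix(rbinom(length(Z), 1, s$contact_density), nrow(Z), ncol(Z))
    else matrix(1, nrow(Z), ncol(Z))
    list(X = X, Y = Y, pre_types = pre_types, post_types = post_types,
         A_true = A_true, B_true = B_true, Z = Z, W = W,
         X_type = X_type, Y_type = Y_type,
         Z_type_true = (X_type %*% A_true) %*% t(Y_type %*% B_true),
         scenario = s)
  })
}

#' Generate a synthetic count matrix with planted variable genes
#'
#' Draws Poisson counts with per-cell library-size factors and, on a
#' planted subset of genes, type-specific expression programs that make
#' those genes genuinely overdispersed across cells. The planted set is
#' returned so highly-variable-gene selection can be scored against
#' ground truth.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_types number of cell types.
#' @param n_hv_genes number of planted high-dispersion genes
#'   (`<= n_genes`).
#' @param base_rate baseline expected count per gene before library-size
#'   scaling.
#' @param effect multiplicative spread of the type programs on planted
#'   genes (larger = stronger dispersion).
#' @param library_size_range range of per-cell library-size factors
#'   (uniform draw).
#' @param seed integer seed.
#' @return A list with `counts` (cells x genes, integer), `types`,
#'   `hv_genes` (planted gene names) and `size_factors`.
#' @export
simulate_counts <- function(n_cells = 300, n_genes = 200, n_types = 5,
                            n_hv_genes = 20, base_rate = 5, effect = 4,
                            library_size_range = c(0.5, 2), seed = 1) {
  if (n_hv_genes > n_genes)
    stop("'n_hv_genes' cannot exceed 'n_genes'", call. = FALSE)
  with_seed(seed, {
    types <- sample(paste0("type", seq_len(n_types)), n_cells,
                    replace = TRUE)
    size <- runif(n_cells, library_size_range[1], library_size_range[2])
    rate <- matrix(base_rate, n_cells, n_genes)
    hv <- if (n_hv_genes > 0) seq_len(n_hv_genes) else integer()
    if (length(hv) > 0) {
      # per-type multiplicative programs on the planted genes
      prog <- matrix(exp(rnorm(n_types * length(hv), sd = log(effect))),
                     n_types, length(hv))
      rate[, hv] <- rate[, hv] *
        prog[match(types, paste0("type", seq_len(n_types))), , drop = FALSE]
    }
    counts <- matrix(rpois(n_cells * n_genes, rate * size),
                     n_cells, n_genes,
                     dimnames = list(paste0("cell", seq_len(n_cells)),
                                     paste0("gene", seq_len(n_genes))))
    list(counts = counts, types = types,
         hv_genes = colnames(counts)[hv], size_factors = size)
  })
}

#' Generate museum-style stratification records
#'
#' Assigns each type a Gaussian-bump profile on the IPL depth grid (bump
#' center and width drawn per type); individual cells jitter the center
#' and width. Records are emitted in the museum JSON structure
#' (`"cell id"`, `"cell type"`, `"cell class"`, `"stratification"`), so
#' [parse_stratification()] is exercised end to end.
#'
#' @param n_types_pre,n_types_post type counts per side.
#' @param cells_per_type cells per type.
#' @param grid depth grid the profiles are sampled on.
#' @param centers optional list with `pre`/`post` bump centers in
#'   `[0, 1]` (drawn uniformly when absent).
#' @param width bump standard deviation in depth units.
#' @param jitter_sd cell-level jitter sd applied to the bump center.
#' @param seed integer seed.
#' @return A list with `records` (list of museum-style records covering
#'   both sides), `pre_ids`, `post_ids`, and the per-type ground-truth
#'   bump `centers`.
#' @export
simulate_stratification <- function(n_types_pre = 4, n_types_post = 3,
                                    cells_per_type = 5,
                                    grid = ipl_depth_grid(),
                                    centers = NULL, width = 0.06,
                                    jitter_sd = 0.01, seed = 1) {
  with_seed(seed, {
    ctr <- centers %||% list(pre = runif(n_types_pre),
                             post = runif(n_types_post))
    stopifnot(all(unlist(ctr) >= 0 & unlist(ctr) <= 1))
    make_side <- function(n_types, centers, side) {
      recs <- list(); ids <- character()
      for (t in seq_len(n_types)) {
        for (c_ in seq_len(cells_per_type)) {
          mu <- centers[t] + rnorm(1, sd = jitter_sd)
          sdv <- width * exp(rnorm(1, sd = jitter_sd))
          prof <- dnorm(grid, mean = mu, sd = sdv)
          id <- sprintf("%s_t%d_c%d", side, t, c_)
          ids <- c(ids, id)
          recs[[length(recs) + 1L]] <- list(
            `cell id` = id,
            `cell type` = sprintf("%s_type%d", side, t),
            `cell class` = side,
            stratification = lapply(seq_along(grid), function(g)
              list(depth = grid[g], value = prof[g])))
        }
      }
      list(records = recs, ids = ids)
    }
    pre <- make_side(n_types_pre, ctr$pre, "pre")
    post <- make_side(n_types_post, ctr$post, "post")
    list(records = c(pre$records, post$records),
         pre_ids = pre$ids, post_ids = post$ids, centers = ctr,
         grid = grid)
  })
}
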