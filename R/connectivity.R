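#' Default IPL depth grid
#'
#' Stratification profiles are resampled onto a common grid of 120 evenly
#' spaced points on normalized inner-plexiform-layer depth \[0, 1\] before
#' any similarity computation.
#'
#' @param n number of grid points.
#' @export
ipl_depth_grid <- function(n = 120) seq(0, 1, length.out = n)

# Landmark depths used only for reporting/grouping, never for computation:
# ON/OFF starburst amacrine laminae and the outer/inner IPL boundary.
ipl_landmarks <- function() c(off_sac = 0.28, on_sac = 0.62, outer_inner = 0.47)

#' Parse museum-style stratification records
#'
#' Each record is expected to carry `"cell id"`, `"cell type"`,
#' `"cell class"` and `"stratification"`, the latter a list of
#' `{"depth", "value"}` points giving the linear density of voxel volume
#' as a function of IPL depth. Profiles are linearly interpolated onto
#' `grid` (values outside a record's depth range become 0). Records with
#' a missing or empty stratification are skipped with a warning.
#'
#' @param records a list of records (e.g. from [jsonlite::fromJSON()] with
#'   `simplifyVector = FALSE`).
#' @param grid common depth grid (default [ipl_depth_grid()]).
#' @return An object of class `"strat_profiles"`: list with `density`
#'   (cells x grid matrix), `depth` (the grid), `cell_ids`, `cell_types`,
#'   `cell_class` and `n_skipped`.
#' @export
parse_stratification <- function(records, grid = ipl_depth_grid()) {
  if (!is.list(records)) stop("'records' must be a list", call. = FALSE)
  ids <- character(); types <- character(); classes <- character()
  rows <- list(); skipped <- 0L
  for (k in seq_along(records)) {
    rec <- records[[k]]
    if (!is.list(rec) || is.null(rec[["cell id"]]) ||
        is.null(rec[["cell type"]]))
      stop("malformed record at index ", k,
           ": needs 'cell id' and 'cell type'", call. = FALSE)
    strat <- rec[["stratification"]]
    if (is.null(strat) || length(strat) == 0) { skipped <- skipped + 1L; next }
    if (is.list(strat)) {
      depth <- vapply(strat, function(s) as.numeric(s[["depth"]]), 0)
      value <- vapply(strat, function(s) as.numeric(s[["value"]]), 0)
    } else stop("malformed stratification in record ", k, call. = FALSE)
    if (anyNA(depth) || anyNA(value))
      stop("malformed stratification in record ", k, call. = FALSE)
    prof <- approx(depth, value, xout = grid, rule = 1)$y
    prof[is.na(prof)] <- 0
    ids <- c(ids, as.character(rec[["cell id"]]))
    types <- c(types, as.character(rec[["cell type"]]))
    classes <- c(classes, as.character(rec[["cell class"]] %||% NA))
    rows[[length(rows) + 1L]] <- prof
  }
  if (skipped > 0)
    warning(skipped, " record(s) without stratification skipped")
  density <- do.call(rbind, rows)
  rownames(density) <- ids
  structure(list(density = density, depth = grid, cell_ids = ids,
                 cell_types = types, cell_class = classes,
                 n_skipped = skipped),
            class = "strat_profiles")
}

#' Read museum-style JSON stratification records
#'
#' @param path path to a JSON file containing an array of cell records.
#' @inheritParams parse_stratification
#' @return See [parse_stratification()].
#' @export
read_museum_json <- function(path, grid = ipl_depth_grid()) {
  parse_stratification(jsonlite::fromJSON(path, simplifyVector = FALSE),
                       grid = grid)
}

#' @export
print.strat_profiles <- function(x, ...) {
  cat(sprintf("Stratification profiles: %d cells (%d types) on %d depth points\n",
              nrow(x$density), length(unique(x$cell_types)),
              length(x$depth)))
  invisible(x)
}

#' Cosine similarity of two stratification profiles
#'
#' The connectivity proxy between a presynaptic and a postsynaptic cell:
#' the cosine of their stratification-profile vectors, i.e. the degree of
#' overlap of their voxel-volume densities across IPL depth. For
#' nonnegative profiles the value lies in \[0, 1\].
#'
#' @param u,v nonnegative numeric profiles on a shared depth grid.
#' @return A single number in `[-1, 1]` (`[0, 1]` for nonnegative input).
#' @examples
#' profile_cosine(c(1, 0, 1), c(1, 1, 0))  # 0.5
#' @export
profile_cosine <- function(u, v) {
  if (length(u) != length(v))
    stop("profiles must share one depth grid", call. = FALSE)
  cosine(u, v)
}

#' Cell-level connectivity matrix from stratification profiles
#'
#' Computes pairwise cosine similarities between all presynaptic and
#' postsynaptic profiles.
#'
#' @param pre,post `"strat_profiles"` objects or plain matrices
#'   (cells x depth) on the same grid.
#' @return A connectivity matrix (pre cells x post cells) with cell ids as
#'   dimnames and, when available, cell types attached as attributes
#'   `"pre_types"` / `"post_types"`.
#' @export
build_cell_connectivity <- function(pre, post) {
  pre_types <- post_types <- NULL
  if (inherits(pre, "strat_profiles")) { pre_types <- pre$cell_types; pre <- pre$density }
  if (inherits(post, "strat_profiles")) { post_types <- post$cell_types; post <- post$density }
  pre <- as_num_matrix(pre); post <- as_num_matrix(post)
  if (ncol(pre) != ncol(post))
    stop("pre and post profiles must share one depth grid", call. = FALSE)
  norm_rows <- function(m, side) {
    n <- sqrt(rowSums(m^2))
    if (any(n == 0)) {
      ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
      stop("zero-norm stratification profile for ", side, " cell(s): ",
           paste(head(ids[n == 0], 5), collapse = ", "), call. = FALSE)
    }
    m / n
  }
  Z <- tcrossprod(norm_rows(pre, "pre"), norm_rows(post, "post"))
  attr(Z, "pre_types") <- pre_types
  attr(Z, "post_types") <- post_types
  Z
}

#' Standardize a connectivity matrix
#'
#' Subtracts the entrywise mean and divides by the entrywise (population)
#' standard deviation, so the matrix admits both positive and negative
#' values with mean 0 and sd 1.
#'
#' @param Z connectivity matrix with at least 2 entries.
#' @return The standardized matrix (dimnames preserved).
#' @export
standardize_connectivity <- function(Z) {
  Z <- as_num_matrix(Z)
  if (length(Z) < 2) stop("need at least 2 entries", call. = FALSE)
  s <- pop_sd(as.numeric(Z))
  if (s == 0)
    stop("connectivity matrix is constant; standardization undefined",
         call. = FALSE)
  (Z - mean(Z)) / s
}

#' Average a cell-level connectivity matrix by type
#'
#' Each type-pair entry is the mean of the connectivity metrics over all
#' cell pairs of those types.
#'
#' @param Z cell-level connectivity matrix.
#' @param pre_types,post_types type label per row / column of `Z`.
#' @return A type-level matrix (pre types x post types), types ordered by
#'   first appearance.
#' @export
average_by_type <- function(Z, pre_types, post_types) {
  Z <- as_num_matrix(Z)
  if (length(pre_types) != nrow(Z) || anyNA(pre_types))
    stop("every row of Z needs a pre-synaptic type label", call. = FALSE)
  if (length(post_types) != ncol(Z) || anyNA(post_types))
    stop("every column of Z needs a post-synaptic type label", call. = FALSE)
  pre_lev <- unique(as.character(pre_types))
  post_lev <- unique(as.character(post_types))
  out <- matrix(0, length(pre_lev), length(post_lev),
                dimnames = list(pre_lev, post_lev))
  for (i in seq_along(pre_lev))
    for (j in seq_along(post_lev))
      out[i, j] <- mean(Z[pre_types == pre_lev[i],
                          post_types == post_lev[j], drop = FALSE])
  out
}

#' Assemble the weight matrix of the cell-level loss
#'
#' Two modes:
#' * `"contact"` — the weight matrix is a binary physical-contact mask:
#'   1 for pairs in contact, 0 otherwise (pairs without contact never
#'   enter the loss).
#' * `"type_balance"` — each cell pair `(i-type, j-type)` receives weight
#'   `1 / (n_i n_j)`, so every type pair contributes equally to the loss
#'   regardless of how many cells it contains.
#'
#' @param mode `"contact"` or `"type_balance"`.
#' @param contact binary matrix (required in contact mode).
#' @param pre_types,post_types type labels (required in type-balance
#'   mode).
#' @return A nonnegative weight matrix.
#' @export
weight_matrix <- function(mode = c("contact", "type_balance"),
                          contact = NULL, pre_types = NULL,
                          post_types = NULL) {
  mode <- match.arg(mode)
  if (mode == "contact") {
    if (is.null(contact))
      stop("contact mode requires a contact mask", call. = FALSE)
    contact <- as_num_matrix(contact)
    if (!all(contact %in% c(0, 1)))
      stop("contact mask must be binary", call. = FALSE)
    return(contact)
  }
  if (is.null(pre_types) || is.null(post_types))
    stop("type_balance mode requires pre_types and post_types",
         call. = FALSE)
  n_pre <- table(pre_types)[as.character(pre_types)]
  n_post <- table(post_types)[as.character(post_types)]
  outer(as.numeric(n_pre), as.numeric(n_post),
        function(a, b) 1 / (a * b))
}
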