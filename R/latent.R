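#' Connectivity reconstructed from a single latent dimension
#'
#' The bilinear prediction decomposes over latent dimensions:
#' \eqn{XA(YB)^T = \sum_k (Xa_k)(Yb_k)^T}. Each term is a rank-one
#' connectivity motif; inspecting them separately reveals which
#' connectivity pattern each latent dimension encodes.
#'
#' @param object a fitted [bilm()] model.
#' @param k latent dimension index (`1 <= k <= d`).
#' @param X,Y feature matrices (default: training data).
#' @return The rank-<= 1 matrix \eqn{(Xa_k)(Yb_k)^T}.
#' @export
reconstruct_dimension <- function(object, k, X = object$X, Y = object$Y) {
  if (k < 1 || k > object$d)
    stop("'k' must lie in 1..d = ", object$d, call. = FALSE)
  X <- as_num_matrix(X); Y <- as_num_matrix(Y)
  out <- (X %*% object$A[, k, drop = FALSE]) %*%
    t(Y %*% object$B[, k, drop = FALSE])
  dimnames(out) <- list(rownames(X), rownames(Y))
  out
}

#' Latent coordinates of types (or cells)
#'
#' Projects a feature matrix through a transformation factor, giving each
#' row a position in the shared latent space (`XA` for the presynaptic
#' side, `YB` for the postsynaptic side). The sign of each coordinate is
#' what groups types into the positive/negative halves of a latent
#' dimension when relating dimensions to stratification patterns; zero
#' coordinates are assigned to the positive group.
#'
#' @param features types x features matrix (e.g. a normalized type-mean
#'   matrix).
#' @param factor features x d transformation matrix, or a [bilm()] fit
#'   combined with `side`.
#' @param side when `factor` is a `bilm` fit: `"pre"` uses `A`, `"post"`
#'   uses `B`.
#' @return A types x d coordinate matrix; attribute `"half"` holds the
#'   `"+"`/`"-"` group per type and dimension.
#' @export
latent_coordinates <- function(features, factor, side = c("pre", "post")) {
  if (inherits(factor, "bilm")) {
    side <- match.arg(side)
    factor <- if (side == "pre") factor$A else factor$B
  }
  features <- as_num_matrix(features); factor <- as_num_matrix(factor)
  check_dims(ncol(features), nrow(factor), "feature columns",
             "rows of the transformation factor")
  out <- features %*% factor
  colnames(out) <- colnames(factor) %||% paste0("dim", seq_len(ncol(out)))
  attr(out, "half") <- ifelse(out >= 0, "+", "-")
  out
}

#' Back-project latent coefficients into gene space
#'
#' The type-level model operates on variance-normalized PC features, so a
#' factor column only assigns weights to PCs. The effective gene-space
#' weight of latent dimension `k` is obtained by undoing the chain:
#' `loadings %*% diag(1 / max(pooled_sd, floor)) %*% factor[, k]`. Per
#' dimension, the `top_n` genes with the largest positive and largest
#' negative weights are tabulated (one call per side, pre or post).
#'
#' @param factor PCs x d transformation matrix (one side's factor, e.g.
#'   `coef(fit, "pre")`).
#' @param loadings genes x PCs PCA loading matrix of the same side.
#' @param pooled_sd per-PC pooled within-type standard deviation used in
#'   the normalization.
#' @param top_n number of genes to keep per sign and dimension.
#' @param sd_floor lower bound on `pooled_sd`, matching
#'   [normalize_type_matrix()].
#' @return A list with `weights` (genes x d matrix of effective weights)
#'   and `table`, a data frame with columns `dimension`, `gene`,
#'   `weight`, `sign` and `rank` (by `|weight|`, descending within each
#'   dimension/sign block).
#' @export
gene_weights <- function(factor, loadings, pooled_sd, top_n = 50,
                         sd_floor = 1e-8) {
  factor <- as_num_matrix(factor); loadings <- as_num_matrix(loadings)
  check_dims(ncol(loadings), nrow(factor), "PC columns of loadings",
             "rows of the factor")
  if (length(pooled_sd) != nrow(factor))
    stop("'pooled_sd' must have one value per PC", call. = FALSE)
  scale <- 1 / pmax(pooled_sd, sd_floor)
  weights <- loadings %*% (scale * factor)
  rownames(weights) <- rownames(loadings) %||%
    paste0("g", seq_len(nrow(loadings)))
  colnames(weights) <- colnames(factor) %||%
    paste0("dim", seq_len(ncol(factor)))
  tab <- do.call(rbind, lapply(seq_len(ncol(weights)), function(k) {
    w <- weights[, k]
    blocks <- list(positive = sort(w[w > 0], decreasing = TRUE),
                   negative = sort(w[w < 0]))
    do.call(rbind, lapply(names(blocks), function(sgn) {
      b <- head(blocks[[sgn]], top_n)
      if (length(b) == 0) return(NULL)
      data.frame(dimension = k, gene = names(b), weight = as.numeric(b),
                 sign = sgn, rank = seq_along(b),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tab) <- NULL
  list(weights = weights, table = tab)
}

#' Predict connectivity partners for new types
#'
#' Projects previously unseen (e.g. transcriptionally defined) types into
#' the latent space of a trained type-level model and ranks the candidate
#' partner types by predicted connectivity. The new types must have been
#' processed through the identical preprocessing chain as the training
#' types (same highly variable genes, same PCA loadings, same pooled-sd
#' normalization), otherwise the feature spaces are incompatible.
#'
#' @param object a fitted type-level [bilm()] model.
#' @param new_types matrix of new postsynaptic types (rows) in the same
#'   normalized feature space as the training `Y`.
#' @param partner_types matrix of candidate presynaptic partner types in
#'   the training `X` space (default: the training matrix itself).
#' @param top_k number of partners to report per new type.
#' @return A data frame with columns `new_type`, `rank`, `partner` and
#'   `predicted`; attribute `"coordinates"` carries the latent positions
#'   of the new types. Ties are broken by partner order.
#' @export
predict_partners <- function(object, new_types,
                             partner_types = object$X, top_k = 3) {
  new_types <- as_num_matrix(new_types)
  partner_types <- as_num_matrix(partner_types)
  if (ncol(new_types) != nrow(object$B))
    stop("new types live in a ", ncol(new_types),
         "-dimensional feature space but the model was trained on ",
         nrow(object$B), " post-synaptic features; run the new types ",
         "through the identical preprocessing chain (same HVGs, PCA ",
         "loadings and pooled-sd normalization)", call. = FALSE)
  check_dims(ncol(partner_types), nrow(object$A),
             "feature columns of partner_types", "rows of fitted A")
  coords <- new_types %*% object$B
  pred <- (partner_types %*% object$A) %*% t(coords)  # partners x new
  partner_ids <- rownames(partner_types) %||%
    as.character(seq_len(nrow(partner_types)))
  new_ids <- rownames(new_types) %||%
    paste0("new", seq_len(nrow(new_types)))
  top_k <- min(top_k, nrow(pred))
  out <- do.call(rbind, lapply(seq_len(ncol(pred)), function(j) {
    ord <- order(-pred[, j])[seq_len(top_k)]  # stable: ties by row order
    data.frame(new_type = new_ids[j], rank = seq_len(top_k),
               partner = partner_ids[ord], predicted = pred[ord, j],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "coordinates") <- structure(coords,
                                        dimnames = list(new_ids,
                                                        colnames(object$B)))
  out
}
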