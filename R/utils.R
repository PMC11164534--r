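# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded fits and generators are pure functions of
#' their arguments and never perturb the session RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

as_num_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  x
}

check_finite <- function(x, arg = deparse(substitute(x))) {
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains missing or non-finite values", arg),
         call. = FALSE)
  invisible(x)
}

# Dimension check with an error naming the offending axes.
check_dims <- function(actual, expected, what, against) {
  if (!identical(as.integer(actual), as.integer(expected)))
    stop(sprintf(
      "dimension mismatch: %s is %s but %s requires %s",
      what, paste(actual, collapse = " x "),
      against, paste(expected, collapse = " x ")), call. = FALSE)
  invisible(TRUE)
}

cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

# Population standard deviation (divisor n).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
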