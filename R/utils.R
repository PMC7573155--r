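#' @importFrom rlang %||% abort warn
#' @importFrom stats cor sd var qt pt rnorm runif median mad coef fitted
#'   resid lm lm.fit setNames quantile
NULL

# Upper-triangle edge bookkeeping -------------------------------------------
#
# Edges of an n-node undirected graph are stored as a vector in the order of
# m[upper.tri(m)] (column-major, i < j). All modules share this convention.

#' Enumerate the upper-triangle node pairs of an n-node graph
#'
#' Returns the (i, j) pairs (i < j) in the order used throughout the package
#' to vectorize symmetric node-by-node matrices, i.e. the order of
#' `m[upper.tri(m)]`.
#'
#' @param n_nodes Number of nodes.
#' @return Integer matrix with columns `i` and `j`, one row per edge.
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  idx <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[, c("i", "j"), drop = FALSE]
}

#' Number of edges of a full graph on n nodes
#' @param n_nodes Number of nodes.
#' @return Integer edge count n*(n-1)/2.
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

# Vectorize a symmetric matrix (upper triangle, column-major).
ut_vec <- function(m) m[upper.tri(m)]

# Rebuild a symmetric zero-diagonal matrix from its upper-triangle vector.
sym_from_vec <- function(v, n_nodes) {
  m <- matrix(0, n_nodes, n_nodes)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Edge-vector index of a node pair
#'
#' Maps node pairs to their position in the upper-triangle edge vector
#' (the order of [edge_pairs()]).
#'
#' @param i,j Node indices (vectorized), `i != j`.
#' @param n_nodes Number of nodes.
#' @return Integer edge indices.
#' @export
edge_index <- function(i, j, n_nodes) {
  a <- pmin(i, j); b <- pmax(i, j)
  as.integer((b - 1) * (b - 2) / 2 + a)
}

# Scoped RNG: seed the generator for the duration of the calling function
# only, restoring the caller's stream afterwards. NULL leaves the RNG alone.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  set.seed(as.integer(seed))
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(NULL)
}

# Column-standardize with sample SD (n - 1); zero-variance columns error.
standardize <- function(x, what = "column") {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    abort(paste0("zero-variance ", what, "(s): ",
                 paste(which(s == 0), collapse = ", ")))
  }
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

# Residualize the columns of y on the columns of x (including whatever
# intercept the caller put in x). Used for partial correlations and the
# Frisch-Waugh step of the permutation engine.
residualize <- function(y, x) {
  qr.resid(qr(x), as.matrix(y))
}
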