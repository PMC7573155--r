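# Network-based statistics ---------------------------------------------------
#
# Edge-wise inference on verum-minus-placebo connectivity differences: a
# general linear model per edge with the score change as regressor of
# interest and sex, age, mean connectivity and an intercept as covariates;
# suprathreshold edges (one-sided t at p <= 0.001) form connected
# components, whose extent (edge count) and intensity (summed suprathreshold
# excess) are tested against a max-component permutation null
# (Freedman-Lane residual permutation) for family-wise error control.

#' Edge-wise design matrix
#'
#' @param score_change Per-subject regressor of interest (post minus pre).
#' @param covariates Data frame or matrix of per-subject covariates (the
#'   study design uses sex, age and mean connectivity), or `NULL` for a
#'   covariate-free design.
#' @return List of class `edge_design`: full design matrix `X` (intercept
#'   first, regressor of interest last), the reduced (covariates + intercept)
#'   matrix `Z`, and the index of the column of interest.
#' @export
edge_design <- function(score_change, covariates = NULL) {
  n <- length(score_change)
  Z <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates)[
      , setdiff(colnames(as.data.frame(covariates)), "subject"), drop = FALSE])
    storage.mode(C) <- "double"
    stopifnot(nrow(C) == n)
    Z <- cbind(Z, C)
  }
  X <- cbind(Z, score_change = score_change)
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient.")
  structure(list(X = X, Z = Z, interest = ncol(X)), class = "edge_design")
}

#' Edge-wise general linear model t-statistics
#'
#' Ordinary least squares per edge with a common design; the returned
#' statistic is the t of the regressor of interest with `n - p` degrees of
#' freedom. Edges with numerically zero residual variance are flagged as
#' degenerate (their t is +/-Inf), not treated as errors.
#'
#' @param dz_stack Subjects-by-edges matrix of connectivity differences.
#' @param design An [edge_design()].
#' @return Numeric vector of t-values with attributes `df` and
#'   `degenerate` (edge indices).
#' @export
edge_glm <- function(dz_stack, design) {
  stopifnot(inherits(design, "edge_design"))
  Y <- as.matrix(dz_stack)
  X <- design$X
  n <- nrow(Y)
  p <- ncol(X)
  if (n < p + 2) abort("need at least p + 2 subjects.")
  qx <- qr(X)
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  XtX_inv <- solve(crossprod(X))
  v <- XtX_inv[design$interest, design$interest]
  se <- sqrt(sigma2 * v)
  tval <- coefs[design$interest, ] / se
  degen <- which(sigma2 < .Machine$double.eps * colSums(Y^2) / df + 1e-300)
  tval[se == 0] <- sign(coefs[design$interest, se == 0]) * Inf
  attr(tval, "df") <- df
  attr(tval, "degenerate") <- degen
  tval
}

#' Edge-inclusion t threshold
#'
#' The t-value corresponding to a one-sided tail probability `p` at the
#' available degrees of freedom; the contrast direction is applied by the
#' caller through the sign of the tested statistic.
#'
#' @param df Degrees of freedom.
#' @param p Tail probability (study value 0.001).
#' @return Upper-tail t quantile.
#' @export
t_threshold <- function(df, p = 0.001) {
  stopifnot(df >= 1)
  qt(1 - p, df)
}

#' Connected components of a suprathreshold graph
#'
#' Maximal node-connected components (two edges are linked when they share
#' a node); singleton nodes without suprathreshold edges are not reported.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal, or a two-column
#'   edge matrix with `n_nodes` supplied.
#' @param n_nodes Number of nodes when `adjacency` is an edge list.
#' @return List of components, each a list with `nodes` and `edges` (a
#'   two-column node-pair matrix).
#' @export
edge_components <- function(adjacency, n_nodes = NULL) {
  if (is.null(n_nodes)) {
    m <- as.matrix(adjacency)
    n_nodes <- nrow(m)
    el <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  } else {
    el <- as.matrix(adjacency)
    if (nrow(el) && ncol(el) != 2) abort("edge list needs two columns.")
  }
  if (nrow(el) == 0) return(list())
  g <- igraph::graph_from_edgelist(matrix(as.integer(el), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[el[, 1]]
  lapply(sort(unique(comp_of_edge)), function(cid) {
    sel <- comp_of_edge == cid
    list(nodes = sort(unique(as.integer(el[sel, , drop = FALSE]))),
         edges = el[sel, , drop = FALSE])
  })
}

#' Component summary statistic
#'
#' Extent is the number of edges; intensity is the summed excess of the
#' (direction-signed) edge statistic over the inclusion threshold.
#'
#' @param component One element of [edge_components()].
#' @param t_map Edge t-values in upper-triangle order (direction-signed).
#' @param t_thresh Inclusion threshold.
#' @param n_nodes Number of nodes (for edge indexing).
#' @param mode `"extent"` or `"intensity"`.
#' @return A single number.
#' @export
component_stat <- function(component, t_map, t_thresh, n_nodes,
                           mode = c("extent", "intensity")) {
  mode <- match.arg(mode)
  ne <- nrow(component$edges)
  if (mode == "extent") return(ne)
  idx <- edge_index(component$edges[, 1], component$edges[, 2], n_nodes)
  sum(t_map[idx] - t_thresh)
}

# Union-find max-component statistics for the permutation hot loop: given
# the suprathreshold edge list and signed t excess, return the maximum
# extent and intensity over components. Cross-tested against
# edge_components().
max_component_stats <- function(ei, ej, excess) {
  m <- length(ei)
  if (m == 0) return(c(extent = 0, intensity = 0))
  nodes <- unique(c(ei, ej))
  id <- seq_along(nodes)
  names(id) <- nodes
  parent <- id
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a <- id[as.character(ei)]
  b <- id[as.character(ej)]
  for (e in seq_len(m)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(a, find, integer(1))
  ext <- tapply(rep(1, m), root, sum)
  intens <- tapply(excess, root, sum)
  c(extent = max(ext), intensity = max(intens))
}

#' Network-based statistics test
#'
#' Runs the edge-wise GLM, forms suprathreshold components in the requested
#' contrast direction, and tests each component's extent and intensity
#' against a max-component permutation null. The null respects the
#' covariates by Freedman-Lane residual permutation: the reduced
#' (covariates-only) model is fitted once, its residual rows are permuted,
#' the reduced fit is re-added, and the full-model t is recomputed (via the
#' Frisch-Waugh identity) for every edge. FWER p-values use the
#' +1-smoothed estimator, so the smallest attainable p is
#' `1/(n_perm + 1)`.
#'
#' @param dz_stack Subjects-by-edges difference stack.
#' @param design An [edge_design()].
#' @param direction +1 to test positive association of connectivity change
#'   with the score change, -1 for negative (the two contrast directions
#'   are run separately).
#' @param p_thresh Edge-inclusion tail probability (study value 0.001).
#' @param alpha Component significance level (study value 0.10 to cover
#'   trend-level effects).
#' @param n_perm Number of permutations (study value 10,000).
#' @param n_nodes Number of nodes.
#' @param seed Seed for the permutation stream.
#' @return Object of class `nbs_result`: the edge t-map, threshold,
#'   components tibble (extent, intensity, FWER p for both statistics,
#'   significance flags), the permutation nulls, and the configuration.
#' @export
nbs_test <- function(dz_stack, design, direction = 1, p_thresh = 0.001,
                     alpha = 0.10, n_perm = 10000, n_nodes, seed = 1L) {
  stopifnot(direction %in% c(-1, 1), inherits(design, "edge_design"))
  if (n_perm < 100) warn("fewer than 100 permutations; p-values are coarse.")
  Y <- as.matrix(dz_stack)
  n <- nrow(Y)
  X <- design$X
  Z <- design$Z
  p <- ncol(X)
  df <- n - p
  thr <- t_threshold(df, p_thresh)

  # Frisch-Waugh pieces shared by the observed and permuted statistics
  qz <- qr(Z)
  x_res <- qr.resid(qz, X[, design$interest]) # score change purged of covariates
  xx <- sum(x_res^2)
  R_red <- qr.resid(qz, Y) # reduced-model residuals (Freedman-Lane)

  t_from_resid <- function(Yr) {
    # Yr = covariate-purged responses; t for the regressor of interest
    b <- crossprod(x_res, Yr)[1, ] / xx
    ss <- colSums(Yr^2) - b^2 * xx
    sigma2 <- pmax(ss, 0) / df
    b / sqrt(sigma2 / xx)
  }

  t_obs <- t_from_resid(R_red)
  t_dir <- direction * t_obs
  supra <- which(t_dir >= thr)
  pairs <- edge_pairs(n_nodes)
  comps <- edge_components(pairs[supra, , drop = FALSE], n_nodes = n_nodes)

  local_seed(seed)
  null_extent <- numeric(n_perm)
  null_intensity <- numeric(n_perm)
  for (b_i in seq_len(n_perm)) {
    perm <- sample.int(n)
    # M_Z (fitted_red + permuted residuals) = M_Z permuted residuals
    Yp <- qr.resid(qz, R_red[perm, , drop = FALSE])
    tp <- direction * t_from_resid(Yp)
    sel <- which(tp >= thr)
    st <- max_component_stats(pairs[sel, 1], pairs[sel, 2], tp[sel] - thr)
    null_extent[b_i] <- st["extent"]
    null_intensity[b_i] <- st["intensity"]
  }

  comp_tbl <- purrr::map_dfr(seq_along(comps), function(ci) {
    comp <- comps[[ci]]
    ext <- component_stat(comp, t_dir, thr, n_nodes, "extent")
    intens <- component_stat(comp, t_dir, thr, n_nodes, "intensity")
    tibble::tibble(
      component = ci,
      n_nodes = length(comp$nodes),
      extent = ext,
      intensity = intens,
      p_extent = (1 + sum(null_extent >= ext)) / (1 + n_perm),
      p_intensity = (1 + sum(null_intensity >= intens)) / (1 + n_perm)
    )
  })
  if (nrow(comp_tbl)) {
    comp_tbl$significant_extent <- comp_tbl$p_extent <= alpha
    comp_tbl$significant_intensity <- comp_tbl$p_intensity <= alpha
  }
  structure(list(
    t_map = as.numeric(t_obs), df = df, t_thresh = thr,
    direction = direction, components = comps, component_table = comp_tbl,
    null_extent = null_extent, null_intensity = null_intensity,
    n_nodes = n_nodes, alpha = alpha, p_thresh = p_thresh,
    n_perm = n_perm, seed = seed,
    permutation_scheme = "freedman-lane"
  ), class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result> direction ", x$direction, ", t threshold ",
      round(x$t_thresh, 3), " (df = ", x$df, "), ",
      length(x$components), " component(s), ", x$n_perm,
      " permutations\n", sep = "")
  if (nrow(x$component_table)) print(x$component_table)
  invisible(x)
}

# Edge indices (upper-triangle order) of the components flagged significant
# by the given statistic; alpha = 1 selects every observed component.
significant_component_edges <- function(nbs_result,
                                        stat = c("extent", "intensity")) {
  stat <- match.arg(stat)
  tbl <- nbs_result$component_table
  if (!nrow(tbl)) return(integer(0))
  flag <- tbl[[paste0("p_", stat)]] <= nbs_result$alpha
  keep <- which(flag)
  if (!length(keep)) return(integer(0))
  unlist(lapply(nbs_result$components[keep], function(comp) {
    edge_index(comp$edges[, 1], comp$edges[, 2], nbs_result$n_nodes)
  }))
}
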