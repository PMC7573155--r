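# Questionnaire factor analysis --------------------------------------------
#
# Depression questionnaires (a 17-item clinician rating and a 21-item
# self-rating in the motivating study) are summarized by orthogonal latent
# factors fitted on pre-treatment scores only: items with poor sampling
# adequacy are removed until the overall KMO exceeds 0.5 and the extraction
# converges, factors are extracted by principal axis factoring with the
# Kaiser criterion, rotated by Varimax, and scored by the Anderson-Rubin
# construction so that the pre-score factors are exactly uncorrelated.
# Post-treatment scores are projected with the stored pre-sample weights,
# never re-fit, so treatment response cannot influence the factor solution.

#' Kaiser-Meyer-Olkin and per-item sampling adequacy
#'
#' Anti-image partial correlations `a_ij` are derived from the inverse of
#' the correlation matrix; KMO is the ratio of summed squared correlations
#' to summed squared correlations plus squared anti-image correlations over
#' all off-diagonal pairs, and each item's MSA restricts the sums to its
#' row.
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @return List with `kmo` (scalar) and `msa` (per item), all in \[0, 1\].
#' @export
compute_kmo <- function(R) {
  R <- as.matrix(R)
  S <- tryCatch(solve(R), error = function(e) {
    abort("correlation matrix is singular; remove collinear items first.")
  })
  d <- 1 / sqrt(diag(S))
  A <- -S * tcrossprod(d) # anti-image (partial) correlations
  diag(A) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  a2 <- A^2
  kmo <- sum(r2) / (sum(r2) + sum(a2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(a2))
  names(msa) <- rownames(R)
  list(kmo = kmo, msa = msa)
}

#' Number of factors by the Kaiser criterion
#'
#' @param R Correlation matrix.
#' @return Count of eigenvalues strictly greater than 1.
#' @export
kaiser_count <- function(R) {
  sum(eigen(as.matrix(R), symmetric = TRUE, only.values = TRUE)$values > 1)
}

#' Principal axis factoring
#'
#' Iterated communality estimation on the reduced correlation matrix:
#' communalities start at the squared multiple correlations
#' `1 - 1/diag(R^-1)`, the reduced matrix (communalities on the diagonal) is
#' eigendecomposed, loadings are taken from the top eigenpairs, and the
#' procedure repeats until the largest communality change drops below `tol`
#' or `max_iter` is reached (non-convergence is returned as a flag, not an
#' error, because the fitting loop treats it as a trigger for item
#' removal). Communalities exceeding 1 (Heywood cases) are flagged with the
#' offending items and clipped.
#'
#' @param R Correlation matrix.
#' @param n_factors Number of factors, at least 1 and fewer than items.
#' @param max_iter,tol Iteration control.
#' @return List: `loadings` (unrotated), `communalities`, `converged`,
#'   `n_iter`, `heywood_items`.
#' @export
principal_axis_factor <- function(R, n_factors, max_iter = 1000, tol = 1e-6) {
  R <- as.matrix(R)
  p <- nrow(R)
  if (n_factors < 1 || n_factors >= p) {
    abort("need 1 <= n_factors < number of items.")
  }
  h2 <- 1 - 1 / diag(solve(R))
  heywood <- integer(0)
  lambda <- NULL
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(n_factors)], 0)
    lambda <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(vals), n_factors)
    h2_new <- rowSums(lambda^2)
    over <- which(h2_new > 1)
    if (length(over)) {
      heywood <- union(heywood, over)
      h2_new[over] <- 1
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # deterministic column signs: largest-magnitude loading positive
  for (f in seq_len(n_factors)) {
    j <- which.max(abs(lambda[, f]))
    if (lambda[j, f] < 0) lambda[, f] <- -lambda[, f]
  }
  rownames(lambda) <- rownames(R)
  colnames(lambda) <- paste0("F", seq_len(n_factors))
  list(loadings = lambda, communalities = h2, converged = converged,
       n_iter = iter,
       heywood_items = if (length(heywood)) rownames(R)[heywood] %||% heywood
                       else character(0))
}

#' Varimax rotation (Kaiser-normalized)
#'
#' Orthogonal rotation maximizing the Kaiser-normalized varimax criterion,
#' delegated to [stats::varimax()]. One factor returns the identity
#' rotation. The rotation matrix is orthogonal and the row sums of squared
#' loadings (communalities) are preserved.
#'
#' @param loadings Unrotated items-by-factors loading matrix.
#' @param tol Convergence tolerance passed to `stats::varimax()`.
#' @return List with `loadings` (rotated) and `rotation` (orthogonal T such
#'   that rotated = unrotated %*% T).
#' @export
varimax_rotate <- function(loadings, tol = 1e-10) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) == 1) {
    return(list(loadings = loadings, rotation = matrix(1, 1, 1)))
  }
  v <- stats::varimax(loadings, normalize = TRUE, eps = tol)
  lam <- loadings %*% v$rotmat
  rot <- v$rotmat
  for (f in seq_len(ncol(lam))) { # deterministic column signs
    j <- which.max(abs(lam[, f]))
    if (lam[j, f] < 0) {
      lam[, f] <- -lam[, f]
      rot[, f] <- -rot[, f]
    }
  }
  dimnames(lam) <- dimnames(loadings)
  list(loadings = lam, rotation = rot)
}

#' Anderson-Rubin factor-score weights
#'
#' Bartlett-type weights symmetrically orthogonalized through the
#' correlation matrix: `W = U^-1 L (L' U^-1 R U^-1 L)^(-1/2)` with `U` the
#' diagonal uniqueness matrix. Scores `S = Z W` computed on the fitting
#' sample have sample covariance exactly the identity, which is what makes
#' the pre-score factor correlations exactly zero.
#'
#' @param R Correlation matrix of the fitting sample.
#' @param loadings Rotated loading matrix.
#' @param uniquenesses Per-item uniqueness (1 - communality), all positive.
#' @return Items-by-factors weight matrix.
#' @export
anderson_rubin_weights <- function(R, loadings, uniquenesses) {
  R <- as.matrix(R)
  loadings <- as.matrix(loadings)
  if (any(uniquenesses <= 0)) abort("uniquenesses must be positive.")
  B <- loadings / uniquenesses
  # symmetric orthogonalization through R, via the SVD of chol(R) %*% B for
  # numerical stability when uniquenesses are tiny
  G <- tryCatch(chol(R), error = function(e) {
    abort("correlation matrix is singular.")
  })
  sv <- svd(G %*% B)
  if (any(sv$d <= sv$d[1] * 1e-12)) abort("correlation matrix is singular.")
  W <- B %*% sv$v %*% (t(sv$v) / sv$d)
  dimnames(W) <- dimnames(loadings)
  W
}

# Pull the numeric item matrix out of an item table (tibble or matrix).
item_matrix <- function(items, id_col = "subject") {
  if (is.matrix(items)) return(items)
  items <- as.data.frame(items)
  if (id_col %in% names(items)) {
    ids <- items[[id_col]]
    items <- items[setdiff(names(items), id_col)]
  } else {
    ids <- paste0("S", seq_len(nrow(items)))
  }
  m <- as.matrix(items)
  rownames(m) <- ids
  m
}

#' Fit the questionnaire factor model with MSA-driven item removal
#'
#' The fitting loop on pre-treatment items: compute KMO/MSA; while the KMO
#' is at or below `kmo_min`, drop the item with the lowest MSA (ties broken
#' by original item order) and recompute. Once the KMO clears the bar, the
#' factor count is set by the Kaiser criterion and principal axis factoring
#' is run; if the extraction fails to converge, the next-lowest-MSA item is
#' removed and the loop restarts. The converged solution is Varimax-rotated
#' and Anderson-Rubin score weights are computed. The full audit trail of
#' removals is kept.
#'
#' @param pre_items Item table (tibble with a subject id column plus one
#'   integer column per item, or a plain matrix) of pre-treatment scores.
#' @param kmo_min KMO bar that item removal must clear (study value 0.5).
#' @param max_iter,tol Extraction iteration control.
#' @param id_col Name of the subject id column.
#' @return Object of class `factor_model`: retained/dropped items, rotated
#'   loadings, rotation matrix, score weights, communalities, KMO/MSA,
#'   variance explained, pre-sample item means/SDs, and the fitting-sample
#'   factor scores.
#' @export
fit_factor_model <- function(pre_items, kmo_min = 0.5, max_iter = 1000,
                             tol = 1e-6, id_col = "subject") {
  X_all <- item_matrix(pre_items, id_col)
  all_items <- colnames(X_all) %||% paste0("I", seq_len(ncol(X_all)))
  colnames(X_all) <- all_items
  if (ncol(X_all) < 4) abort("need at least 4 items.")
  retained <- all_items
  dropped <- tibble::tibble(item = character(0), msa = numeric(0),
                            reason = character(0), step = integer(0))
  step <- 0
  repeat {
    if (length(retained) < 4) {
      abort(paste0(
        "item-removal loop exhausted the item set; removal trail: ",
        paste(dropped$item, collapse = ", ")))
    }
    X <- X_all[, retained, drop = FALSE]
    R <- cor(X, use = "pairwise.complete.obs")
    adequacy <- compute_kmo(R)
    drop_item <- function(reason) {
      worst <- which.min(adequacy$msa) # ties: earliest item wins
      dropped <<- dplyr::bind_rows(dropped, tibble::tibble(
        item = retained[worst], msa = unname(adequacy$msa[worst]),
        reason = reason, step = step))
      retained <<- retained[-worst]
    }
    step <- step + 1
    if (adequacy$kmo <= kmo_min) {
      drop_item("kmo")
      next
    }
    k <- kaiser_count(R)
    if (k < 1) abort("Kaiser criterion retained no factor.")
    if (k >= length(retained)) {
      abort("Kaiser criterion retained as many factors as items.")
    }
    paf <- principal_axis_factor(R, k, max_iter = max_iter, tol = tol)
    if (!paf$converged) {
      drop_item("nonconvergence")
      next
    }
    break
  }
  rot <- varimax_rotate(paf$loadings)
  uniq <- pmax(1 - paf$communalities, 1e-6)
  W <- anderson_rubin_weights(R, rot$loadings, uniq)
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, means, "-"), 2, sds, "/")
  scores <- Z %*% W
  colnames(scores) <- colnames(W)
  structure(list(
    all_items = all_items, retained_items = retained, dropped_items = dropped,
    n_factors = ncol(rot$loadings), loadings = rot$loadings,
    rotation = rot$rotation, score_weights = W,
    communalities = paf$communalities, uniquenesses = uniq,
    kmo = adequacy$kmo, msa = adequacy$msa,
    variance_explained = sum(paf$communalities) / length(retained),
    item_means = means, item_sds = sds, correlation = R,
    scores = scores, converged = paf$converged,
    heywood_items = paf$heywood_items
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> ", x$n_factors, " factors on ",
      length(x$retained_items), "/", length(x$all_items),
      " items; KMO = ", round(x$kmo, 3),
      "; variance explained = ", round(100 * x$variance_explained, 2),
      "%\n", sep = "")
  if (nrow(x$dropped_items)) {
    cat("dropped:", paste0(x$dropped_items$item, " (", x$dropped_items$reason,
                           ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score subjects with a fitted factor model
#'
#' Projection, not re-fitting: items are standardized with the pre-sample
#' means/SDs stored in the model, so post-treatment factor scores cannot be
#' influenced by treatment response. The sum score is the plain sum over
#' all original items, including any dropped from the factor solution.
#'
#' @param model A [fit_factor_model()] result.
#' @param items Item table to score (must contain every retained item; the
#'   sum score additionally requires every original item).
#' @param id_col Subject id column name.
#' @return Tibble: `subject`, one column per factor, and `sum_score`.
#' @export
score_subjects <- function(model, items, id_col = "subject") {
  X <- item_matrix(items, id_col)
  missing_items <- setdiff(model$retained_items, colnames(X))
  if (length(missing_items)) {
    abort(paste0("missing retained item(s): ",
                 paste(missing_items, collapse = ", ")))
  }
  Xr <- X[, model$retained_items, drop = FALSE]
  Z <- sweep(sweep(Xr, 2, model$item_means, "-"), 2, model$item_sds, "/")
  S <- Z %*% model$score_weights
  missing_sum <- setdiff(model$all_items, colnames(X))
  sum_score <- if (length(missing_sum)) {
    warn(paste0("sum score omits missing item(s): ",
                paste(missing_sum, collapse = ", ")))
    rowSums(X[, intersect(model$all_items, colnames(X)), drop = FALSE])
  } else {
    rowSums(X[, model$all_items, drop = FALSE])
  }
  out <- tibble::as_tibble(S)
  dplyr::bind_cols(
    tibble::tibble(subject = rownames(X) %||% paste0("S", seq_len(nrow(X)))),
    out,
    tibble::tibble(sum_score = unname(sum_score)))
}

#' Linear imputation of a missing visit score, rounded up
#'
#' The midpoint of the visits before and after, with the ceiling taken
#' because item scores are integers.
#'
#' @param prev_visit,next_visit Integer scores of the adjacent visits.
#' @return Integer imputed score.
#' @export
impute_post_linear <- function(prev_visit, next_visit) {
  as.integer(ceiling((prev_visit + next_visit) / 2))
}

#' Clinical dichotomization into remission and response
#'
#' Remission is a post-treatment total of 7 or less; response is a total
#' score reduction of at least 50%.
#'
#' @param pre_sum,post_sum Integer questionnaire totals (vectorized);
#'   `pre_sum` must be positive for response to be defined.
#' @return Tibble: `pre_sum`, `post_sum`, `remission`, `response`.
#' @export
dichotomize <- function(pre_sum, post_sum) {
  if (any(pre_sum <= 0)) abort("pre_sum must be positive (response undefined).")
  tibble::tibble(
    pre_sum = pre_sum, post_sum = post_sum,
    remission = post_sum <= 7,
    response = (pre_sum - post_sum) / pre_sum >= 0.5
  )
}
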