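# Cross-validated prediction -------------------------------------------------
#
# The predictive procedure: per-edge weights are |partial Pearson
# correlation| between the connectivity difference and the score change
# (covariate-corrected in the full models), scaled by the SD of all absolute
# correlations in the training set; the FC predictor is the weighted average
# of the masked connectivity differences; a robust bisquare regression maps
# the predictor (plus covariates) to the score change; generalizability is
# estimated by leave-one-out CV and repeated 3-fold CV without role
# reversal, with an explicitly circular (double-dipping) variant retained
# for comparison.

#' Training-set edge weights from partial correlations
#'
#' Per edge, the partial Pearson correlation between the connectivity
#' difference and the score change controlling for the covariates (plain
#' Pearson when `covariates` is `NULL`, the "without covariates" reduced
#' models); the weight is the absolute correlation divided by the sample SD
#' of all absolute correlations within the training set. Signed mode keeps
#' the sign of the correlation.
#'
#' @param dz_stack Training subjects-by-edges difference stack.
#' @param score_change Training score changes.
#' @param covariates Covariate data frame/matrix or `NULL`.
#' @param signed Keep correlation signs?
#' @param mask Integer edge indices to weight (others get weight 0);
#'   defaults to all edges.
#' @return Object of class `weight_vector`: full-length `weights`, the
#'   `mask`, raw partial correlations, the scaling SD, and flags.
#' @export
edge_weights <- function(dz_stack, score_change, covariates = NULL,
                         signed = FALSE, mask = NULL) {
  Y <- as.matrix(dz_stack)
  n <- nrow(Y)
  n_edge <- ncol(Y)
  mask <- mask %||% seq_len(n_edge)
  if (sd(score_change) == 0) abort("zero-variance score change.")
  q <- if (is.null(covariates)) 0 else ncol(as.matrix(covariates))
  if (n < q + 3) abort("need at least covariates + 3 training subjects.")
  Z <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates)[
      , setdiff(colnames(as.data.frame(covariates)), "subject"), drop = FALSE])
    storage.mode(C) <- "double"
    Z <- cbind(Z, C)
  }
  s_res <- residualize(score_change, Z)
  ss <- sum(s_res^2)
  if (ss < 1e-12 * sum(score_change^2) + 1e-300) {
    abort("score change is collinear with the covariates; partial correlations undefined.")
  }
  Ym <- Y[, mask, drop = FALSE]
  Y_res <- residualize(Ym, Z)
  denom <- sqrt(colSums(Y_res^2) * ss)
  r <- as.numeric(crossprod(Y_res, s_res)) / denom
  r[denom == 0] <- 0
  abs_r <- abs(r)
  scale_sd <- sd(abs_r)
  flagged_unscaled <- FALSE
  if (is.na(scale_sd) || scale_sd == 0) {
    scale_sd <- 1
    flagged_unscaled <- TRUE
  }
  w <- numeric(n_edge)
  w[mask] <- if (signed) r / scale_sd else abs_r / scale_sd
  structure(list(weights = w, mask = as.integer(mask), r_partial = r,
                 scale_sd = scale_sd, signed = signed,
                 flagged_unscaled = flagged_unscaled),
            class = "weight_vector")
}

#' Edge-selection strategies
#'
#' Three ways to choose which edges enter the predictor:
#' * `"nbs"` — the edges of the significant components of a (full-sample)
#'   NBS result; deliberately circular when that NBS saw the test subjects.
#' * `"threshold"` — edges passing the NBS t threshold, in the stated
#'   contrast direction, computed on the training set only.
#' * `"all"` — every edge (no threshold).
#'
#' @param strategy `"nbs"`, `"threshold"` or `"all"`.
#' @param n_edge Total number of edges.
#' @param nbs_result Required for `"nbs"`.
#' @param t_map,t_thresh,direction Required for `"threshold"`.
#' @param stat Component statistic used to flag significance for `"nbs"`.
#' @return Integer vector of selected edge indices (possibly empty).
#' @export
select_edges <- function(strategy = c("all", "threshold", "nbs"), n_edge,
                         nbs_result = NULL, t_map = NULL, t_thresh = NULL,
                         direction = 1, stat = "extent") {
  strategy <- match.arg(strategy)
  switch(strategy,
    all = seq_len(n_edge),
    threshold = {
      if (is.null(t_map) || is.null(t_thresh)) {
        abort("strategy \"threshold\" needs t_map and t_thresh.")
      }
      which(direction * t_map >= t_thresh)
    },
    nbs = {
      if (is.null(nbs_result)) abort("strategy \"nbs\" needs an nbs_result.")
      sort(unique(significant_component_edges(nbs_result, stat)))
    })
}

#' Functional-connectivity predictor
#'
#' The weighted average of the masked connectivity differences,
#' `sum(w * dz) / sum(|w|)` — identical to the plain weighted mean for the
#' unsigned weights, and invariant to uniform rescaling of the weights
#' (which makes the SD scaling of [edge_weights()] a reporting convention,
#' not a change of predictions).
#'
#' @param dz Per-subject edge vector, or subjects-by-edges matrix.
#' @param weights A [edge_weights()] result.
#' @return One predictor value per subject (`NA` with attribute
#'   `flagged = TRUE` when the mask is empty: a flagged non-prediction).
#' @export
fc_predictor <- function(dz, weights) {
  stopifnot(inherits(weights, "weight_vector"))
  if (is.null(dim(dz))) dz <- matrix(dz, nrow = 1)
  mask <- weights$mask
  if (!length(mask)) {
    out <- rep(NA_real_, nrow(dz))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  w <- weights$weights[mask]
  denom <- sum(abs(w))
  if (denom == 0) {
    out <- rep(NA_real_, nrow(dz))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  as.numeric(dz[, mask, drop = FALSE] %*% w) / denom
}

#' Robust response regression (Tukey bisquare IRLS)
#'
#' Linear model of the score change on the FC predictor (and covariates in
#' the full models), fitted by iteratively reweighted least squares with
#' Tukey's bisquare weight function (tuning 4.685, 95% Gaussian
#' efficiency), MAD residual scale re-estimated per iteration, initialized
#' from least squares — delegated to [MASS::rlm()]. Non-convergence is
#' flagged and the last iterate returned.
#'
#' @param predictor Training FC predictor values.
#' @param covariates Covariate data frame/matrix or `NULL`.
#' @param score_change Training score changes.
#' @param tuning Bisquare tuning constant.
#' @param max_iter,tol Iteration control.
#' @return Object of class `response_model`: `coefficients`, IRLS weights,
#'   scale estimate, convergence flag.
#' @export
fit_response_model <- function(predictor, covariates = NULL, score_change,
                               tuning = 4.685, max_iter = 50, tol = 1e-7) {
  if (sd(predictor) == 0) abort("predictor has zero variance.")
  X <- cbind(`(intercept)` = 1, predictor = predictor)
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates)[
      , setdiff(colnames(as.data.frame(covariates)), "subject"), drop = FALSE])
    storage.mode(C) <- "double"
    X <- cbind(X, C)
  }
  n <- nrow(X)
  if (n <= ncol(X) + 1) abort("need n > number of model columns + 1.")
  # an (almost) exact linear fit has no residual scale for the MAD estimate;
  # the robust fit then coincides with least squares by construction
  ls_coef <- qr.coef(qr(X), score_change)
  ls_res <- score_change - X %*% ls_coef
  if (mad(ls_res) < 1e-10 * (sd(score_change) + 1e-300)) {
    return(structure(list(coefficients = setNames(as.numeric(ls_coef),
                                                  colnames(X)),
                          irls_weights = rep(1, n), scale = 0,
                          converged = TRUE, terms = colnames(X)),
                     class = "response_model"))
  }
  fit <- withCallingHandlers(
    MASS::rlm(X, score_change, psi = MASS::psi.bisquare, c = tuning,
              method = "M", scale.est = "MAD", init = "ls",
              maxit = max_iter, acc = tol),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(coefficients = coef(fit), irls_weights = fit$w,
                 scale = fit$s, converged = fit$converged,
                 terms = colnames(X)),
            class = "response_model")
}

#' Predict score change from a fitted response model
#'
#' @param model A [fit_response_model()] result.
#' @param predictor New FC predictor values.
#' @param covariates Covariates matching the fitted model (or `NULL`).
#' @return Predicted score changes.
#' @export
predict_response <- function(model, predictor, covariates = NULL) {
  X <- cbind(1, predictor)
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates)[
      , setdiff(colnames(as.data.frame(covariates)), "subject"), drop = FALSE])
    storage.mode(C) <- "double"
    X <- cbind(X, C)
  }
  as.numeric(X %*% model$coefficients)
}

#' Covariate columns of a study
#'
#' The covariates of the edge-wise and response designs: sex, age and mean
#' connectivity.
#'
#' @param study A `study_set`.
#' @param with_covariates `FALSE` returns `NULL` (the reduced models).
#' @return A tibble of covariates, or `NULL`.
#' @export
study_covariates <- function(study, with_covariates = TRUE) {
  if (!with_covariates) return(NULL)
  study$covariates[, c("sex", "age", "mean_fc")]
}

# One train/test evaluation: recompute selection (strategy "threshold"),
# weights and response model on the training subjects, predict the test
# subjects. Returns flagged = TRUE (with NA predictions) for degenerate
# folds (empty mask, zero-variance predictor).
run_fold <- function(study, train, test, strategy, with_covariates, signed,
                     p_thresh, direction, nbs_result, stat) {
  Y <- study$dz
  n_edge <- ncol(Y)
  covs <- study_covariates(study, with_covariates)
  covs_train <- if (is.null(covs)) NULL else covs[train, , drop = FALSE]
  covs_test <- if (is.null(covs)) NULL else covs[test, , drop = FALSE]
  s_train <- study$score_change[train]
  mask <- switch(strategy,
    all = seq_len(n_edge),
    threshold = {
      des <- edge_design(s_train,
                         if (with_covariates) covs_train else NULL)
      tmap <- edge_glm(Y[train, , drop = FALSE], des)
      select_edges("threshold", n_edge, t_map = tmap,
                   t_thresh = t_threshold(attr(tmap, "df"), p_thresh),
                   direction = direction)
    },
    nbs = select_edges("nbs", n_edge, nbs_result = nbs_result, stat = stat))
  if (!length(mask)) {
    return(list(pred = rep(NA_real_, length(test)), weights = NULL,
                flagged = TRUE, reason = "empty mask"))
  }
  wv <- edge_weights(Y[train, , drop = FALSE], s_train, covs_train,
                     signed = signed, mask = mask)
  p_train <- fc_predictor(Y[train, , drop = FALSE], wv)
  p_test <- fc_predictor(Y[test, , drop = FALSE], wv)
  if (isTRUE(attr(p_train, "flagged")) || sd(p_train) == 0) {
    return(list(pred = rep(NA_real_, length(test)), weights = wv,
                flagged = TRUE, reason = "degenerate predictor"))
  }
  model <- fit_response_model(p_train, covs_train, s_train)
  list(pred = predict_response(model, p_test, covs_test), weights = wv,
       flagged = FALSE, reason = NA_character_)
}

new_cv_result <- function(scheme, predictions, per_redraw, r_pooled, r_median,
                          weights, strategy, with_covariates, signed,
                          circular, n_flagged, seed, n_nodes) {
  structure(list(scheme = scheme, predictions = predictions,
                 per_redraw = per_redraw, r_pooled = r_pooled,
                 r_median = r_median, weights = weights, strategy = strategy,
                 with_covariates = with_covariates, signed = signed,
                 circular = circular, n_flagged = n_flagged, seed = seed,
                 n_nodes = n_nodes),
            class = "cv_result")
}

#' Leave-one-out cross-validation of the FC predictor
#'
#' For every held-out subject the edge selection (strategy `"threshold"`),
#' weights and response model are recomputed on the remaining subjects and
#' the held-out score change is predicted; the generalizability estimate is
#' the Pearson correlation between the pooled held-out predictions and the
#' actual changes. Flagged folds (empty selection, degenerate predictor)
#' are recorded and excluded from pooling.
#'
#' @param study A `study_set`.
#' @param strategy `"all"`, `"threshold"` or `"nbs"` (the last is the
#'   circular variant; see [insample_circular()]).
#' @param with_covariates Include sex, age and mean connectivity in the
#'   weights (partial correlations) and the response model?
#' @param signed Signed edge weights?
#' @param p_thresh Edge-inclusion tail probability for `"threshold"`.
#' @param direction Contrast direction for `"threshold"`.
#' @param nbs_result Full-sample NBS result for `"nbs"`.
#' @param stat Component statistic flag used by `"nbs"`.
#' @param store_weights Keep the per-fold weight vectors (needed for
#'   [median_weight_matrix()])?
#' @return Object of class `cv_result` with pooled predictions and
#'   `r_pooled`.
#' @export
loocv <- function(study, strategy = "all", with_covariates = TRUE,
                  signed = FALSE, p_thresh = 0.001, direction = 1,
                  nbs_result = NULL, stat = "extent", store_weights = TRUE) {
  n <- length(study$score_change)
  if (n < 10) abort("need at least 10 subjects for LOOCV.")
  n_edge <- ncol(study$dz)
  preds <- rep(NA_real_, n)
  flagged <- logical(n)
  W <- if (store_weights) matrix(0, n, n_edge) else NULL
  for (i in seq_len(n)) {
    fold <- run_fold(study, setdiff(seq_len(n), i), i, strategy,
                     with_covariates, signed, p_thresh, direction,
                     nbs_result, stat)
    preds[i] <- fold$pred
    flagged[i] <- fold$flagged
    if (store_weights && !is.null(fold$weights)) {
      W[i, ] <- fold$weights$weights
    }
  }
  ok <- !flagged
  r <- if (sum(ok) >= 3 && sd(preds[ok]) > 0) {
    cor(preds[ok], study$score_change[ok])
  } else NA_real_
  predictions <- tibble::tibble(
    subject = study$covariates$subject, fold = seq_len(n),
    actual = study$score_change, predicted = preds, flagged = flagged)
  new_cv_result("loocv", predictions, per_redraw = NULL, r_pooled = r,
                r_median = r, weights = W, strategy = strategy,
                with_covariates = with_covariates, signed = signed,
                circular = identical(strategy, "nbs"),
                n_flagged = sum(flagged), seed = NULL,
                n_nodes = study$n_nodes)
}

#' Repeated 3-fold cross-validation without role reversal
#'
#' Per redraw, subjects are randomly partitioned into three folds and one
#' randomly chosen fold serves as the test set while the other two train
#' the model — there is no rotation of test and training roles. The
#' per-redraw Pearson correlation on the test fold is summarized by its
#' median over redraws.
#'
#' @inheritParams loocv
#' @param n_redraws Number of redraws (study value 1,000).
#' @param seed Seed of the redraw stream.
#' @return Object of class `cv_result` with `per_redraw` correlations and
#'   `r_median`.
#' @export
repeated_3fold <- function(study, strategy = "all", with_covariates = TRUE,
                           signed = FALSE, p_thresh = 0.001, direction = 1,
                           nbs_result = NULL, stat = "extent",
                           n_redraws = 1000, seed = 1L,
                           store_weights = TRUE) {
  n <- length(study$score_change)
  if (n < 12) abort("need at least 12 subjects for 3-fold CV.")
  local_seed(seed)
  n_edge <- ncol(study$dz)
  r_redraw <- rep(NA_real_, n_redraws)
  flagged <- logical(n_redraws)
  W <- if (store_weights) matrix(0, n_redraws, n_edge) else NULL
  for (b in seq_len(n_redraws)) {
    membership <- sample(rep_len(1:3, n))
    test_fold <- sample.int(3, 1)
    test <- which(membership == test_fold)
    train <- which(membership != test_fold)
    fold <- run_fold(study, train, test, strategy, with_covariates, signed,
                     p_thresh, direction, nbs_result, stat)
    if (store_weights && !is.null(fold$weights)) {
      W[b, ] <- fold$weights$weights
    }
    if (fold$flagged || sd(fold$pred) == 0 ||
        sd(study$score_change[test]) == 0) {
      flagged[b] <- TRUE
      next
    }
    r_redraw[b] <- cor(fold$pred, study$score_change[test])
  }
  per_redraw <- tibble::tibble(redraw = seq_len(n_redraws), r = r_redraw,
                               flagged = flagged)
  new_cv_result("repeated3fold", predictions = NULL, per_redraw = per_redraw,
                r_pooled = NA_real_,
                r_median = median(r_redraw, na.rm = TRUE), weights = W,
                strategy = strategy, with_covariates = with_covariates,
                signed = signed, circular = identical(strategy, "nbs"),
                n_flagged = sum(flagged), seed = seed,
                n_nodes = study$n_nodes)
}

#' Deliberately circular (double-dipping) cross-validation
#'
#' The edge selection is fixed from an NBS run on the *full* sample —
#' including the subjects later used as test cases — and the usual CV is
#' then run on that fixed selection. Because the selection already saw the
#' outcome of every subject, the resulting correlations are inflated; the
#' procedure is retained only to demonstrate that inflation against the
#' honest strategies, and its result is always labeled circular.
#'
#' @param study A `study_set`.
#' @param nbs_result NBS result computed on the full sample.
#' @param scheme `"loocv"` or `"repeated3fold"`.
#' @param ... Passed to the scheme function.
#' @return A `cv_result` with `circular = TRUE` (flagged non-prediction
#'   when the NBS selection is empty).
#' @export
insample_circular <- function(study, nbs_result,
                              scheme = c("loocv", "repeated3fold"), ...) {
  scheme <- match.arg(scheme)
  if (scheme == "loocv") {
    loocv(study, strategy = "nbs", nbs_result = nbs_result, ...)
  } else {
    repeated_3fold(study, strategy = "nbs", nbs_result = nbs_result, ...)
  }
}

#' Sidak correction for multiplicity
#'
#' `p' = 1 - (1 - p)^m`, capped at 1; the study adjusts for the number of
#' factors per questionnaire (six factors plus the sum, m = 7).
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of tests.
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Median weight matrix across folds or redraws
#'
#' Per edge, the median of the weight over all folds/redraws, with
#' unselected edges entering as 0 — so an edge selected in fewer than half
#' the redraws has median weight 0.
#'
#' @param cv A `cv_result` fitted with `store_weights = TRUE`.
#' @return Symmetric node-by-node matrix of median weights.
#' @export
median_weight_matrix <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  if (is.null(cv$weights)) abort("cv_result was fitted without stored weights.")
  med <- apply(cv$weights, 2, median)
  sym_from_vec(med, cv$n_nodes)
}

#' Top-k nodes and edges of a weight matrix
#'
#' Nodes are ranked by the sum of weights of adjacent edges, edges by their
#' weight; ties are broken by index.
#'
#' @param weight_matrix Symmetric nonnegative node-by-node matrix.
#' @param k Number of nodes/edges to report.
#' @return List of tibbles `nodes` (node, weight_sum) and `edges`
#'   (i, j, weight).
#' @export
top_nodes_edges <- function(weight_matrix, k = 10) {
  W <- as.matrix(weight_matrix)
  n <- nrow(W)
  sums <- rowSums(W)
  node_ord <- order(-sums, seq_len(n))
  pairs <- edge_pairs(n)
  w <- ut_vec(W)
  edge_ord <- order(-w, seq_along(w))
  list(
    nodes = tibble::tibble(node = node_ord[seq_len(min(k, n))],
                           weight_sum = sums[node_ord[seq_len(min(k, n))]]),
    edges = tibble::tibble(
      i = pairs[edge_ord[seq_len(min(k, length(w)))], 1],
      j = pairs[edge_ord[seq_len(min(k, length(w)))], 2],
      weight = w[edge_ord[seq_len(min(k, length(w)))]])
  )
}

# Rank (Mann-Whitney) AUC of a continuous score against a binary outcome,
# ties counted one half.
auc_rank <- function(score, outcome) {
  outcome <- as.logical(outcome)
  n1 <- sum(outcome)
  n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Post-hoc classification metrics of threshold-free predictions
#'
#' The continuous predicted score *reductions* (pre minus post) are
#' evaluated against the clinical dichotomizations: AUC is the Mann-Whitney
#' rank statistic of the prediction against each outcome (ties one half);
#' balanced accuracy applies the clinical cutoffs to the predicted
#' post-score `pre_sum - predicted_reduction` (remission: predicted post
#' <= 7; response: predicted reduction >= half the pre-score) and averages
#' sensitivity and specificity. Outcomes with a single class are flagged
#' undefined (`NA`).
#'
#' @param predicted_reduction Predicted score reduction per subject
#'   (pre minus post; the negative of a post-minus-pre change).
#' @param pre_sum Pre-treatment questionnaire totals.
#' @param remission,response Actual binary outcomes.
#' @return Tibble with `auc_remission`, `auc_response`, `bac_remission`,
#'   `bac_response`.
#' @export
roc_metrics <- function(predicted_reduction, pre_sum, remission, response) {
  bac <- function(pred_label, outcome) {
    outcome <- as.logical(outcome)
    if (!any(outcome) || all(outcome)) return(NA_real_)
    sens <- mean(pred_label[outcome])
    spec <- mean(!pred_label[!outcome])
    (sens + spec) / 2
  }
  predicted_post <- pre_sum - predicted_reduction
  pred_rem <- predicted_post <= 7
  pred_resp <- predicted_reduction >= 0.5 * pre_sum
  tibble::tibble(
    auc_remission = auc_rank(predicted_reduction, remission),
    auc_response = auc_rank(predicted_reduction, response),
    bac_remission = bac(pred_rem, remission),
    bac_response = bac(pred_resp, response)
  )
}

#' ROC curve points of a continuous prediction
#'
#' Sensitivity/specificity at every distinct threshold, for plotting.
#'
#' @param score Continuous prediction (higher = more likely positive).
#' @param outcome Binary outcome.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve_points <- function(score, outcome) {
  outcome <- as.logical(outcome)
  th <- c(-Inf, sort(unique(score)), Inf)
  purrr::map_dfr(th, function(t0) {
    pred <- score >= t0
    tibble::tibble(threshold = t0,
                   sensitivity = if (any(outcome)) mean(pred[outcome]) else NA,
                   specificity = if (any(!outcome)) mean(!pred[!outcome]) else NA)
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$scheme, ", strategy ", x$strategy,
      if (x$circular) " (CIRCULAR: selection saw the test data)", "\n",
      "  covariates: ", x$with_covariates, "; signed: ", x$signed, "\n",
      sep = "")
  if (!is.null(x$r_pooled) && !is.na(x$r_pooled)) {
    cat("  pooled r =", round(x$r_pooled, 3), "\n")
  }
  if (!is.null(x$per_redraw)) {
    cat("  median r over", nrow(x$per_redraw), "redraws =",
        round(x$r_median, 3), "\n")
  }
  if (x$n_flagged > 0) cat("  flagged folds/redraws:", x$n_flagged, "\n")
  invisible(x)
}
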