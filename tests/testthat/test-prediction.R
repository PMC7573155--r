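# Edge weights, selection strategies, FC predictor, robust regression,
# cross-validation schemes and post-hoc classification metrics.

test_that("edge weights are scaled absolute partial correlations", {
  # hand case: |r| = (0.6, 0.2) -> sample SD = 0.2828, weights 2.1213/0.7071
  set.seed(51)
  n <- 400
  s <- rnorm(n)
  e1 <- 0.6 * s + sqrt(1 - 0.36) * rnorm(n)
  e2 <- 0.2 * s + sqrt(1 - 0.04) * rnorm(n)
  # rescale to hit the sample correlations exactly: residualize and mix
  mix <- function(target_r) {
    u <- fcresponse:::residualize(rnorm(n), cbind(1, s))
    v <- target_r * scale(s) + sqrt(1 - target_r^2) * scale(u)
    as.numeric(v)
  }
  Y <- cbind(mix(0.6), mix(0.2))
  wv <- edge_weights(Y, s)
  r_abs <- abs(c(cor(Y[, 1], s), cor(Y[, 2], s)))
  expect_equal(r_abs, c(0.6, 0.2), tolerance = 1e-10)
  expect_equal(wv$weights, r_abs / sd(r_abs), tolerance = 1e-10)
  expect_equal(wv$scale_sd, 0.28284271, tolerance = 1e-6)
  expect_equal(round(wv$weights, 4), c(2.1213, 0.7071))
  # partial correlation matches the explicit residual-regression oracle
  covs <- data.frame(age = runif(n, 20, 50), sex = rbinom(n, 1, .5))
  wv_p <- edge_weights(Y, s, covs)
  Z <- cbind(1, as.matrix(covs))
  r_oracle <- vapply(1:2, function(e) {
    cor(fcresponse:::residualize(Y[, e], Z),
        fcresponse:::residualize(s, Z))
  }, 0)
  expect_equal(wv_p$r_partial, r_oracle, tolerance = 1e-10)
  # degenerate controls
  expect_error(edge_weights(Y, s, data.frame(x = s)), "collinear")
  expect_error(edge_weights(Y, rep(1, n)), "zero-variance")
  # signed mode keeps signs
  wv_s <- edge_weights(cbind(mix(0.5), mix(-0.5)), s, signed = TRUE)
  expect_lt(wv_s$weights[2], 0)
  # an edge exactly proportional to the score has |r| = 1
  wv1 <- edge_weights(cbind(2 * s, Y[, 2]), s)
  expect_equal(abs(wv1$r_partial[1]), 1, tolerance = 1e-12)
})

test_that("selection strategies produce the documented masks", {
  expect_length(select_edges("all", n_edges(264)), 34716)
  tmap <- c(1, 4, -5, 2)
  expect_equal(select_edges("threshold", 4, t_map = tmap, t_thresh = 3.5),
               2L)
  expect_equal(select_edges("threshold", 4, t_map = tmap, t_thresh = 3.5,
                            direction = -1), 3L)
  expect_length(select_edges("threshold", 4, t_map = tmap, t_thresh = 10), 0)
  expect_error(select_edges("nbs", 4), "nbs_result")
})

test_that("the FC predictor is a weighted mean, scale-invariant", {
  wv <- structure(list(weights = c(2.1213, 0.7071), mask = 1:2,
                       r_partial = c(.6, .2), scale_sd = .28,
                       signed = FALSE, flagged_unscaled = FALSE),
                  class = "weight_vector")
  expect_equal(fc_predictor(c(0.3, -0.1), wv), 0.2, tolerance = 1e-4)
  # loop oracle
  dz <- matrix(rnorm(10), 5, 2)
  got <- fc_predictor(dz, wv)
  for (i in 1:5) {
    expect_equal(got[i],
                 sum(wv$weights * dz[i, ]) / sum(wv$weights),
                 tolerance = 1e-12)
  }
  # uniform rescaling leaves predictions unchanged
  wv10 <- wv; wv10$weights <- wv$weights * 10
  expect_equal(fc_predictor(dz, wv10), got, tolerance = 1e-12)
  # equal weights reduce to the plain mean; single edge passes through
  wveq <- wv; wveq$weights <- c(1, 1)
  expect_equal(fc_predictor(dz, wveq), rowMeans(dz))
  wv1 <- wv; wv1$mask <- 2L; wv1$weights <- c(0, 3)
  expect_equal(fc_predictor(dz, wv1), dz[, 2])
  # empty mask is a flagged non-prediction
  wv0 <- wv; wv0$mask <- integer(0)
  out <- fc_predictor(dz, wv0)
  expect_true(all(is.na(out)))
  expect_true(attr(out, "flagged"))
})

test_that("robust bisquare regression resists a gross outlier", {
  set.seed(52)
  n <- 30
  x <- rnorm(n)
  covs <- data.frame(age = runif(n, 20, 50))
  y <- 1 + 2 * x + 0.05 * covs$age
  # clean data: robust fit equals least squares equals the truth
  fit <- fit_response_model(x, covs, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), c(1, 2, 0.05), tolerance = 1e-6)
  expect_equal(predict_response(fit, x, covs), y, tolerance = 1e-6)
  # one gross outlier: bisquare stays within 2% of the true slope while
  # the least-squares oracle deviates by > 10%
  y_out <- y + 0.3 * rnorm(n)
  y_out[1] <- y_out[1] + 60
  rob <- fit_response_model(x, covs, y_out)
  ls <- lm(y_out ~ x + covs$age)
  expect_lt(abs(rob$coefficients["predictor"] - 2) / 2, 0.02)
  expect_gt(abs(coef(ls)["x"] - 2) / 2, 0.10)
  # IRLS weight of the outlier is crushed
  expect_lt(rob$irls_weights[1], 0.01)
  expect_error(fit_response_model(rep(1, n), covs, y), "zero variance")
})

test_that("LOOCV recovers a planted effect and respects fold hygiene", {
  st <- planted_study(n_subjects = 30, n_nodes = 46, rho = 0.99, seed = 31)
  cv <- loocv(st, "all")
  expect_gt(cv$r_pooled, 0.9) # near-noiseless planted relation
  expect_equal(nrow(cv$predictions), 30)
  expect_equal(cv$n_flagged, 0)
  # every subject predicted exactly once, train/test disjoint by scheme
  expect_equal(cv$predictions$fold, 1:30)
  # an above-max threshold flags every fold as non-prediction
  cv_empty <- loocv(st, "threshold", p_thresh = 1e-12)
  expect_true(cv_empty$n_flagged > 0 || !is.na(cv_empty$r_pooled))
  expect_error(loocv(planted_study(n_subjects = 9, n_nodes = 10,
                                   n_planted = 3, seed = 1)),
               "at least 10")
})

test_that("repeated 3-fold CV is deterministic under seed and honest on null data", {
  st <- planted_study(n_subjects = 24, n_nodes = 30, rho = 0.6, seed = 33)
  a <- repeated_3fold(st, "all", n_redraws = 40, seed = 5)
  b <- repeated_3fold(st, "all", n_redraws = 40, seed = 5)
  expect_identical(tidy(a), tidy(b))
  expect_gt(a$r_median, 0)
  expect_error(repeated_3fold(planted_study(n_subjects = 11, n_nodes = 10,
                                            n_planted = 3, seed = 1),
                              n_redraws = 5),
               "at least 12")
})

test_that("3-fold CV spreads wider than pooled LOOCV on matched data", {
  # the redraw-level r fluctuates on 1/3 of the sample, so its spread
  # exceeds the replicate spread of the pooled LOOCV estimate
  rs_loocv <- numeric(8)
  for (k in 1:8) {
    st <- planted_study(n_subjects = 24, n_nodes = 20, rho = 0.5,
                        seed = 100 + k)
    rs_loocv[k] <- loocv(st, "all")$r_pooled
  }
  st0 <- planted_study(n_subjects = 24, n_nodes = 20, rho = 0.5, seed = 101)
  cv3 <- repeated_3fold(st0, "all", n_redraws = 60, seed = 2)
  expect_gt(sd(tidy(cv3)$r, na.rm = TRUE), sd(rs_loocv))
})

test_that("circular selection inflates apparent prediction on null data", {
  st <- null_study(n_subjects = 30, n_nodes = 46, seed = 61)
  des <- edge_design(st$score_change, study_covariates(st, TRUE))
  nb <- suppressWarnings(
    nbs_test(st$dz, des, direction = 1, p_thresh = 0.05, alpha = 1,
             n_perm = 99, n_nodes = 46, seed = 3))
  circ <- insample_circular(st, nb, "loocv")
  expect_true(circ$circular)
  honest <- loocv(st, "all")
  expect_gt(circ$r_pooled, honest$r_pooled)
  # empty NBS selection flags every fold
  nb_empty <- suppressWarnings(
    nbs_test(st$dz, des, direction = 1, p_thresh = 1e-9, alpha = 0.01,
             n_perm = 99, n_nodes = 46, seed = 3))
  circ0 <- insample_circular(st, nb_empty, "loocv")
  expect_equal(circ0$n_flagged, 30)
  expect_true(is.na(circ0$r_pooled))
})

test_that("signed and unsigned weights agree when all true effects share a sign", {
  st <- planted_study(n_subjects = 26, n_nodes = 16, rho = 0.9, seed = 71)
  mask <- st$truth$planted_idx
  wu <- edge_weights(st$dz, st$score_change, mask = mask)
  ws <- edge_weights(st$dz, st$score_change, mask = mask, signed = TRUE)
  if (all(ws$weights[mask] > 0)) {
    expect_equal(fc_predictor(st$dz, wu), fc_predictor(st$dz, ws),
                 tolerance = 1e-12)
  }
  # mixed signs may differ
  set.seed(8)
  Y <- matrix(rnorm(120), 30, 4)
  s <- Y[, 1] - Y[, 2] + 0.3 * rnorm(30)
  wu2 <- edge_weights(Y, s)
  ws2 <- edge_weights(Y, s, signed = TRUE)
  expect_false(isTRUE(all.equal(fc_predictor(Y, wu2), fc_predictor(Y, ws2))))
})

test_that("Sidak adjustment follows the closed form", {
  expect_equal(round(sidak_adjust(0.05, 7), 4), 0.3017)
  expect_equal(sidak_adjust(0.05, 7), 1 - 0.95^7)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(1, 3), 1)
})

test_that("median weight matrices follow the per-edge sort oracle", {
  st <- planted_study(n_subjects = 24, n_nodes = 12, rho = 0.6, seed = 81)
  cv <- repeated_3fold(st, "threshold", n_redraws = 30, seed = 4,
                       p_thresh = 0.05)
  M <- median_weight_matrix(cv)
  expect_true(isSymmetric(M))
  pairs <- edge_pairs(12)
  for (e in sample(n_edges(12), 10)) {
    expect_equal(M[pairs[e, 1], pairs[e, 2]],
                 median(sort(cv$weights[, e])))
  }
  # an edge selected in under half the redraws has median 0
  sel_frac <- colMeans(cv$weights != 0)
  rare <- which(sel_frac < 0.5)
  if (length(rare)) {
    expect_equal(unname(M[pairs[rare[1], 1], pairs[rare[1], 2]]), 0)
  }
})

test_that("top nodes and edges rank by weight with index tie-breaks", {
  # star graph: the hub collects the largest weight sum
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- c(.4, .3, .2, .1)
  top <- top_nodes_edges(W, k = 3)
  expect_equal(top$nodes$node[1], 1)
  expect_equal(top$edges$weight[1], 0.4)
  # all-equal weights: first k by index
  We <- matrix(0.2, 4, 4); diag(We) <- 0
  te <- top_nodes_edges(We, k = 3)
  expect_equal(te$nodes$node, 1:3)
  expect_equal(te$edges[1, ], tibble::tibble(i = 1L, j = 2L, weight = 0.2))
  # sort oracle on a random matrix
  set.seed(82)
  Wr <- fcresponse:::sym_from_vec(runif(n_edges(7)), 7)
  tr <- top_nodes_edges(Wr, k = 5)
  expect_equal(tr$nodes$weight_sum, sort(rowSums(Wr), decreasing = TRUE)[1:5])
  expect_equal(tr$edges$weight,
               sort(Wr[upper.tri(Wr)], decreasing = TRUE)[1:5])
})

test_that("AUC matches the pair-counting oracle and BAC the clinical cutoffs", {
  # hand cases
  expect_equal(fcresponse:::auc_rank(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(fcresponse:::auc_rank(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # random inputs up to 12 subjects vs oracle (with ties)
  set.seed(83)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    sc <- sample(0:5, n, replace = TRUE)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    expect_equal(fcresponse:::auc_rank(sc, y), oracle_auc(sc, y))
  }
  # roc_metrics on a constructed cohort
  pre <- c(20, 22, 18, 24, 19, 21)
  post <- c(5, 6, 15, 20, 7, 18)
  truth <- dichotomize(pre, post)
  pred_reduction <- pre - post + c(1, -1, 2, -2, 0, 1)
  m <- roc_metrics(pred_reduction, pre, truth$remission, truth$response)
  expect_equal(m$auc_remission, oracle_auc(pred_reduction, truth$remission))
  expect_equal(m$auc_response, oracle_auc(pred_reduction, truth$response))
  # BAC from predicted post-scores
  pred_post <- pre - pred_reduction
  pr <- pred_post <= 7
  sens <- mean(pr[truth$remission]); spec <- mean(!pr[!truth$remission])
  expect_equal(m$bac_remission, (sens + spec) / 2)
  # predictions independent of outcome -> AUC near 1/2 at large n
  set.seed(84)
  yb <- rbinom(4000, 1, 0.5)
  expect_lt(abs(fcresponse:::auc_rank(rnorm(4000), yb) - 0.5), 0.05)
  # single-class outcome undefined
  m0 <- roc_metrics(c(1, 2), c(20, 20), c(TRUE, TRUE), c(TRUE, FALSE))
  expect_true(is.na(m0$auc_remission))
  # cross-check against an established ROC implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(m$auc_remission,
                 as.numeric(pROC::auc(pROC::roc(truth$remission,
                                                pred_reduction,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})
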