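# Synthetic study generator -------------------------------------------------
#
# The study this package emulates is a within-subject pharmacological
# challenge: each subject contributes one verum and one placebo resting-state
# connectivity matrix, questionnaire items before and after treatment, and
# age/sex covariates. None of the clinical data is deposited, so every
# downstream stage is exercised on data generated here with known ground
# truth: an orthogonal latent factor structure behind the items, and a
# planted connected edge subnetwork whose verum-minus-placebo connectivity
# difference correlates with the score change at a controlled effect size.

#' Specification of a synthetic challenge study
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' sample size, connectome size, questionnaire model (loading matrix and item
#' noise), the planted predictive subnetwork and its effect size, background
#' connectivity noise, and covariate effects.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of connectome nodes.
#' @param loading_matrix Items-by-factors matrix of true loadings; must have
#'   full column rank. Rows with unit norm give unit-variance items when
#'   `item_noise_sd` absorbs the remaining variance.
#' @param item_noise_sd Standard deviation of item-level noise, either a
#'   scalar or one value per item.
#' @param item_range Inclusive integer score range of every item, e.g.
#'   `c(0, 4)` for clinician-rated or `c(0, 3)` for self-rated layouts.
#' @param planted_edges Two-column matrix of node pairs forming the planted
#'   subnetwork; must induce a single connected component on the nodes it
#'   touches. `NULL` for a global-null study.
#' @param effect_rho Target population correlation, in \[-1, 1\], between the
#'   planted-edge connectivity difference and the score change.
#' @param background_sd Standard deviation (z-units) of the background
#'   connectivity noise in each condition.
#' @param covariate_effects Named or length-2 numeric `c(sex, age)`: linear
#'   effect of each standardized covariate on the planted-edge connectivity
#'   difference. Defaults to no covariate effect.
#' @param factor_shift Mean pre-to-post shift of each latent factor
#'   (recycled); drives true treatment response in the questionnaire.
#' @param shift_sd Subject-level SD of the latent factor shift.
#' @param seed Integer seed; every generator draws from an RNG fully
#'   determined by it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects,
                       n_nodes = 60,
                       loading_matrix = default_loading_matrix(),
                       item_noise_sd = NULL,
                       item_range = c(0L, 4L),
                       planted_edges = NULL,
                       effect_rho = 0,
                       background_sd = 0.1,
                       covariate_effects = c(sex = 0, age = 0),
                       factor_shift = 0,
                       shift_sd = 1,
                       seed = 1L) {
  loading_matrix <- as.matrix(loading_matrix)
  n_items <- nrow(loading_matrix)
  n_factors <- ncol(loading_matrix)
  if (qr(loading_matrix)$rank < n_factors) {
    abort("invalid spec: `loading_matrix` is rank-deficient.")
  }
  if (is.null(item_noise_sd)) {
    # absorb the variance the common factors leave over (unit-variance items)
    u2 <- pmax(1 - rowSums(loading_matrix^2), 1e-4)
    item_noise_sd <- sqrt(u2)
  }
  if (any(item_noise_sd <= 0) || background_sd <= 0 || shift_sd < 0) {
    abort("invalid spec: all SDs must be positive.")
  }
  if (abs(effect_rho) > 1) abort("invalid spec: |effect_rho| must be <= 1.")
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (ncol(planted_edges) != 2) abort("`planted_edges` needs two columns.")
    if (any(planted_edges < 1) || any(planted_edges > n_nodes) ||
        any(planted_edges[, 1] == planted_edges[, 2])) {
      abort("invalid spec: planted edges outside node range or self-loops.")
    }
    g <- igraph::graph_from_edgelist(apply(planted_edges, 2, as.integer),
                                     directed = FALSE)
    comp <- igraph::components(g)
    touched <- unique(as.integer(planted_edges))
    if (length(unique(comp$membership[touched])) != 1) {
      abort("invalid spec: planted edges must form one connected component.")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    n_items = n_items, n_factors = n_factors,
    loading_matrix = loading_matrix,
    item_noise_sd = rep_len(item_noise_sd, n_items),
    item_range = as.integer(item_range),
    planted_edges = planted_edges, effect_rho = effect_rho,
    background_sd = background_sd,
    covariate_effects = rep_len(covariate_effects, 2),
    factor_shift = rep_len(factor_shift, n_factors), shift_sd = shift_sd,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' Default 17-item, 6-factor orthogonal loading pattern
#'
#' A simple-structure loading matrix in the layout of a 17-item
#' clinician-rated depression questionnaire summarized by six orthogonal
#' factors: five factors carry three items each and one carries two, with
#' primary loadings of 0.75/0.8 and no cross-loadings.
#'
#' @param primary Loading of each item on its factor.
#' @return A 17 x 6 matrix.
#' @export
default_loading_matrix <- function(primary = 0.75) {
  lambda <- matrix(0, 17, 6)
  blocks <- split(1:17, rep(1:6, times = c(3, 3, 3, 3, 3, 2)))
  for (f in seq_along(blocks)) {
    lambda[blocks[[f]], f] <- ifelse(length(blocks[[f]]) == 2, 0.8, primary)
  }
  dimnames(lambda) <- list(paste0("I", 1:17), paste0("F", 1:6))
  lambda
}

#' Generate pre- and post-treatment questionnaire item tables
#'
#' Items are linear combinations of orthogonal standard-normal latent
#' factors (`loading_matrix`) plus item noise. Post-treatment items are
#' produced from latent factors shifted by `factor_shift` (plus
#' subject-level `shift_sd` noise), so the true factor-change values are
#' returned alongside the tables. With `discretize = TRUE` the continuous
#' items are mapped to the declared integer score range (mean at mid-range,
#' SD a quarter of the range, rounded and clipped); the continuous values
#' are returned either way for calibration checks.
#'
#' @param spec A [synth_spec()].
#' @param discretize Round and clip items to `spec$item_range`?
#' @param seed Seed; defaults to `spec$seed`.
#' @return A list of class `item_tables`: tibbles `pre` and `post`
#'   (`subject` column plus one column per item), matrices `latent_pre`,
#'   `latent_post`, `factor_change`, and the continuous item matrices.
#' @export
gen_questionnaire <- function(spec, discretize = TRUE, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_subjects < 3 * spec$n_factors) {
    abort("need n_subjects >= 3 * n_factors.")
  }
  local_seed(seed)
  n <- spec$n_subjects; p <- spec$n_items; k <- spec$n_factors
  lambda <- spec$loading_matrix
  f_pre <- matrix(rnorm(n * k), n, k)
  shift <- matrix(spec$factor_shift, n, k, byrow = TRUE) +
    spec$shift_sd * matrix(rnorm(n * k), n, k)
  f_post <- f_pre + shift
  noise_pre <- matrix(rnorm(n * p), n, p)
  noise_post <- matrix(rnorm(n * p), n, p)
  cont_pre <- f_pre %*% t(lambda) + sweep(noise_pre, 2, spec$item_noise_sd, "*")
  cont_post <- f_post %*% t(lambda) + sweep(noise_post, 2, spec$item_noise_sd, "*")
  items <- rownames(lambda) %||% paste0("I", 1:p)
  colnames(cont_pre) <- colnames(cont_post) <- items
  to_table <- function(x, occasion) {
    if (discretize) {
      mid <- mean(spec$item_range)
      half <- diff(spec$item_range) / 4
      x <- pmin(pmax(round(mid + half * x), spec$item_range[1]),
                spec$item_range[2])
    }
    out <- tibble::as_tibble(x)
    out <- dplyr::bind_cols(tibble::tibble(subject = paste0("S", 1:n)), out)
    attr(out, "occasion") <- occasion
    out
  }
  structure(list(
    pre = to_table(cont_pre, "pre"), post = to_table(cont_post, "post"),
    latent_pre = f_pre, latent_post = f_post, factor_change = shift,
    continuous_pre = cont_pre, continuous_post = cont_post,
    item_range = spec$item_range
  ), class = "item_tables")
}

#' Generate a per-subject, per-condition connectivity study
#'
#' Each condition's z-matrix is symmetric zero-diagonal background noise
#' (independent between conditions, SD `background_sd`); on the planted
#' edges the verum condition additionally carries an effect term scaled so
#' that the population correlation between the planted-edge connectivity
#' difference and `score_changes` equals `effect_rho` marginally (covariate
#' effects, when requested, are accounted for in the scaling). Age is
#' uniform on 20-55 years and sex a balanced binary covariate; the
#' mean-connectivity covariate is the pooled upper-triangle mean over both
#' conditions.
#'
#' @param spec A [synth_spec()].
#' @param score_changes Numeric, one score change (post minus pre) per
#'   subject; the quantity the planted subnetwork predicts.
#' @param seed Seed; defaults to `spec$seed`.
#' @param keep_matrices Keep the full node-by-node z-matrix arrays (set
#'   `FALSE` in large simulations; the edge stack is always kept).
#' @return An object of class `study_set`: `dz` (subjects x edges difference
#'   stack), optional `verum_z`/`placebo_z` arrays, `covariates` tibble
#'   (subject, age, sex, mean_fc), `score_change`, `edge_pairs`, and a
#'   `truth` list with the planted edge indices and effect scaling.
#' @export
gen_connectivity_study <- function(spec, score_changes, seed = spec$seed,
                                   keep_matrices = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_subjects
  if (n < 1) abort("n_subjects must be >= 1.")
  if (length(score_changes) != n) {
    abort("`score_changes` must have one value per subject.")
  }
  if (spec$effect_rho != 0 && sd(score_changes) == 0) {
    abort("effect_rho != 0 requires score_changes with nonzero variance.")
  }
  local_seed(seed)
  nn <- spec$n_nodes
  ne <- n_edges(nn)
  pairs <- edge_pairs(nn)
  placebo <- matrix(rnorm(n * ne, sd = spec$background_sd), n, ne)
  verum <- matrix(rnorm(n * ne, sd = spec$background_sd), n, ne)

  age <- runif(n, 20, 55)
  sex <- sample(rep_len(c(0L, 1L), n))
  planted_idx <- integer(0)
  alpha <- 0
  if (!is.null(spec$planted_edges) && nrow(spec$planted_edges) > 0) {
    planted_idx <- edge_index(spec$planted_edges[, 1], spec$planted_edges[, 2], nn)
    s_std <- if (sd(score_changes) > 0) {
      (score_changes - mean(score_changes)) / sd(score_changes)
    } else rep(0, n)
    gam <- spec$covariate_effects
    cov_term <- 0
    if (any(gam != 0)) {
      sx <- (sex - mean(sex)) / sd(sex)
      ag <- (age - mean(age)) / sd(age)
      cov_term <- gam[1] * sx + gam[2] * ag
    }
    rho <- spec$effect_rho
    if (abs(rho) == 1) {
      # noiseless limiting case: the difference on planted edges is the
      # standardized score exactly
      verum[, planted_idx] <- placebo[, planted_idx] +
        outer(sign(rho) * s_std + cov_term, rep(1, length(planted_idx)))
      alpha <- sign(rho)
    } else {
      sd_delta2 <- 2 * spec$background_sd^2 + sum(gam^2)
      alpha <- rho * sqrt(sd_delta2) / sqrt(1 - rho^2)
      verum[, planted_idx] <- verum[, planted_idx] +
        outer(alpha * s_std + cov_term, rep(1, length(planted_idx)))
    }
  }
  dz <- verum - placebo
  mean_fc <- rowMeans(cbind(verum, placebo))
  arrays <- NULL
  if (keep_matrices) {
    to_array <- function(stack) {
      a <- array(0, c(nn, nn, n))
      for (s in 1:n) a[, , s] <- sym_from_vec(stack[s, ], nn)
      a
    }
    arrays <- list(verum_z = to_array(verum), placebo_z = to_array(placebo))
  }
  structure(list(
    dz = dz,
    verum_z = arrays$verum_z, placebo_z = arrays$placebo_z,
    covariates = tibble::tibble(subject = paste0("S", 1:n),
                                age = age, sex = sex, mean_fc = mean_fc),
    score_change = as.numeric(score_changes),
    n_nodes = nn, edge_pairs = pairs,
    truth = list(planted_idx = planted_idx,
                 planted_edges = spec$planted_edges, alpha = alpha,
                 effect_rho = spec$effect_rho),
    seed = seed
  ), class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat("<study_set> ", length(x$score_change), " subjects, ",
      x$n_nodes, " nodes (", ncol(x$dz), " edges), ",
      length(x$truth$planted_idx), " planted edge(s)\n", sep = "")
  invisible(x)
}

#' Connected planted subnetwork on the first nodes of the graph
#'
#' Convenience constructor for a planted component: a path through
#' `n_edges_planted + 1` consecutive nodes, which is always a single
#' connected component.
#'
#' @param n_edges_planted Number of edges.
#' @param offset First node index minus one.
#' @return Two-column matrix of node pairs.
#' @export
planted_path_edges <- function(n_edges_planted = 10, offset = 0) {
  cbind(offset + 1:n_edges_planted, offset + 2:(n_edges_planted + 1))
}

#' Generate a 4-D imaging fixture with planted ROI signals
#'
#' Builds a small volume on an isotropic 2 mm grid: voxels inside 10 mm
#' diameter spheres around the ROI centers carry that ROI's latent signal,
#' voxels of the supplied tissue masks carry shared nuisance components, and
#' everything is overlaid with white noise. Ground-truth signals are
#' returned so extraction and cleaning can be checked exactly.
#'
#' @param n_frames Number of frames.
#' @param grid_shape Length-3 voxel counts (kept small, e.g. <= 40^3).
#' @param tr Repetition time in seconds.
#' @param roi_centers Matrix of ROI centers in mm (one row per ROI), in the
#'   grid's coordinate frame (voxel (1,1,1) center at the origin).
#' @param roi_signals Optional ROI-by-frame matrix of latent signals;
#'   standard-normal signals are drawn when omitted.
#' @param tissue_masks Optional named list of logical arrays (grid-shaped)
#'   marking nuisance tissue; defaults to a two-slab white-matter/CSF-like
#'   pair outside the spheres.
#' @param nuisance_signals Optional components-by-frame matrix of shared
#'   nuisance time courses added inside the tissue masks.
#' @param noise_sd White-noise SD added to every voxel.
#' @param seed Seed.
#' @return List of class `nifti_fixture`: `volume` (4-D array, with `spacing`
#'   attribute), `rois` (a `roi_set`), `tissue_masks`, `roi_signals`,
#'   `nuisance_signals`, `tr`.
#' @export
gen_nifti_fixture <- function(n_frames, grid_shape = c(20, 20, 20), tr = 2.5,
                              roi_centers, roi_signals = NULL,
                              tissue_masks = NULL, nuisance_signals = NULL,
                              noise_sd = 0, seed = 1L) {
  local_seed(seed)
  roi_centers <- as.matrix(roi_centers)
  rois <- build_sphere_rois(roi_centers, grid_shape)
  k <- nrow(roi_centers)
  if (is.null(roi_signals)) {
    roi_signals <- matrix(rnorm(k * n_frames), k, n_frames)
  }
  stopifnot(nrow(roi_signals) == k, ncol(roi_signals) == n_frames)
  in_sphere <- logical(prod(grid_shape))
  for (v in rois$voxels) in_sphere[v] <- TRUE
  if (is.null(tissue_masks)) {
    wm <- csf <- array(FALSE, grid_shape)
    wm[, , 1] <- TRUE
    csf[, , grid_shape[3]] <- TRUE
    wm[array(in_sphere, grid_shape)] <- FALSE
    csf[array(in_sphere, grid_shape)] <- FALSE
    tissue_masks <- list(wm = wm, csf = csf)
  }
  if (is.null(nuisance_signals)) {
    nuisance_signals <- matrix(rnorm(2 * n_frames), 2, n_frames)
  }
  nv <- prod(grid_shape)
  vol <- matrix(rnorm(nv * n_frames, sd = noise_sd), nv, n_frames)
  for (r in seq_len(k)) {
    vol[rois$voxels[[r]], ] <-
      vol[rois$voxels[[r]], , drop = FALSE] +
      matrix(roi_signals[r, ], length(rois$voxels[[r]]), n_frames, byrow = TRUE)
  }
  nuis_total <- colSums(nuisance_signals)
  for (m in tissue_masks) {
    idx <- which(as.logical(m))
    vol[idx, ] <- vol[idx, , drop = FALSE] +
      matrix(nuis_total, length(idx), n_frames, byrow = TRUE)
  }
  volume <- array(vol, c(grid_shape, n_frames))
  attr(volume, "spacing") <- 2
  structure(list(volume = volume, rois = rois, tissue_masks = tissue_masks,
                 roi_signals = roi_signals,
                 nuisance_signals = nuisance_signals, tr = tr),
            class = "nifti_fixture")
}
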