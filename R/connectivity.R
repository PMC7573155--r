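# Connectivity construction -------------------------------------------------
#
# ROI time series are extracted as voxel means over non-overlapping 10 mm
# diameter spheres, cleaned with nuisance regression and band-pass filtering
# in a single model, Pearson-correlated and Fisher-z transformed. The
# verum-minus-placebo difference of the z-matrices is the input of all
# downstream inference.

#' Build non-overlapping spherical ROIs on a voxel grid
#'
#' A voxel belongs to a sphere iff its center lies within `radius` mm
#' (inclusive) of the ROI center; a voxel within reach of several centers is
#' assigned to the nearest one (ties to the lower node id), which makes the
#' voxel sets pairwise disjoint. When subject masks are supplied, only
#' voxels present in all of them are used.
#'
#' @param centers_mm ROI centers, one row per node, in mm. Voxel `(1,1,1)`
#'   has its center at the origin and the grid is isotropic `spacing` mm.
#' @param grid_shape Length-3 voxel counts.
#' @param subject_masks Optional list of logical grid-shaped arrays; the
#'   conjunction of all of them restricts every ROI.
#' @param radius Sphere radius in mm (10 mm diameter by default).
#' @param spacing Isotropic voxel spacing in mm.
#' @return Object of class `roi_set`: `centers`, `grid_shape`, `spacing`,
#'   and `voxels`, a list of linear voxel indices per node.
#' @export
build_sphere_rois <- function(centers_mm, grid_shape, subject_masks = NULL,
                              radius = 5, spacing = 2) {
  centers_mm <- as.matrix(centers_mm)
  stopifnot(ncol(centers_mm) == 3, length(grid_shape) == 3)
  extent <- (grid_shape - 1) * spacing
  bad <- which(centers_mm[, 1] < 0 | centers_mm[, 1] > extent[1] |
               centers_mm[, 2] < 0 | centers_mm[, 2] > extent[2] |
               centers_mm[, 3] < 0 | centers_mm[, 3] > extent[3])
  if (length(bad)) {
    abort(paste0("ROI center(s) outside grid: ",
                 paste(bad, collapse = ", ")))
  }
  k <- nrow(centers_mm)
  # candidate voxels per node within the bounding box of the sphere
  assign_node <- integer(0)
  assign_vox <- integer(0)
  assign_d2 <- numeric(0)
  for (node in seq_len(k)) {
    ctr <- centers_mm[node, ]
    lo <- pmax(ceiling((ctr - radius) / spacing) + 1, 1)
    hi <- pmin(floor((ctr + radius) / spacing) + 1, grid_shape)
    if (any(lo > hi)) next
    gi <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], l = lo[3]:hi[3])
    pos <- (as.matrix(gi) - 1) * spacing
    d2 <- rowSums(sweep(pos, 2, ctr, "-")^2)
    keep <- d2 <= radius^2 + 1e-9
    if (!any(keep)) next
    lin <- (gi$l[keep] - 1) * grid_shape[1] * grid_shape[2] +
      (gi$j[keep] - 1) * grid_shape[1] + gi$i[keep]
    assign_node <- c(assign_node, rep(node, sum(keep)))
    assign_vox <- c(assign_vox, lin)
    assign_d2 <- c(assign_d2, d2[keep])
  }
  # nearest-center rule for voxels claimed by several nodes (tie: lower id)
  ord <- order(assign_vox, assign_d2, assign_node)
  first <- !duplicated(assign_vox[ord])
  win_vox <- assign_vox[ord][first]
  win_node <- assign_node[ord][first]
  if (!is.null(subject_masks)) {
    conj <- Reduce(`&`, lapply(subject_masks, as.logical))
    keep <- conj[win_vox]
    win_vox <- win_vox[keep]
    win_node <- win_node[keep]
  }
  voxels <- split(win_vox, factor(win_node, levels = seq_len(k)))
  empty <- which(lengths(voxels) == 0)
  if (length(empty)) {
    abort(paste0("ROI(s) empty after masking: ",
                 paste(empty, collapse = ", ")))
  }
  structure(list(centers = centers_mm, grid_shape = as.integer(grid_shape),
                 spacing = spacing, voxels = voxels),
            class = "roi_set")
}

#' Extract mean ROI time series from a 4-D volume
#'
#' @param volume4d 4-D array (x, y, z, frame) on the ROI grid.
#' @param rois A [build_sphere_rois()] result.
#' @return Node-by-frame matrix of per-frame voxel means.
#' @export
extract_timeseries <- function(volume4d, rois) {
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(volume4d)
  if (length(d) != 4 || !all(d[1:3] == rois$grid_shape)) {
    abort("volume grid does not match the ROI grid.")
  }
  n_frames <- d[4]
  flat <- matrix(volume4d, prod(d[1:3]), n_frames)
  ts <- t(vapply(rois$voxels, function(v) {
    colMeans(flat[v, , drop = FALSE])
  }, numeric(n_frames)))
  rownames(ts) <- paste0("N", seq_along(rois$voxels))
  ts
}

#' Principal component time courses of tissue voxels
#'
#' Top-k principal components of the demeaned voxel-by-frame tissue matrix,
#' returned as unit-variance time courses with a deterministic sign (the
#' largest-magnitude element of each course is positive). Degenerate
#' components (zero singular value) and a shortfall of voxels are flagged.
#'
#' @param tissue_voxel_series Voxel-by-frame matrix.
#' @param k Number of components (the study used 5 per tissue class).
#' @return Frame-by-k matrix with attributes `flagged` (indices of
#'   degenerate components) and `shortfall` (TRUE when fewer than `k` voxels
#'   were available).
#' @export
tissue_pcs <- function(tissue_voxel_series, k = 5) {
  x <- as.matrix(tissue_voxel_series)
  if (k == 0) {
    out <- matrix(numeric(0), ncol(x), 0)
    attr(out, "flagged") <- integer(0)
    attr(out, "shortfall") <- FALSE
    return(out)
  }
  shortfall <- nrow(x) < k
  k_eff <- min(k, nrow(x), ncol(x))
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = 0, nv = k_eff)
  comps <- sv$v[, seq_len(k_eff), drop = FALSE]
  flagged <- which(sv$d[seq_len(k_eff)] < max(sv$d[1], 1e-12) * 1e-10)
  for (c_i in seq_len(k_eff)) {
    s <- apply(comps, 2, sd)[c_i]
    if (s > 0 && !(c_i %in% flagged)) comps[, c_i] <- comps[, c_i] / s
    j <- which.max(abs(comps[, c_i]))
    if (comps[j, c_i] < 0) comps[, c_i] <- -comps[, c_i]
  }
  attr(comps, "flagged") <- flagged
  attr(comps, "shortfall") <- shortfall
  comps
}

#' Cleaning specification: passband, repetition time, frame censoring
#'
#' @param tr Repetition time in seconds (study value 2.44 s).
#' @param passband Retained frequency band in Hz, default 0.01-0.10.
#' @param censor Logical per frame, `TRUE` = frame excluded from regression
#'   and from the output; `NULL` keeps every frame.
#' @param n_tissue_pcs Number of tissue principal components the pipeline
#'   extracts per tissue class (carried as metadata).
#' @return Object of class `clean_spec`.
#' @export
clean_spec <- function(tr = 2.44, passband = c(0.01, 0.10), censor = NULL,
                       n_tissue_pcs = 5) {
  nyq <- 1 / (2 * tr)
  if (!(passband[1] > 0 && passband[1] < passband[2] && passband[2] <= nyq)) {
    abort("need 0 < low < high <= Nyquist = 1/(2 tr).")
  }
  structure(list(tr = tr, passband = passband, censor = censor,
                 n_tissue_pcs = n_tissue_pcs),
            class = "clean_spec")
}

# Fourier basis over the full-run frequency grid, evaluated at the retained
# frame times. Returns in-band and out-of-band regressor blocks.
fourier_blocks <- function(n_total, tr, passband, t_retained) {
  freqs <- seq_len(floor(n_total / 2)) / (n_total * tr)
  in_band <- freqs >= passband[1] & freqs <= passband[2]
  if (!any(in_band)) abort("passband empty after discretization.")
  build <- function(fs) {
    if (!length(fs)) return(matrix(numeric(0), length(t_retained), 0))
    cols <- lapply(fs, function(f) {
      cbind(cos(2 * pi * f * t_retained), sin(2 * pi * f * t_retained))
    })
    b <- do.call(cbind, cols)
    # drop numerically null columns (e.g. the Nyquist sine on a full grid)
    b[, sqrt(colSums(b^2)) > 1e-8 * sqrt(length(t_retained)), drop = FALSE]
  }
  list(in_band = build(freqs[in_band]), out_band = build(freqs[!in_band]))
}

#' Simultaneous nuisance regression and band-pass filtering
#'
#' Cleans node time series with nuisance removal and frequency filtering in
#' one model: censored frames are dropped from estimation and output, the
#' nuisance regressors are band-limited to the passband (projection on the
#' in-band Fourier basis over the retained frames), and out-of-band
#' variation is removed through the out-of-band Fourier basis included as
#' regressors in the same joint model. The residuals are therefore exactly
#' orthogonal to the filtered nuisance set. An FFT path (`method = "fft"`)
#' is available for uncensored data and agrees with the regression path to
#' numerical precision on the full grid.
#'
#' @param ts Node-by-frame matrix.
#' @param nuisance Frame-by-q nuisance matrix (full-length rows; censored
#'   frames are dropped internally), or `NULL`.
#' @param spec A [clean_spec()].
#' @param method `"regression"` (default; handles censoring) or `"fft"`.
#' @return Node-by-retained-frame matrix of cleaned series, with attribute
#'   `n_retained`.
#' @export
simultaneous_clean <- function(ts, nuisance = NULL, spec = clean_spec(),
                               method = c("regression", "fft")) {
  method <- match.arg(method)
  ts <- as.matrix(ts)
  n_total <- ncol(ts)
  censor <- spec$censor %||% rep(FALSE, n_total)
  if (length(censor) != n_total) {
    abort("censor mask length must equal the number of frames.")
  }
  keep <- !censor
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_total)
  }
  if (method == "fft") {
    if (any(censor)) abort("the FFT path requires uncensored data.")
    pass <- fft_bandpass_mask(n_total, spec$tr, spec$passband)
    filt <- function(x) {
      Re(stats::mvfft(stats::mvfft(x) * pass, inverse = TRUE) / n_total)
    }
    y <- filt(t(ts))
    if (!is.null(nuisance)) {
      nf <- filt(nuisance)
      y <- residualize(y, cbind(1, nf))
    }
    out <- t(y)
  } else {
    t_ret <- (which(keep) - 1) * spec$tr
    blocks <- fourier_blocks(n_total, spec$tr, spec$passband, t_ret)
    y <- t(ts[, keep, drop = FALSE])
    design <- cbind(1, blocks$out_band)
    if (!is.null(nuisance)) {
      nuis_ret <- nuisance[keep, , drop = FALSE]
      nuis_filt <- qr.fitted(qr(blocks$in_band), nuis_ret)
      design <- cbind(design, nuis_filt)
    }
    if (ncol(design) >= nrow(y)) {
      abort("too many censored frames for the requested passband (model has no residual degrees of freedom).")
    }
    out <- t(residualize(y, design))
  }
  dimnames(out) <- list(rownames(ts), NULL)
  attr(out, "n_retained") <- sum(keep)
  out
}

# 0/1 mask over DFT bins retaining low <= f <= high (mirrored bins included).
fft_bandpass_mask <- function(n, tr, passband) {
  f <- (seq_len(n) - 1) / (n * tr)
  f <- pmin(f, 1 / tr - f) # fold to [0, Nyquist]
  as.numeric(f >= passband[1] - 1e-12 & f <= passband[2] + 1e-12)
}

#' Fisher-z connectivity matrix of cleaned time series
#'
#' Pearson-correlates every node pair and applies the Fisher z-transform
#' `atanh(r)`; the diagonal is zero.
#'
#' @param ts Node-by-frame matrix (at least 3 frames).
#' @param condition Optional condition tag (`"verum"` or `"placebo"`) stored
#'   as an attribute.
#' @param subject Optional subject id attribute.
#' @return Symmetric node-by-node matrix of z-values with attributes
#'   `condition`, `subject`, `n_frames`.
#' @export
connectivity_matrix <- function(ts, condition = NULL, subject = NULL) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) abort("need at least 3 retained frames.")
  s <- apply(ts, 1, sd)
  if (any(s == 0)) {
    abort(paste0("zero-variance node(s): ",
                 paste(which(s == 0), collapse = ", ")))
  }
  r <- cor(t(ts))
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12)) {
    abort("degenerate input: |r| = 1 between distinct nodes.")
  }
  z <- atanh(r)
  diag(z) <- 0
  attr(z, "condition") <- condition
  attr(z, "subject") <- subject
  attr(z, "n_frames") <- ncol(ts)
  z
}

#' Mean connectivity over all connections and both conditions
#'
#' The per-subject covariate of the edge-wise design matrices: the mean of
#' the upper-triangle z-values pooled over the verum and placebo matrices.
#'
#' @param z_verum,z_placebo Same-shaped symmetric z-matrices.
#' @return A single number.
#' @export
mean_connectivity <- function(z_verum, z_placebo) {
  if (!all(dim(z_verum) == dim(z_placebo))) abort("shape mismatch.")
  mean(c(ut_vec(z_verum), ut_vec(z_placebo)))
}

#' Verum-minus-placebo difference matrix
#'
#' @param z_verum,z_placebo Same-subject, same-shaped z-matrices.
#' @return Symmetric zero-diagonal difference matrix.
#' @export
difference_matrix <- function(z_verum, z_placebo) {
  if (!all(dim(z_verum) == dim(z_placebo))) abort("shape mismatch.")
  d <- z_verum - z_placebo
  diag(d) <- 0
  d
}
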