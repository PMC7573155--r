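# ROI construction, extraction, simultaneous cleaning and the Fisher-z
# connectivity matrices.

test_that("grid-aligned 10 mm sphere contains 81 voxels on a 2 mm grid", {
  rois <- build_sphere_rois(matrix(c(20, 20, 20), 1), c(21, 21, 21))
  expect_length(rois$voxels[[1]], 81)
  # geometric oracle: enumerate lattice offsets with squared norm <= 25
  offs <- expand.grid(i = -3:3, j = -3:3, k = -3:3)
  expect_equal(sum(4 * (offs$i^2 + offs$j^2 + offs$k^2) <= 25), 81)
})

test_that("overlapping spheres are split by the nearest-center rule", {
  centers <- rbind(c(14, 20, 20), c(20, 20, 20)) # 6 mm apart
  rois <- build_sphere_rois(centers, c(21, 21, 21))
  expect_length(intersect(rois$voxels[[1]], rois$voxels[[2]]), 0)
  # geometric oracle: each claimed voxel is nearer (or tied, id 1) its node
  grid <- c(21, 21, 21)
  for (node in 1:2) {
    for (v in rois$voxels[[node]]) {
      k <- (v - 1) %/% (grid[1] * grid[2])
      rem <- (v - 1) %% (grid[1] * grid[2])
      pos <- 2 * c(rem %% grid[1], rem %/% grid[1], k)
      d <- sqrt(colSums((t(centers) - pos)^2))
      expect_lte(d[node], 5 + 1e-9)
      expect_true(d[node] < d[-node] ||
                    (d[node] == d[-node] && node == 1))
    }
  }
})

test_that("subject masks restrict ROIs and empty ROIs error", {
  grid <- c(15, 15, 15)
  centers <- matrix(c(14, 14, 14), 1)
  full <- build_sphere_rois(centers, grid)
  mask <- array(FALSE, grid)
  mask[full$voxels[[1]][1]] <- TRUE
  one <- build_sphere_rois(centers, grid, subject_masks = list(mask))
  expect_length(one$voxels[[1]], 1)
  empty <- array(FALSE, grid)
  expect_error(build_sphere_rois(centers, grid, subject_masks = list(empty)),
               "empty after masking: 1")
})

test_that("time-series extraction averages voxels exactly", {
  grid <- c(12, 12, 12)
  vol <- array(3.5, c(grid, 7))
  rois <- build_sphere_rois(matrix(c(10, 10, 10), 1), grid)
  ts <- extract_timeseries(vol, rois)
  expect_equal(unname(ts), matrix(3.5, 1, 7))
  expect_error(extract_timeseries(array(0, c(5, 5, 5, 7)), rois), "grid")
})

test_that("tissue PCs recover planted components in variance order", {
  n_frames <- 80
  set.seed(3)
  s1 <- sin(2 * pi * (1:n_frames) / 20) * 3
  s2 <- cos(2 * pi * (1:n_frames) / 11)
  # rank-1 tissue: PC1 equals the shared signal up to sign, rest degenerate
  tissue1 <- outer(runif(30, 0.5, 2), s1)
  p1 <- tissue_pcs(tissue1, k = 3)
  expect_gt(abs(cor(p1[, 1], s1)), 1 - 1e-10)
  expect_equal(attr(p1, "flagged"), 2:3)
  # two orthogonal signals with distinct variances come out in order
  tissue2 <- rbind(outer(rep(1, 20), s1), outer(rep(1, 20), s2)) +
    matrix(rnorm(40 * n_frames, sd = 1e-4), 40)
  p2 <- tissue_pcs(tissue2, k = 2)
  expect_gt(abs(cor(p2[, 1], s1)), 0.99)
  expect_gt(abs(cor(p2[, 2], s2)), 0.99)
  # deterministic sign: largest-magnitude coefficient positive
  expect_gt(p2[which.max(abs(p2[, 1])), 1], 0)
  # k = 0: empty component set
  expect_equal(ncol(tissue_pcs(tissue1, k = 0)), 0)
  # fewer voxels than k: all available, flagged shortfall
  p3 <- tissue_pcs(tissue1[1:2, ], k = 5)
  expect_true(attr(p3, "shortfall"))
  expect_lte(ncol(p3), 2)
})

test_that("simultaneous cleaning removes stopband and preserves passband", {
  n <- 400; tr <- 2.5
  t0 <- (0:(n - 1)) * tr
  spec <- clean_spec(tr = tr, passband = c(0.01, 0.10))
  amp <- function(x) sqrt(mean(x^2))
  ts <- rbind(drift = sin(2 * pi * 0.005 * t0),
              slow = sin(2 * pi * 0.001 * t0),
              mid = sin(2 * pi * 0.055 * t0),
              nyquist = cos(2 * pi * 0.2 * t0))
  out <- simultaneous_clean(ts, NULL, spec)
  # stopband attenuation >= 40 dB (amplitude ratio <= 0.01)
  expect_lt(amp(out["drift", ]) / amp(ts["drift", ]), 0.01)
  expect_lt(amp(out["slow", ]) / amp(ts["slow", ]), 0.01)
  expect_lt(amp(out["nyquist", ]) / amp(ts["nyquist", ]), 0.01)
  # passband ripple <= 1% at band center
  expect_lt(abs(amp(out["mid", ]) / amp(ts["mid", ]) - 1), 0.01)
})

test_that("cleaning is an idempotent projection with residuals orthogonal to nuisance", {
  n <- 300; tr <- 2.5
  t0 <- (0:(n - 1)) * tr
  spec <- clean_spec(tr = tr)
  set.seed(8)
  y <- matrix(rnorm(4 * n), 4, n)
  nuis <- cbind(rnorm(n), sin(2 * pi * 0.04 * t0))
  c1 <- simultaneous_clean(y, nuis, spec)
  c2 <- simultaneous_clean(c1, nuis, spec)
  expect_lt(max(abs(c1 - c2)), 1e-8)
  # residuals orthogonal to the band-limited nuisance set
  blocks <- fcresponse:::fourier_blocks(n, tr, spec$passband, t0)
  nuis_filt <- qr.fitted(qr(blocks$in_band), nuis)
  expect_lt(max(abs(crossprod(nuis_filt, t(c1)))), 1e-8)
  # a nuisance regressor equal to a node's series wipes that node
  y2 <- y
  nuis2 <- cbind(y[2, ])
  c3 <- simultaneous_clean(y2, nuis2, spec)
  # node 2 retains only what the filter basis cannot represent of itself
  expect_lt(amp_ratio <- sqrt(mean(c3[2, ]^2)) / sqrt(mean(y[2, ]^2)), 0.05)
})

test_that("FFT and regression paths agree on uncensored data", {
  n <- 256; tr <- 2.0
  spec <- clean_spec(tr = tr)
  set.seed(12)
  y <- matrix(rnorm(3 * n), 3, n)
  nuis <- cbind(rnorm(n))
  a <- simultaneous_clean(y, nuis, spec)
  b <- simultaneous_clean(y, nuis, spec, method = "fft")
  expect_lt(max(abs(a - b)), 1e-6)
  spec_c <- clean_spec(tr = tr, censor = c(TRUE, rep(FALSE, n - 1)))
  expect_error(simultaneous_clean(y, nuis, spec_c, method = "fft"),
               "uncensored")
})

test_that("censored frames are dropped from estimation and output", {
  n <- 300; tr <- 2.5
  set.seed(9)
  censor <- rep(FALSE, n)
  censor[sample(n, 30)] <- TRUE
  spec <- clean_spec(tr = tr, censor = censor)
  y <- matrix(rnorm(2 * n), 2, n)
  out <- simultaneous_clean(y, NULL, spec)
  expect_equal(ncol(out), n - 30)
  expect_equal(attr(out, "n_retained"), n - 30)
})

test_that("connectivity matrices are Fisher-z with guarded degeneracies", {
  set.seed(10)
  ts <- matrix(rnorm(5 * 2000), 5, 2000)
  z <- connectivity_matrix(ts, condition = "verum")
  expect_true(isSymmetric(unclass(z)))
  expect_equal(diag(z), rep(0, 5))
  expect_equal(z[1, 2], atanh(cor(ts[1, ], ts[2, ])))
  # independent white noise: mean |z| small at 2000 frames
  expect_lt(mean(abs(z[upper.tri(z)])), 0.05)
  # closed form: r = 0.9 -> z = 1.4722 (log-form oracle)
  expect_equal(atanh(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  expect_equal(round(atanh(0.9), 4), 1.4722)
  # error paths
  expect_error(connectivity_matrix(rbind(ts[1, ], 2 * ts[1, ], ts[2, ])),
               "degenerate")
  expect_error(connectivity_matrix(rbind(ts[1, ], rep(1, 2000))),
               "zero-variance node")
  # invariance to per-node affine rescaling
  ts2 <- ts * c(2, 0.5, 3, 1, 10) + c(1, -2, 0, 5, 3)
  expect_equal(connectivity_matrix(ts2), z, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("mean connectivity pools both triangles and differences are elementwise", {
  set.seed(13)
  a <- sym_from <- function(v, n) fcresponse:::sym_from_vec(v, n)
  zv <- sym_from(runif(15, 0.3, 0.5), 6)
  zp <- sym_from(runif(15, 0.1, 0.3), 6)
  # loop oracle
  tot <- 0; cnt <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    tot <- tot + zv[i, j] + zp[i, j]; cnt <- cnt + 2
  }
  expect_equal(mean_connectivity(zv, zp), tot / cnt)
  zv2 <- sym_from(rep(0.4, 15), 6); zp2 <- sym_from(rep(0.2, 15), 6)
  expect_equal(mean_connectivity(zv2, zp2), 0.3)
  d <- difference_matrix(zv, zp)
  expect_equal(d, zv - zp)
  expect_error(difference_matrix(zv, zp[1:5, 1:5]), "shape")
})

test_that("fixture nuisance is removed and planted inter-ROI correlation recovered", {
  n_frames <- 240; tr <- 2.5
  t0 <- (0:(n_frames - 1)) * tr
  # planted in-band correlated ROI signals (rho = 0.5)
  set.seed(18)
  base <- matrix(rnorm(3 * n_frames), 3)
  spec <- clean_spec(tr = tr)
  rho <- 0.5
  s1 <- base[1, ]
  s2 <- rho * base[1, ] + sqrt(1 - rho^2) * base[2, ]
  nuis_sig <- rbind(sin(2 * pi * 0.05 * t0)) # in-band nuisance
  fx <- gen_nifti_fixture(n_frames, c(16, 16, 16), tr = tr,
                          roi_centers = rbind(c(8, 8, 8), c(22, 22, 22)),
                          roi_signals = rbind(s1, s2),
                          nuisance_signals = nuis_sig,
                          noise_sd = 0.02, seed = 19)
  ts <- extract_timeseries(fx$volume, fx$rois)
  wm <- matrix(fx$volume, prod(dim(fx$volume)[1:3]),
               n_frames)[which(fx$tissue_masks$wm), ]
  pcs <- tissue_pcs(wm, k = 2)
  cleaned <- simultaneous_clean(ts, pcs, spec)
  r <- cor(cleaned[1, ], cleaned[2, ])
  expect_lt(abs(r - rho), 0.12)
  # planted pure-sinusoid nuisance is projected out of tissue voxels:
  # the remaining amplitude at the planted frequency is < 1% of the input's
  wm_clean <- simultaneous_clean(wm[1:3, , drop = FALSE], pcs, spec)
  sin_amp <- function(x) {
    b <- cbind(sin(2 * pi * 0.05 * t0), cos(2 * pi * 0.05 * t0))
    sqrt(sum(qr.fitted(qr(b), x)^2))
  }
  expect_lt(sin_amp(wm_clean[1, ]) / sin_amp(wm[1, ]), 0.01)
})
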