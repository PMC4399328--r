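test_that("the canonical HRF has the double-gamma shape", {
  expect_equal(canonical_hrf(0), 0)
  tt <- seq(0, 30, by = 0.01)
  h <- canonical_hrf(tt)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_true(abs(tt[which.max(h)] - 5) < 1.5)   # peak near 5-6 s
  # independent oracle: the same double-gamma via stats::dgamma
  oracle <- function(t) {
    raw <- function(t) dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6
    raw(t) / max(raw(seq(0, 32, by = 0.01)))
  }
  expect_equal(canonical_hrf(c(3, 5, 10, 25)), oracle(c(3, 5, 10, 25)),
               tolerance = 1e-6)
  u <- canonical_hrf(25)
  expect_lt(u, 0)            # undershoot
  expect_lt(abs(u), 0.2)
  expect_equal(canonical_hrf(-1), 0)
})

test_that("design matrices are 76 x 18 and full rank for generated designs", {
  for (seed in c(1, 23, 99)) {
    d <- make_run_design(seed)
    X <- build_design_matrix(d)
    expect_equal(dim(X), c(76, 18))
    expect_equal(qr(X)$rank, 18)
    expect_equal(colnames(X)[17:18], c("trend", "intercept"))
    # every location column is active (4 trials each)
    expect_true(all(colSums(abs(X[, 1:16])) > 0))
  }
  # degenerate HRF: all location columns vanish -> rank error names them
  d <- make_run_design(1)
  expect_error(build_design_matrix(d, hrf = function(t) 0 * t),
               "rank deficient.*loc_00")
})

test_that("OLS recovers known coefficients exactly and orthogonalizes residuals", {
  d <- make_run_design(4)
  X <- build_design_matrix(d)
  grid <- c(5L, 4L, 3L)
  V <- prod(grid)
  B <- with_seed(8, matrix(rnorm(18 * V), 18, V))
  Y <- X %*% B
  vol <- structure(list(data = array(as.vector(t(Y)), c(grid, 76)),
                        acquisition_times_s = d$acquisition_onset_s,
                        voxel_size_mm = c(3, 3, 3), tr_s = 5.5,
                        smoothed = FALSE),
                   class = "volume_series")
  ri <- fit_run_glm(vol, X, run_id = 1)
  bm <- matrix(ri$betas, nrow = V)
  expect_equal(bm, t(B[1:16, ]), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(as.vector(ri$residual_variance), rep(0, V),
               tolerance = 1e-12)
  # residual orthogonality at machine precision on noisy data
  Yn <- Y + with_seed(9, matrix(rnorm(76 * V), 76, V))
  res <- qr.resid(qr(X), Yn)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)
  expect_error(fit_run_glm(vol, X[1:50, ]), "design rows")
})

test_that("eight fitted runs yield 128 beta maps", {
  responses <- tiny_subject()$responses
  n_maps <- sum(vapply(responses, function(r) dim(r$betas)[4], numeric(1)))
  expect_equal(n_maps, 128)
})

test_that("pure-drift data recover the slope and give null location betas", {
  d <- make_run_design(12)
  X <- build_design_matrix(d)
  grid <- c(4L, 3L, 2L)
  V <- prod(grid)
  slope <- 0.7
  Y <- matrix(rep(100 + slope * X[, "trend"], V), 76, V)
  vol <- structure(list(data = array(as.vector(t(Y)), c(grid, 76)),
                        acquisition_times_s = d$acquisition_onset_s,
                        voxel_size_mm = c(3, 3, 3), tr_s = 5.5,
                        smoothed = FALSE),
                   class = "volume_series")
  ri <- fit_run_glm(vol, X)
  expect_equal(max(abs(ri$betas)), 0, tolerance = 1e-9)
  expect_equal(as.vector(ri$extra$trend), rep(slope, V), tolerance = 1e-9)
  expect_equal(as.vector(ri$extra$intercept), rep(100, V), tolerance = 1e-9)
})

test_that("beta estimates are unbiased over repeated noisy simulations", {
  # fixed design, 100 AR(1)-noise replicates; mean bias within 3 SEM
  spec <- tiny_spec(amplitude = 1, noise_sd = 1, seed = 6,
                    grid = c(8L, 8L, 4L), n_informative = 5L,
                    roi_mask = array(TRUE, c(8, 8, 4)))
  pat <- spec$condition_patterns$left_vs_right
  vox <- pat$voxels[1]
  truth <- spec$baseline_amplitude + pat$effects
  est <- matrix(NA_real_, 100, 16)
  for (i in 1:100) {
    ds <- simulate_subject(spec, seed = 1000 + i, n_runs = 1)
    ri <- fit_run_glm(ds$runs[[1]]$volume,
                      build_design_matrix(ds$runs[[1]]$design))
    est[i, ] <- matrix(ri$betas, nrow = prod(spec$grid_shape))[vox, ]
  }
  bias <- colMeans(est) - truth
  sem <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 3 * sem + 1e-8))
})

test_that("gaussian smoothing has the stated width and invariances", {
  g <- array(0, c(21, 21, 21))
  g[11, 11, 11] <- 1
  sm <- smooth_volume(g, fwhm_mm = 5, voxel_size_mm = c(1, 1, 1))
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  measured_fwhm <- diff(above) + 1 # voxel-quantized width at half maximum
  expect_lt(abs(measured_fwhm - 5), 1.5)
  # mass preserved up to the edge renormalization of the kernel tails
  expect_equal(sum(sm), 1, tolerance = 5e-3)
  const <- array(3.7, c(9, 9, 9))
  expect_equal(smooth_volume(const, 5, c(1, 1, 1)), const, tolerance = 1e-9)
  expect_identical(smooth_volume(const, 0, c(1, 1, 1)), const)
})

test_that("the multivariate path refuses smoothed data", {
  ds <- tiny_subject()$ds
  run <- ds$runs[[1]]
  vol <- run$volume
  vol$smoothed <- TRUE
  X <- build_design_matrix(run$design)
  expect_error(fit_run_glm(vol, X), "smoothed")
  expect_silent(invisible(fit_run_glm(vol, X, allow_smoothed = TRUE)))
})

# step-up rule oracle for Benjamini-Hochberg, by direct enumeration
bh_oracle <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  k <- max(c(0, which(p[o] <= alpha * seq_len(n) / n)))
  rejected <- rep(FALSE, n)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

test_that("the contrast's FDR mask equals the step-up oracle", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  expect_equal(bh_oracle(p, 0.05), p.adjust(p, "BH") <= 0.05)
  # and on a full contrast computed from planted data
  spec <- tiny_spec(amplitude = 0, noise_sd = 1, seed = 14,
                    baseline_amplitude = 3)
  ds <- simulate_subject(spec, seed = 31, n_runs = 3)
  vols <- lapply(ds$runs, `[[`, "volume")
  designs <- lapply(ds$runs, `[[`, "design")
  cr <- univariate_contrast(vols, designs, alpha = 0.05, fwhm_mm = 5)
  keep <- !is.na(cr$p_map)
  expect_equal(as.vector(cr$significance_mask)[keep],
               bh_oracle(as.vector(cr$p_map)[keep], 0.05))
  expect_true(all(cr$p_map[keep] >= 0 & cr$p_map[keep] <= 1))
  # planted baseline response is recovered inside the ROI
  sens <- mean(cr$significance_mask[spec$roi_mask])
  expect_gt(sens, 0.9)
  expect_error(univariate_contrast(vols[1], designs[1]), ">= 2 runs")
})

test_that("null data give calibrated raw p-values and empty FDR masks", {
  # scaled down: 25 small null datasets of 2 runs each
  n_empty <- 0
  frac <- numeric(25)
  for (i in 1:25) {
    grid <- c(6L, 6L, 4L)
    spec <- make_pattern_spec(list(grid_shape = grid,
                                   roi_mask = array(TRUE, grid),
                                   n_informative = 2L,
                                   amplitudes = list(left_vs_right = 0,
                                                     up_vs_down = 0,
                                                     front_vs_back = 0),
                                   baseline_amplitude = 0, noise_sd = 1,
                                   ar1_coeff = 0, drift_slope = 0),
                              seed = i)
    ds <- simulate_subject(spec, seed = 500 + i, n_runs = 2)
    cr <- univariate_contrast(lapply(ds$runs, `[[`, "volume"),
                              lapply(ds$runs, `[[`, "design"),
                              fwhm_mm = 0)
    frac[i] <- mean(cr$p_map < 0.05, na.rm = TRUE)
    n_empty <- n_empty + (sum(cr$significance_mask) == 0)
  }
  expect_lt(abs(mean(frac) - 0.05), 0.02)
  expect_gte(n_empty, 23)
})
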