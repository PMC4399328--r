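#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma shape: a positive response gamma (delay 6 s,
#' dispersion 1 s) minus an undershoot gamma (delay 16 s, dispersion 1 s)
#' scaled by `undershoot_ratio` (default 1/6). The curve is normalized so its
#' peak over \[0, 32\] s equals 1; the peak sits near 5 s and the undershoot
#' near 15 s.
#'
#' @param t_s Time in seconds (vectorized); values < 0 return 0.
#' @param peak_delay_s,under_delay_s Gamma shape parameters (seconds).
#' @param peak_disp_s,under_disp_s Gamma rate parameters (seconds).
#' @param undershoot_ratio Relative amplitude of the undershoot gamma.
#' @return HRF amplitude, unitless, peak-normalized.
#' @export
canonical_hrf <- function(t_s, peak_delay_s = 6, under_delay_s = 16,
                          peak_disp_s = 1, under_disp_s = 1,
                          undershoot_ratio = 1 / 6) {
  shape <- function(t) {
    a1 <- peak_delay_s / peak_disp_s
    a2 <- under_delay_s / under_disp_s
    pos <- t >= 0
    h <- numeric(length(t))
    tb1 <- t[pos] / peak_disp_s
    tb2 <- t[pos] / under_disp_s
    h[pos] <- exp((a1 - 1) * log(pmax(tb1, .Machine$double.xmin)) - tb1 -
                    lgamma(a1)) / peak_disp_s -
      undershoot_ratio *
        exp((a2 - 1) * log(pmax(tb2, .Machine$double.xmin)) - tb2 -
              lgamma(a2)) / under_disp_s
    h[t == 0] <- 0
    h
  }
  peak <- max(shape(seq(0, 32, by = 0.01)))
  shape(t_s) / peak
}

# Convolve per-location stimulus boxcars with the HRF on a fine grid and
# sample at the given times. Returns a length(sample_times_s) vector.
convolve_regressor <- function(onsets_s, durations_s, sample_times_s,
                               hrf = canonical_hrf, dt = 0.1,
                               t_max_s = NULL) {
  t_max_s <- t_max_s %||% (max(sample_times_s) + 33)
  grid <- seq(0, t_max_s, by = dt)
  neural <- numeric(length(grid))
  for (k in seq_along(onsets_s)) {
    on <- grid >= onsets_s[k] & grid < onsets_s[k] + durations_s[k]
    neural[on] <- neural[on] + 1
  }
  kern <- hrf(seq(0, 32, by = dt))
  full <- convolve(neural, rev(kern), type = "open")[seq_along(grid)] * dt
  idx <- pmin(pmax(round(sample_times_s / dt) + 1, 1), length(grid))
  full[idx]
}

#' Build the per-run GLM design matrix (16 location regressors)
#'
#' One regressor per sound location: the four 0.55 s stimulus boxcars of that
#' location convolved with the HRF on a fine time grid and sampled at the
#' volume acquisition times; plus a mean-centred linear trend (one step per
#' trial, modelling slow scanner drift) and an intercept. Silent trials add
#' no regressor. 76 rows by 18 columns for the canonical design.
#'
#' @param design A `run_design` from [make_run_design()].
#' @param hrf HRF function of time in seconds.
#' @param acquisition_times_s Sampling times (defaults to the design's
#'   acquisition onsets plus `acquisition_lag_s`).
#' @param acquisition_lag_s Lag of the effective sample within the 2 s
#'   acquisition window (default 0).
#' @param dt Fine-grid resolution in seconds for the convolution.
#' @param n_locations Number of location regressors (default 16).
#' @return A numeric matrix with colnames `loc_00`..`loc_15`, `trend`,
#'   `intercept`; errors if rank-deficient, naming the collinear columns.
#' @export
build_design_matrix <- function(design, hrf = canonical_hrf,
                                acquisition_times_s = NULL,
                                acquisition_lag_s = 0, dt = 0.1,
                                n_locations = 16L) {
  stopifnot(inherits(design, "run_design"))
  times <- acquisition_times_s %||%
    (design$acquisition_onset_s + acquisition_lag_s)
  n <- nrow(design)
  X <- matrix(0, n, n_locations + 2L)
  colnames(X) <- c(sprintf("loc_%02d", seq_len(n_locations) - 1L),
                   "trend", "intercept")
  for (loc in seq_len(n_locations) - 1L) {
    rows <- which(design$trial_type == "stimulus" & design$location_id == loc)
    if (length(rows) == 0) next
    X[, loc + 1L] <- convolve_regressor(design$stim_onset_s[rows],
                                        design$stim_duration_s[rows],
                                        times, hrf = hrf, dt = dt)
  }
  tr_col <- seq_len(n) - (n + 1) / 2
  X[, "trend"] <- tr_col / max(abs(tr_col))
  X[, "intercept"] <- 1
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_sl("design matrix is rank deficient; collinear column(s): %s",
            paste(dropped, collapse = ", "))
  }
  X
}

# Two-condition design for the univariate contrast: one pooled stimulus
# regressor (all 64 stimulus boxcars) + trend + intercept.
build_stimulus_design <- function(design, hrf = canonical_hrf,
                                  acquisition_lag_s = 0, dt = 0.1) {
  stopifnot(inherits(design, "run_design"))
  times <- design$acquisition_onset_s + acquisition_lag_s
  rows <- which(design$trial_type == "stimulus")
  n <- nrow(design)
  stim <- convolve_regressor(design$stim_onset_s[rows],
                             design$stim_duration_s[rows], times,
                             hrf = hrf, dt = dt)
  tr_col <- seq_len(n) - (n + 1) / 2
  X <- cbind(stimulus = stim, trend = tr_col / max(abs(tr_col)),
             intercept = 1)
  X
}

#' Fit the per-run, per-voxel GLM and extract the 16 location betas
#'
#' Ordinary least squares at every voxel; the 16 location coefficients are
#' the per-location responses ("betas") consumed by the multivariate
#' analysis. No spatial smoothing is applied here (the multivariate path must
#' see unsmoothed data); the input `volume_series` must carry
#' `smoothed = FALSE` unless `allow_smoothed = TRUE`.
#'
#' @param vol A `volume_series` (see [simulate_subject()]).
#' @param dm Design matrix from [build_design_matrix()]; rows must match the
#'   number of volumes.
#' @param run_id Identifier stored in the result.
#' @param allow_smoothed Permit smoothed input (used by the univariate path).
#' @return A `response_image`: list with `betas` (4D array, 16 volumes in
#'   location_id order), `residual_variance` (3D), `extra` coefficients
#'   (trend, intercept), `df`, `run_id`.
#' @export
fit_run_glm <- function(vol, dm, run_id = NA_integer_,
                        allow_smoothed = FALSE) {
  stopifnot(inherits(vol, "volume_series"))
  if (!allow_smoothed && isTRUE(vol$smoothed)) {
    stop_sl("fit_run_glm: refusing smoothed data on the multivariate path")
  }
  dims <- dim(vol$data)
  nt <- dims[4]
  if (nt != nrow(dm)) {
    stop_sl("fit_run_glm: %d volumes but %d design rows", nt, nrow(dm))
  }
  grid <- dims[1:3]
  V <- prod(grid)
  Y <- t(matrix(vol$data, nrow = V))          # nt x V
  qrX <- qr(dm)
  coef <- qr.coef(qrX, Y)                     # p x V
  res <- qr.resid(qrX, Y)
  df <- nt - qrX$rank
  rv <- colSums(res^2) / df
  loc_cols <- grep("^loc_", colnames(dm))
  betas <- array(as.vector(t(coef[loc_cols, , drop = FALSE])),
                 c(grid, length(loc_cols)))
  structure(list(betas = betas,
                 residual_variance = array(rv, grid),
                 extra = list(trend = array(coef["trend", ], grid),
                              intercept = array(coef["intercept", ], grid)),
                 df = df, run_id = run_id,
                 location_ids = seq_along(loc_cols) - 1L),
            class = "response_image")
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Smooths along each axis with a Gaussian kernel whose full width at half
#' maximum is `fwhm_mm` (per axis, SPM-style "5 x 5 x 5 mm" convention).
#' Edges are renormalized by the in-bounds kernel mass, so a constant field
#' is exactly invariant; `fwhm_mm = 0` is the identity.
#'
#' @param grid_3d Numeric 3D array.
#' @param fwhm_mm Kernel FWHM in millimetres (scalar, applied per axis).
#' @param voxel_size_mm Length-3 voxel size in millimetres.
#' @return Smoothed array of the same dimension.
#' @export
smooth_volume <- function(grid_3d, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim(grid_3d)) == 3, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(grid_3d)
  out <- grid_3d
  ones <- array(1, dim(grid_3d))
  for (axis in 1:3) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm[axis]
    radius <- max(1L, ceiling(3 * sigma_vox))
    k <- exp(-0.5 * ((-radius:radius) / sigma_vox)^2)
    k <- k / sum(k)
    out <- conv_axis(out, k, axis)
    ones <- conv_axis(ones, k, axis)
  }
  out / ones
}

# Zero-padded 1D convolution of a 3D array along one axis.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  radius <- (length(k) - 1L) / 2L
  padded <- rbind(matrix(0, radius, ncol(m)), m, matrix(0, radius, ncol(m)))
  sm <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    sm <- sm + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
  }
  back <- array(sm, d[perm])
  aperm(back, order(perm))
}

#' Univariate stimulus-vs-silent contrast with FDR control
#'
#' Smooths each run's volumes (5 mm FWHM by default), fits the pooled
#' stimulus regressor per run, combines runs as a fixed-effects sum
#' (t = sum of betas / sqrt(sum of squared standard errors)), and thresholds
#' two-sided p-values with the Benjamini-Hochberg step-up procedure at
#' `alpha`.
#'
#' @param vols List of `volume_series`, one per run (>= 2 runs).
#' @param designs List of `run_design`s matching `vols`.
#' @param alpha FDR level (default 0.05).
#' @param fwhm_mm Smoothing kernel FWHM (default 5 mm); 0 disables.
#' @param mask Optional logical 3D array restricting the analysis.
#' @param hrf HRF function.
#' @return A `contrast_result`: `t_map`, `p_map`, `significance_mask`,
#'   `alpha`, `method`, `df`.
#' @export
univariate_contrast <- function(vols, designs, alpha = 0.05, fwhm_mm = 5,
                                mask = NULL, hrf = canonical_hrf) {
  if (length(vols) < 2) stop_sl("univariate_contrast: need >= 2 runs")
  stopifnot(length(vols) == length(designs))
  grid <- dim(vols[[1]]$data)[1:3]
  V <- prod(grid)
  keep <- if (is.null(mask)) rep(TRUE, V) else as.vector(mask)
  beta_sum <- numeric(V)
  var_sum <- numeric(V)
  df_tot <- 0
  for (r in seq_along(vols)) {
    vol <- vols[[r]]
    vdat <- vol$data
    if (fwhm_mm > 0) {
      for (t in seq_len(dim(vdat)[4])) {
        vdat[, , , t] <- smooth_volume(vdat[, , , t], fwhm_mm,
                                       vol$voxel_size_mm)
      }
    }
    X <- build_stimulus_design(designs[[r]], hrf = hrf)
    nt <- dim(vdat)[4]
    Y <- t(matrix(vdat, nrow = V))
    qrX <- qr(X)
    coef <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    df <- nt - qrX$rank
    xtxi <- chol2inv(qr.R(qrX))[1, 1]
    beta_sum <- beta_sum + coef["stimulus", ]
    var_sum <- var_sum + colSums(res^2) / df * xtxi
    df_tot <- df_tot + df
  }
  tval <- beta_sum / sqrt(var_sum)
  pval <- 2 * pt(-abs(tval), df = df_tot)
  pval[!keep] <- NA
  padj <- rep(NA_real_, V)
  padj[keep] <- p.adjust(pval[keep], method = "BH")
  # step-up rule: reject when the adjusted p does not exceed alpha
  sig <- !is.na(padj) & padj <= alpha
  structure(list(t_map = array(tval, grid), p_map = array(pval, grid),
                 significance_mask = array(sig, grid), alpha = alpha,
                 method = "Benjamini-Hochberg", df = df_tot),
            class = "contrast_result")
}
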