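#' Generate one run's experimental design
#'
#' A run is 76 trials at TR = 5.5 s: 64 stimulus trials (4 per each of 16
#' locations) and 12 silent trials in uniformly random order. Each trial
#' starts with a 2 s image acquisition; on stimulus trials a 550 ms stimulus
#' starts at a uniformly jittered point within the following 2.5 s. The run
#' lasts 76 * 5.5 = 418 s.
#'
#' @param seed Integer seed; the same seed reproduces the same design.
#' @param tr_s Trial/repetition time in seconds.
#' @param n_locations Number of sound locations.
#' @param trials_per_location Stimulus trials per location.
#' @param n_silent Number of silent (null) trials.
#' @param acq_dur_s Acquisition window at the start of each trial (seconds).
#' @param jitter_s Width of the uniform stimulus-onset jitter window.
#' @param stim_duration_s Stimulus duration in seconds.
#' @return A data frame of class `run_design` with one row per trial and
#'   columns `index`, `trial_type`, `location_id`, `trial_onset_s`,
#'   `stim_onset_s`, `stim_duration_s`, `acquisition_onset_s`; attributes
#'   `tr_s` and `run_duration_s`.
#' @export
make_run_design <- function(seed, tr_s = 5.5, n_locations = 16L,
                            trials_per_location = 4L, n_silent = 12L,
                            acq_dur_s = 2, jitter_s = 2.5,
                            stim_duration_s = 0.55) {
  n_stim <- n_locations * trials_per_location
  n <- n_stim + n_silent
  with_seed(seed, {
    locs <- c(rep(seq_len(n_locations) - 1L, each = trials_per_location),
              rep(NA_integer_, n_silent))
    ord <- sample.int(n)
    locs <- locs[ord]
    jitter <- runif(n, 0, jitter_s)
    idx <- seq_len(n) - 1L
    trial_onset <- idx * tr_s
    is_stim <- !is.na(locs)
    design <- data.frame(
      index = idx,
      trial_type = ifelse(is_stim, "stimulus", "silent"),
      location_id = locs,
      trial_onset_s = trial_onset,
      stim_onset_s = ifelse(is_stim, trial_onset + acq_dur_s + jitter,
                            NA_real_),
      stim_duration_s = ifelse(is_stim, stim_duration_s, NA_real_),
      acquisition_onset_s = trial_onset,
      stringsAsFactors = FALSE
    )
    attr(design, "tr_s") <- tr_s
    attr(design, "run_duration_s") <- n * tr_s
    class(design) <- c("run_design", "data.frame")
    design
  })
}

# Ellipsoidal bilateral "temporal lobe" ROI on a small grid: two ellipsoids,
# one per hemisphere, centred laterally and slightly below the grid midline.
default_roi_mask <- function(grid_shape = c(24L, 24L, 12L),
                             semi_axes = c(4, 6, 3)) {
  g <- grid_shape
  centres <- rbind(c(g[1] * 0.28, g[2] / 2 + 0.5, g[3] * 0.45),
                   c(g[1] * 0.72 + 1, g[2] / 2 + 0.5, g[3] * 0.45))
  coords <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                                  z = seq_len(g[3])))
  inside <- rep(FALSE, nrow(coords))
  for (c_i in 1:2) {
    d <- sweep(coords, 2, centres[c_i, ])
    inside <- inside | (d[, 1] / semi_axes[1])^2 +
      (d[, 2] / semi_axes[2])^2 + (d[, 3] / semi_axes[3])^2 <= 1
  }
  array(inside, g)
}

#' Ground-truth pattern specification for synthetic subjects
#'
#' Describes the world a synthetic subject is drawn from: the voxel grid, a
#' temporal-lobe-like ROI, a common auditory baseline response in all ROI
#' voxels, and per-condition sets of "informative" voxels whose response is
#' shifted by +a for one class of locations and -a for the other. Informative
#' sets are drawn disjointly inside the ROI (configurable). Noise is AR(1)
#' Gaussian plus a linear drift.
#'
#' Config entries (all optional, defaults in parentheses): `grid_shape`
#' (24 x 24 x 12), `voxel_size_mm` (3 mm isotropic), `roi_mask` (bilateral
#' ellipsoids), `baseline_amplitude` (2), `amplitudes` (named list per
#' condition, default 1 each, signal units), `n_informative` (30 per
#' condition), `noise_sd` (1), `ar1_coeff` (0.3), `drift_slope` (0.02 per
#' trial), `offset` (100), `allow_overlap` (FALSE).
#'
#' @param config Named list overriding the defaults above.
#' @param seed Integer seed for the informative-voxel draw.
#' @return A list of class `pattern_spec`; `condition_patterns[[cond]]` holds
#'   `voxels` (linear voxel indices) and `effects` (length-16 per-location
#'   effect vector in signal units).
#' @export
make_pattern_spec <- function(config = list(), seed = 1L) {
  defaults <- list(grid_shape = c(24L, 24L, 12L), voxel_size_mm = c(3, 3, 3),
                   roi_mask = NULL, baseline_amplitude = 2,
                   amplitudes = list(left_vs_right = 1, up_vs_down = 1,
                                     front_vs_back = 1),
                   n_informative = 30L, noise_sd = 1, ar1_coeff = 0.3,
                   drift_slope = 0.02, offset = 100, allow_overlap = FALSE)
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$roi_mask)) cfg$roi_mask <- default_roi_mask(cfg$grid_shape)
  stopifnot(all(dim(cfg$roi_mask) == cfg$grid_shape),
            cfg$ar1_coeff >= 0, cfg$ar1_coeff < 1, cfg$noise_sd >= 0)
  roi_idx <- which(cfg$roi_mask)
  conds <- sl_conditions()
  n_need <- if (cfg$allow_overlap) cfg$n_informative else
    cfg$n_informative * length(conds)
  if (n_need > length(roi_idx)) {
    stop_sl("make_pattern_spec: %d informative voxels requested but ROI has %d",
            n_need, length(roi_idx))
  }
  arr <- build_speaker_array()
  patterns <- with_seed(substream(seed, "patterns"), {
    pool <- roi_idx
    out <- list()
    for (cond in conds) {
      vox <- sort(sample(pool, cfg$n_informative))
      if (!cfg$allow_overlap) pool <- setdiff(pool, vox)
      lab <- condition_labels(arr, cond)
      a <- cfg$amplitudes[[cond]] %||% 0
      eff <- numeric(16)
      eff[lab$class_a + 1L] <- a
      eff[lab$class_b + 1L] <- -a
      out[[cond]] <- list(voxels = as.integer(vox), effects = eff)
    }
    out
  })
  structure(list(grid_shape = as.integer(cfg$grid_shape),
                 voxel_size_mm = cfg$voxel_size_mm,
                 roi_mask = cfg$roi_mask,
                 baseline_amplitude = cfg$baseline_amplitude,
                 condition_patterns = patterns,
                 noise_sd = cfg$noise_sd, ar1_coeff = cfg$ar1_coeff,
                 drift_slope = cfg$drift_slope, offset = cfg$offset,
                 seed = as.integer(seed)),
            class = "pattern_spec")
}

#' Simulate one subject's eight sparse-sampled runs
#'
#' For each run a fresh design is drawn, each voxel's BOLD prediction is
#' built from the HRF-convolved stimulus boxcars (common baseline response in
#' ROI voxels plus the planted per-condition location effects at informative
#' voxels), a linear drift and stationary AR(1) Gaussian noise are added, and
#' the continuous signal is sampled once per trial at the acquisition onset
#' plus `acquisition_lag_s`. Because the sampled regressors are exactly the
#' ones [build_design_matrix()] constructs, a noiseless simulation is an
#' exact GLM identity.
#'
#' @param spec A `pattern_spec`.
#' @param seed Master seed; designs and noise use named substreams.
#' @param n_runs Number of runs (default 8).
#' @param subject_id Identifier string.
#' @param acquisition_lag_s Sampling lag within the acquisition window.
#' @return A list of class `subject_dataset` with `subject_id`, `runs` (each
#'   `list(design, volume)`), `pattern_spec`, `seed`.
#' @export
simulate_subject <- function(spec, seed, n_runs = 8L, subject_id = "sub-01",
                             acquisition_lag_s = 0) {
  stopifnot(inherits(spec, "pattern_spec"))
  grid <- spec$grid_shape
  V <- prod(grid)
  roi_idx <- which(spec$roi_mask)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    design <- make_run_design(substream(seed, sprintf("design.run%d", r)))
    X <- build_design_matrix(design, acquisition_lag_s = acquisition_lag_s)
    nt <- nrow(design)
    loc_cols <- X[, 1:16, drop = FALSE]
    stim_any <- rowSums(loc_cols)
    Y <- matrix(spec$offset, nt, V)
    Y[, roi_idx] <- Y[, roi_idx] + spec$baseline_amplitude * stim_any
    for (cond in names(spec$condition_patterns)) {
      pat <- spec$condition_patterns[[cond]]
      if (length(pat$voxels) == 0 || all(pat$effects == 0)) next
      Y[, pat$voxels] <- Y[, pat$voxels] +
        drop(loc_cols %*% pat$effects)
    }
    Y <- Y + spec$drift_slope * (X[, "trend"] * max(abs(seq_len(nt) - (nt + 1) / 2)))
    if (spec$noise_sd > 0) {
      Y <- Y + with_seed(substream(seed, sprintf("noise.run%d", r)),
                         ar1_noise(nt, V, spec$noise_sd, spec$ar1_coeff))
    }
    vol <- structure(list(data = array(as.vector(t(Y)), c(grid, nt)),
                          acquisition_times_s =
                            design$acquisition_onset_s + acquisition_lag_s,
                          voxel_size_mm = spec$voxel_size_mm,
                          tr_s = attr(design, "tr_s"),
                          smoothed = FALSE),
                     class = "volume_series")
    runs[[r]] <- list(design = design, volume = vol)
  }
  structure(list(subject_id = subject_id, runs = runs, pattern_spec = spec,
                 seed = as.integer(seed)),
            class = "subject_dataset")
}

# Stationary AR(1) noise matrix (nt x V): innovations scaled so the marginal
# sd equals noise_sd; 20 burn-in samples discarded.
ar1_noise <- function(nt, V, noise_sd, phi) {
  burn <- 20L
  eps <- matrix(rnorm((nt + burn) * V, sd = noise_sd * sqrt(1 - phi^2)),
                nt + burn, V)
  if (phi == 0) return(eps[(burn + 1):(burn + nt), , drop = FALSE])
  ac <- stats::filter(eps, phi, method = "recursive")
  matrix(ac[(burn + 1):(burn + nt), ], nt, V)
}

#' Write / read a subject dataset on disk
#'
#' One 4D NIfTI per run (`run-<r>_bold.nii.gz`, float64 so round-trips are
#' exact), one events table per run (`run-<r>_events.tsv`), the pattern spec
#' (including ground truth) as `pattern_spec.json` and subject metadata as
#' `dataset.json`. `read_dataset(write_dataset(ds, path))` is the identity.
#'
#' @param ds A `subject_dataset`.
#' @param path Directory (created if needed).
#' @return `read_dataset` returns the `subject_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "subject_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(ds$runs)) {
    run <- ds$runs[[r]]
    nifti_write(run$volume$data, file.path(path, sprintf("run-%d_bold.nii.gz", r)),
                voxel_size_mm = run$volume$voxel_size_mm,
                tr_s = run$volume$tr_s, datatype = "float64")
    ev <- as.data.frame(run$design)
    write_tsv_exact(ev, file.path(path, sprintf("run-%d_events.tsv", r)))
  }
  write_pattern_spec(ds$pattern_spec, file.path(path, "pattern_spec.json"))
  jsonlite::write_json(list(subject_id = ds$subject_id, seed = ds$seed,
                            n_runs = length(ds$runs)),
                       file.path(path, "dataset.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "dataset.json")
  if (!file.exists(meta_path)) stop_sl("read_dataset: missing %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  spec <- read_pattern_spec(file.path(path, "pattern_spec.json"))
  runs <- vector("list", meta$n_runs)
  for (r in seq_len(meta$n_runs)) {
    ev_path <- file.path(path, sprintf("run-%d_events.tsv", r))
    nii_path <- file.path(path, sprintf("run-%d_bold.nii.gz", r))
    if (!file.exists(ev_path)) {
      stop_sl("read_dataset: missing events file for run %d (%s)", r, ev_path)
    }
    if (!file.exists(nii_path)) {
      stop_sl("read_dataset: missing volume file for run %d (%s)", r, nii_path)
    }
    ev <- read_tsv_exact(ev_path)
    ev$location_id <- as.integer(ev$location_id)
    ev$index <- as.integer(ev$index)
    tr <- if (nrow(ev) > 1) ev$trial_onset_s[2] - ev$trial_onset_s[1] else 5.5
    attr(ev, "tr_s") <- tr
    attr(ev, "run_duration_s") <- nrow(ev) * tr
    class(ev) <- c("run_design", "data.frame")
    nii <- nifti_read(nii_path)
    vol <- structure(list(data = nii$data,
                          acquisition_times_s = ev$acquisition_onset_s,
                          voxel_size_mm = nii$voxel_size_mm,
                          tr_s = nii$tr_s, smoothed = FALSE),
                     class = "volume_series")
    runs[[r]] <- list(design = ev, volume = vol)
  }
  structure(list(subject_id = meta$subject_id, runs = runs,
                 pattern_spec = spec, seed = as.integer(meta$seed)),
            class = "subject_dataset")
}

write_pattern_spec <- function(spec, path) {
  x <- list(grid_shape = spec$grid_shape, voxel_size_mm = spec$voxel_size_mm,
            roi_voxels = which(spec$roi_mask),
            baseline_amplitude = spec$baseline_amplitude,
            condition_patterns = spec$condition_patterns,
            noise_sd = spec$noise_sd, ar1_coeff = spec$ar1_coeff,
            drift_slope = spec$drift_slope, offset = spec$offset,
            seed = spec$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_pattern_spec <- function(path) {
  if (!file.exists(path)) stop_sl("read_pattern_spec: missing %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- as.integer(x$grid_shape)
  roi <- array(FALSE, grid)
  roi[as.integer(x$roi_voxels)] <- TRUE
  pats <- lapply(x$condition_patterns, function(p) {
    list(voxels = as.integer(p$voxels), effects = as.numeric(p$effects))
  })
  structure(list(grid_shape = grid, voxel_size_mm = as.numeric(x$voxel_size_mm),
                 roi_mask = roi, baseline_amplitude = x$baseline_amplitude,
                 condition_patterns = pats, noise_sd = x$noise_sd,
                 ar1_coeff = x$ar1_coeff, drift_slope = x$drift_slope,
                 offset = x$offset, seed = as.integer(x$seed)),
            class = "pattern_spec")
}
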