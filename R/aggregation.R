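#' Effective voxels: voxels selected in more than four of a subject's folds
#'
#' Counts, per voxel, the cross-validation folds in which it was selected and
#' thresholds at `min_folds` (default 5, i.e. "more than four of eight").
#'
#' @param fold_selections List of 8 `selection_result`s (one per fold) for
#'   one subject and condition.
#' @param min_folds Minimum selection count (default 5).
#' @param grid_shape 3D grid dimensions of the underlying volume.
#' @param n_folds Required number of folds (default 8); a different length
#'   errors.
#' @param subject_id Stored in the result.
#' @return A list of class `ev_mask`: `mask` (logical 3D), `fold_counts`
#'   (integer 3D), `min_folds`, `condition`, `subject_id`.
#' @export
effective_voxels <- function(fold_selections, min_folds = 5L, grid_shape,
                             n_folds = 8L, subject_id = NA_character_) {
  if (length(fold_selections) != n_folds) {
    stop_sl("effective_voxels: expected %d fold selections, got %d",
            n_folds, length(fold_selections))
  }
  counts <- array(0L, grid_shape)
  cond <- fold_selections[[1]]$condition
  for (sel in fold_selections) {
    stopifnot(inherits(sel, "selection_result"))
    if (!identical(sel$condition, cond)) {
      stop_sl("effective_voxels: mixed conditions ('%s' vs '%s')",
              cond, sel$condition)
    }
    vox <- sel$voxel_index[sel$selected]
    counts[vox] <- counts[vox] + 1L
  }
  structure(list(mask = counts >= min_folds, fold_counts = counts,
                 min_folds = as.integer(min_folds), condition = cond,
                 subject_id = subject_id),
            class = "ev_mask")
}

#' Significant effective voxels: EVs shared by enough subjects
#'
#' Counts, per voxel, the subjects whose effective-voxel mask contains it and
#' thresholds at `min_subjects` (default 3 of 8).
#'
#' @param ev_masks List of `ev_mask`s, one per subject (same condition and
#'   grid).
#' @param min_subjects Minimum subject count (default 3).
#' @return A list of class `sev_mask`: `mask`, `subject_counts`,
#'   `min_subjects`, `condition`, `n_subjects`.
#' @export
significant_effective_voxels <- function(ev_masks, min_subjects = 3L) {
  stopifnot(length(ev_masks) >= min_subjects)
  dims <- dim(ev_masks[[1]]$mask)
  cond <- ev_masks[[1]]$condition
  counts <- array(0L, dims)
  for (ev in ev_masks) {
    stopifnot(inherits(ev, "ev_mask"))
    if (!identical(dim(ev$mask), dims)) {
      stop_sl("significant_effective_voxels: mismatched grids")
    }
    if (!identical(ev$condition, cond)) {
      stop_sl("significant_effective_voxels: mixed conditions")
    }
    counts <- counts + ev$mask
  }
  structure(list(mask = counts >= min_subjects, subject_counts = counts,
                 min_subjects = as.integer(min_subjects), condition = cond,
                 n_subjects = length(ev_masks)),
            class = "sev_mask")
}

#' Exact upper tail of the binomial distribution
#'
#' P(X >= k_min) for X ~ Binomial(n_subjects, p_success), computed as the
#' exact sum of binomial probabilities. This is the bound attached to the
#' SEV conjunction: if selecting an EV in one subject is a Bernoulli trial
#' with success probability p < 0.05, the probability that the same voxel is
#' an EV in 3 or more of 8 subjects is below P(X >= 3) at p = 0.05, which is
#' about 5.79e-3. The tail is monotone increasing in `p_success`.
#'
#' @param n_subjects Number of trials (subjects).
#' @param p_success Per-subject success probability in \[0, 1\].
#' @param k_min Threshold count in \[0, n_subjects\].
#' @return The exact tail probability.
#' @export
binomial_tail <- function(n_subjects, p_success, k_min) {
  if (length(n_subjects) != 1 || n_subjects < 0 ||
      n_subjects != round(n_subjects)) {
    stop_sl("binomial_tail: n_subjects must be a nonnegative integer")
  }
  if (p_success < 0 || p_success > 1) {
    stop_sl("binomial_tail: p_success must lie in [0, 1]")
  }
  if (k_min < 0 || k_min > n_subjects || k_min != round(k_min)) {
    stop_sl("binomial_tail: k_min must be an integer in [0, n_subjects]")
  }
  k <- k_min:n_subjects
  sum(choose(n_subjects, k) * p_success^k * (1 - p_success)^(n_subjects - k))
}

#' Write an EV or SEV mask as a NIfTI binary volume plus JSON summary
#'
#' @param mask_obj An `ev_mask` or `sev_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`; a `.json` summary
#'   is written next to it.
#' @param voxel_size_mm Voxel size for the NIfTI header.
#' @export
write_mask_volume <- function(mask_obj, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(mask_obj, c("ev_mask", "sev_mask")))
  nifti_write(array(as.integer(mask_obj$mask), dim(mask_obj$mask)), path,
              voxel_size_mm = voxel_size_mm, datatype = "uint8")
  summary <- list(condition = mask_obj$condition,
                  n_voxels = sum(mask_obj$mask),
                  threshold = mask_obj$min_folds %||% mask_obj$min_subjects)
  jsonlite::write_json(summary, paste0(sub("\\.nii(\\.gz)?$", "", path),
                                       "_summary.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
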