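#' Build the analysis ROI by smoothing and re-binarizing a base mask
#'
#' Mirrors the common neuroimaging recipe of Gaussian-smoothing an anatomical
#' mask (5 mm FWHM) and re-thresholding it, which closes small holes and
#' slightly dilates the boundary. The result is checked to be non-empty and
#' its connected-component count is attached as an attribute.
#'
#' @param base_mask Logical or 0/1 3D array.
#' @param fwhm_mm Smoothing kernel FWHM in millimetres; 0 returns the input.
#' @param voxel_size_mm Voxel size.
#' @param threshold Re-binarization threshold on the smoothed mask
#'   (default 0.5).
#' @return Logical 3D array with attribute `n_components`.
#' @export
build_roi_mask <- function(base_mask, fwhm_mm = 5, voxel_size_mm = c(1, 1, 1),
                           threshold = 0.5) {
  m <- array(as.numeric(base_mask != 0), dim(base_mask))
  out <- if (fwhm_mm == 0) m > 0 else
    smooth_volume(m, fwhm_mm, voxel_size_mm) > threshold
  if (!any(out)) stop_sl("build_roi_mask: empty mask after thresholding")
  attr(out, "n_components") <- count_components(out)
  out
}

# 6-connectivity connected components via BFS over voxel indices.
count_components <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  if (length(lin) == 0) return(0L)
  remaining <- rep(TRUE, length(lin))
  names(remaining) <- lin
  pos <- arrayInd(lin, d)
  rownames(pos) <- lin
  comp <- 0L
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(lin)) assign(as.character(lin[i]), i, envir = lookup)
  seen <- rep(FALSE, length(lin))
  for (i in seq_along(lin)) {
    if (seen[i]) next
    comp <- comp + 1L
    queue <- i
    seen[i] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      p <- pos[cur, ]
      for (ax in 1:3) for (dlt in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + dlt
        if (q[ax] < 1 || q[ax] > d[ax]) next
        nl <- q[1] + (q[2] - 1L) * d[1] + (q[3] - 1L) * d[1] * d[2]
        j <- mget(as.character(nl), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Assemble the (run x location) feature table for one condition
#'
#' One row per (training run, included location): the ROI-restricted beta
#' pattern of that location in that run, labelled by its class. Columns are
#' ordered by the stable linear voxel index of the ROI.
#'
#' @param responses List of `response_image`s (all runs of one subject).
#' @param labeling A `condition_labeling`.
#' @param roi Logical 3D ROI mask.
#' @param training_runs Integer indices into `responses`.
#' @return A list of class `feature_table`: `X` (rows x voxels), `y` (factor
#'   `a`/`b`), `run_ids`, `location_ids`, `voxel_index` (linear indices).
#' @export
assemble_features <- function(responses, labeling, roi, training_runs) {
  stopifnot(length(training_runs) >= 1, inherits(labeling, "condition_labeling"))
  vox <- which(roi)
  locs <- c(labeling$class_a, labeling$class_b)
  cls <- c(rep("a", length(labeling$class_a)),
           rep("b", length(labeling$class_b)))
  n_rows <- length(training_runs) * length(locs)
  X <- matrix(NA_real_, n_rows, length(vox))
  y <- character(n_rows)
  run_ids <- integer(n_rows)
  loc_ids <- integer(n_rows)
  row <- 0L
  for (r in training_runs) {
    betas <- responses[[r]]$betas
    V <- prod(dim(betas)[1:3])
    bm <- matrix(betas, nrow = V)
    for (k in seq_along(locs)) {
      row <- row + 1L
      X[row, ] <- bm[vox, locs[k] + 1L]
      y[row] <- cls[k]
      run_ids[row] <- r
      loc_ids[row] <- locs[k]
    }
  }
  structure(list(X = X, y = factor(y, levels = c("a", "b")),
                 run_ids = run_ids, location_ids = loc_ids,
                 voxel_index = vox, condition = labeling$condition),
            class = "feature_table")
}

#' Gaussian null of per-voxel SVM weights under label permutation
#'
#' Trains one linear SVM per seeded uniform permutation of the training
#' labels (default 2000 permutations) and summarizes each voxel's weight
#' distribution by its sample mean and standard deviation — the Gaussian fit
#' used for the selection p-values. Zero-variance (degenerate) voxels get
#' `null_sd = 0` and are flagged.
#'
#' @param ft A `feature_table`.
#' @param n_perm Number of permutations (>= 2; default 2000).
#' @param seed Integer seed for the permutation stream.
#' @param C,standardize,max_iter,tol SVM settings (see [svm_linear()]).
#' @return A list of class `gaussian_null`: `null_mean`, `null_sd` (per
#'   voxel), `n_perm`, `degenerate`, plus the true-label weights `true_w`
#'   (same standardized scale as the null).
#' @export
permutation_null <- function(ft, n_perm = 2000L, seed = 1L, C = 1,
                             standardize = TRUE, max_iter = 500L,
                             tol = 1e-6) {
  stopifnot(inherits(ft, "feature_table"), n_perm >= 2)
  yv <- svm_labels(ft$y)
  if (length(unique(yv)) < 2) stop_sl("permutation_null: both classes required")
  sc <- if (standardize) standardize_train(ft$X) else
    list(X = ft$X, degenerate = rep(FALSE, ncol(ft$X)))
  K <- tcrossprod(sc$X) + 1
  n <- nrow(K)
  A <- matrix(0, n, n_perm)
  with_seed(substream(seed, "permutations"), {
    for (b in seq_len(n_perm)) {
      yp <- yv[sample.int(n)]
      alpha <- dcd_svm_alpha(K, as.integer(yp), C, as.integer(max_iter), tol)
      A[, b] <- alpha * yp
    }
  })
  W <- crossprod(sc$X, A)                       # voxels x n_perm
  alpha_true <- dcd_svm_alpha(K, as.integer(yv), C, as.integer(max_iter), tol)
  true_w <- drop(crossprod(sc$X, alpha_true * yv))
  null_sd <- matrixStats::rowSds(W)
  null_sd[sc$degenerate] <- 0
  structure(list(null_mean = rowMeans(W), null_sd = null_sd,
                 n_perm = as.integer(n_perm), degenerate = sc$degenerate,
                 true_w = true_w, perm_w = W),
            class = "gaussian_null")
}

#' Two-sided Gaussian-tail p-values for observed SVM weights
#'
#' p = 2 * Phi(-|w - mu| / sigma) against the permutation-fitted Gaussian
#' null. Degenerate voxels (sigma = 0) get p = 1 when w equals mu and p = 0
#' otherwise.
#'
#' @param true_weights Observed per-voxel weights (defaults to the null's
#'   stored true-label weights).
#' @param null A `gaussian_null`.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
voxel_pvalues <- function(null, true_weights = NULL) {
  stopifnot(inherits(null, "gaussian_null"))
  w <- true_weights %||% null$true_w
  stopifnot(length(w) == length(null$null_mean))
  z <- abs(w - null$null_mean)
  p <- numeric(length(w))
  ok <- null$null_sd > 0
  p[ok] <- 2 * pnorm(-z[ok] / null$null_sd[ok])
  p[!ok] <- ifelse(z[!ok] == 0, 1, 0)
  p
}

#' Threshold selection p-values into a per-fold voxel selection
#'
#' Strict threshold `p < alpha`. If nothing survives, the fold falls back to
#' the full ROI (all non-degenerate voxels) and is flagged, so that
#' cross-validation stays balanced. Degenerate voxels are never selected.
#'
#' @param p_values Per-voxel p-values.
#' @param alpha Significance level (default 0.05).
#' @param condition,fold_id Metadata stored in the result.
#' @param voxel_index Linear voxel indices matching `p_values`.
#' @param degenerate Logical flags of degenerate voxels.
#' @return A list of class `selection_result`: `condition`, `fold_id`,
#'   `p_values`, `selected` (indices into `p_values`), `alpha`, `fallback`,
#'   `voxel_index`.
#' @export
select_voxels <- function(p_values, alpha = 0.05, condition = NA_character_,
                          fold_id = NA_integer_, voxel_index = NULL,
                          degenerate = NULL) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  degenerate <- degenerate %||% rep(FALSE, length(p_values))
  sel <- which(p_values < alpha & !degenerate)
  fallback <- length(sel) == 0
  if (fallback) sel <- which(!degenerate)
  structure(list(condition = condition, fold_id = fold_id,
                 p_values = p_values, selected = sel, alpha = alpha,
                 fallback = fallback,
                 voxel_index = voxel_index %||% seq_along(p_values)),
            class = "selection_result")
}

# One fold's full selection: permutation null + p-values + threshold,
# computed from training runs only.
fold_selection <- function(responses, labeling, roi, training_runs,
                           fold_id = NA_integer_, n_perm = 2000L, seed = 1L,
                           alpha = 0.05, C = 1, standardize = TRUE) {
  ft <- assemble_features(responses, labeling, roi, training_runs)
  null <- permutation_null(ft, n_perm = n_perm,
                           seed = substream(seed, sprintf("fold%d", fold_id)),
                           C = C, standardize = standardize)
  p <- voxel_pvalues(null)
  select_voxels(p, alpha = alpha, condition = labeling$condition,
                fold_id = fold_id, voxel_index = ft$voxel_index,
                degenerate = null$degenerate)
}

#' Persist / load a selection result as JSON
#'
#' @param sel A `selection_result`.
#' @param path File path.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(unclass(sel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$selected <- as.integer(x$selected)
  x$voxel_index <- as.integer(x$voxel_index)
  x$fold_id <- as.integer(x$fold_id)
  class(x) <- "selection_result"
  x
}
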