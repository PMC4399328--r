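test_that("ROI building smooths, re-binarizes and checks connectivity", {
  # derived by evaluating the smoother on a 10^3 box: a 5 mm kernel at a
  # strict 0.5 threshold keeps the interior and face centres but rounds off
  # corners and edges (erosion, not dilation, in 3D)
  box <- array(FALSE, c(16, 16, 16))
  box[4:13, 4:13, 4:13] <- TRUE
  roi <- build_roi_mask(box, fwhm_mm = 5, voxel_size_mm = c(1, 1, 1))
  expect_equal(sum(roi), 696)
  expect_true(all(roi[6:11, 6:11, 6:11]))   # interior intact
  expect_true(roi[8, 8, 4])                 # face centre survives
  expect_false(roi[4, 4, 4])                # corner rounded off
  expect_false(roi[8, 8, 3])                # no growth beyond the box
  expect_equal(attr(roi, "n_components"), 1)
  expect_error(build_roi_mask(array(FALSE, c(4, 4, 4))), "empty")
  expect_equal(build_roi_mask(box, fwhm_mm = 0), box, ignore_attr = TRUE)
  # the default-world bilateral ROI has two (hemispheric) components
  spec24 <- make_pattern_spec(seed = 1)
  expect_equal(attr(build_roi_mask(spec24$roi_mask, 0), "n_components"), 2)
})

test_that("feature tables have one row per training run and included location", {
  fx <- tiny_subject()
  arr <- speaker_array_fixture()
  expected_rows <- c(left_vs_right = 70, up_vs_down = 56, front_vs_back = 63)
  for (cond in names(expected_rows)) {
    lab <- condition_labels(arr, cond)
    ft <- assemble_features(fx$responses, lab, fx$spec$roi_mask, 1:7)
    expect_equal(nrow(ft$X), unname(expected_rows[cond]), label = cond)
    expect_equal(ncol(ft$X), sum(fx$spec$roi_mask))
    expect_false(any(ft$location_ids %in% lab$excluded))
    expect_equal(as.integer(table(ft$y)),
                 7 * c(length(lab$class_a), length(lab$class_b)))
  }
  # single held-out run: rows = included locations only
  lab <- condition_labels(arr, "left_vs_right")
  ft1 <- assemble_features(fx$responses, lab, fx$spec$roi_mask, 8)
  expect_equal(nrow(ft1$X), 10)
})

test_that("gaussian-tail p-values follow the stated rules", {
  null <- structure(list(null_mean = c(0, 0, 1, 1), null_sd = c(1, 1, 0, 0),
                         degenerate = c(FALSE, FALSE, TRUE, TRUE),
                         true_w = NULL, n_perm = 100L),
                    class = "gaussian_null")
  w <- c(0, 1.959964, 1, 2)
  p <- voxel_pvalues(null, w)
  expect_equal(p[1], 1)
  expect_equal(p[2], 0.05, tolerance = 1e-6)
  expect_equal(p[3], 1)   # sigma = 0, w = mu
  expect_equal(p[4], 0)   # sigma = 0, w != mu
})

test_that("voxel selection thresholds strictly and falls back when empty", {
  sel <- select_voxels(c(0.01, 0.049, 0.05, 0.9), alpha = 0.05)
  expect_equal(sel$selected, c(1L, 2L))
  expect_false(sel$fallback)
  flat <- select_voxels(rep(0.5, 4), alpha = 0.05)
  expect_true(flat$fallback)
  expect_equal(flat$selected, 1:4)
  expect_equal(select_voxels(c(0.2, 0.99), alpha = 1)$selected, 1:2)
  # degenerate voxels never selected, even by the fallback
  degen <- select_voxels(c(0.5, 0.5, 0), alpha = 0.05,
                         degenerate = c(FALSE, FALSE, TRUE))
  expect_equal(degen$selected, 1:2)
})

test_that("permutation nulls are seed-deterministic and row-order symmetric", {
  ft <- null_feature_table(5)
  n1 <- permutation_null(ft, n_perm = 50, seed = 3)
  n2 <- permutation_null(ft, n_perm = 50, seed = 3)
  expect_identical(n1$null_mean, n2$null_mean)
  expect_identical(n1$null_sd, n2$null_sd)
  expect_equal(n1$n_perm, 50L)
  # reordering rows leaves the true-label weights (the converged dual
  # optimum) unchanged up to solver tolerance
  perm <- with_seed(1, sample.int(nrow(ft$X)))
  ft2 <- ft
  ft2$X <- ft$X[perm, ]
  ft2$y <- ft$y[perm]
  n3 <- permutation_null(ft2, n_perm = 2, seed = 3)
  expect_equal(n3$true_w, n1$true_w, tolerance = 1e-3)
  expect_error(permutation_null(ft, n_perm = 1), "n_perm")
})

test_that("gaussian-fit p-values track empirical permutation ranks", {
  # 20-voxel label-free instances at 500 permutations: the Gaussian fit and
  # the empirical rank must agree within Monte-Carlo error
  ft <- null_feature_table(8, n_rows = 24, n_vox = 20)
  null <- permutation_null(ft, n_perm = 500, seed = 11)
  p_gauss <- voxel_pvalues(null)
  W <- null$perm_w
  p_emp <- vapply(seq_len(nrow(W)), function(v) {
    z <- abs(null$true_w[v] - null$null_mean[v])
    (1 + sum(abs(W[v, ] - null$null_mean[v]) >= z)) / (ncol(W) + 1)
  }, numeric(1))
  expect_lt(max(abs(p_gauss - p_emp)), 0.1)
})

test_that("selection is calibrated at level alpha on label-free data", {
  # scaled down: 30 null folds at n_perm = 200 (the 100-fold version runs in
  # the acceptance suite)
  rates <- numeric(30)
  for (i in 1:30) {
    ft <- null_feature_table(100 + i, n_rows = 24, n_vox = 40)
    null <- permutation_null(ft, n_perm = 200, seed = i)
    p <- voxel_pvalues(null)
    rates[i] <- mean(p < 0.05)
  }
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("selection results round-trip through JSON", {
  sel <- select_voxels(c(0.01, 0.2, 0.03), alpha = 0.05,
                       condition = "up_vs_down", fold_id = 2L,
                       voxel_index = c(10L, 20L, 30L))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_equal(back$selected, sel$selected)
  expect_equal(back$p_values, sel$p_values)
  expect_equal(back$voxel_index, sel$voxel_index)
  expect_equal(back$condition, "up_vs_down")
})
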