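#' Leave-one-run-out SVM decoding for one subject and condition
#'
#' For each of the 8 folds, the held-out run is set aside, voxel selection is
#' run on the 7 training runs only (permutation-null SVM-weight selection,
#' unless `selection_config$method = "none"`), a linear SVM is trained on the
#' selected voxels, and accuracy is scored on the held-out run's included
#' locations. The per-fold accuracies are averaged.
#'
#' @param responses List of 8 `response_image`s (one per run).
#' @param labeling A `condition_labeling`.
#' @param roi Logical 3D ROI mask.
#' @param selection_config List: `n_perm` (default 2000), `alpha` (0.05),
#'   `method` (`"permutation"` or `"none"`), `standardize` (TRUE).
#' @param svm_config List: `C` (default 1).
#' @param seed Integer seed for the permutation streams.
#' @param n_runs Expected number of runs (default 8).
#' @param subject_id Stored in the result.
#' @return A list of class `decoding_result`: `fold_accuracies`,
#'   `mean_accuracy`, `balanced_accuracies`, `n_test_per_fold`,
#'   `selection_flags` (fallback per fold), `selections` (per-fold
#'   `selection_result`s, NULL when selection is disabled), `condition`,
#'   `subject_id`.
#' @export
loro_cv <- function(responses, labeling, roi,
                    selection_config = list(), svm_config = list(),
                    seed = 1L, n_runs = 8L, subject_id = NA_character_) {
  if (length(responses) != n_runs) {
    stop_sl("loro_cv: expected %d runs, got %d", n_runs, length(responses))
  }
  sc <- modifyList(list(n_perm = 2000L, alpha = 0.05, method = "permutation",
                        standardize = TRUE), selection_config)
  vc <- modifyList(list(C = 1), svm_config)
  folds <- seq_len(n_runs)
  acc <- numeric(n_runs)
  bacc <- numeric(n_runs)
  ntest <- integer(n_runs)
  flags <- logical(n_runs)
  selections <- vector("list", n_runs)
  for (f in folds) {
    fit <- fit_fold(responses, labeling, roi, f, sc, vc, seed)
    ft_test <- assemble_features(responses, labeling, roi, f)
    Xte <- ft_test$X[, fit$feature_cols, drop = FALSE]
    pred <- predict(fit$model, Xte)
    acc[f] <- mean(pred == ft_test$y)
    bacc[f] <- mean(vapply(levels(ft_test$y), function(l) {
      mean(pred[ft_test$y == l] == l)
    }, numeric(1)))
    ntest[f] <- nrow(Xte)
    flags[f] <- fit$fallback
    selections[[f]] <- fit$selection
  }
  structure(list(subject_id = subject_id, condition = labeling$condition,
                 fold_accuracies = acc, mean_accuracy = mean(acc),
                 balanced_accuracies = bacc,
                 n_test_per_fold = ntest, selection_flags = flags,
                 selections = selections),
            class = "decoding_result")
}

# Train the model for one fold from training runs only. Exposed internally
# so tests can verify that the held-out run never influences the model.
fit_fold <- function(responses, labeling, roi, fold, sc, vc, seed) {
  training_runs <- setdiff(seq_along(responses), fold)
  ft <- assemble_features(responses, labeling, roi, training_runs)
  if (identical(sc$method, "none")) {
    cols <- seq_len(ncol(ft$X))
    sel <- NULL
    fallback <- FALSE
  } else {
    sel <- fold_selection(responses, labeling, roi, training_runs,
                          fold_id = fold, n_perm = sc$n_perm, seed = seed,
                          alpha = sc$alpha, C = vc$C,
                          standardize = sc$standardize)
    cols <- sel$selected
    fallback <- sel$fallback
  }
  model <- svm_linear(ft$X[, cols, drop = FALSE], ft$y, C = vc$C,
                      standardize = sc$standardize)
  list(model = model, feature_cols = cols, selection = sel,
       fallback = fallback)
}

#' Group-level test of decoding accuracy against chance
#'
#' One-sided one-sample t-test of per-subject mean accuracies against the
#' chance level (0.5). With zero variance across subjects the t statistic is
#' undefined; the result is flagged degenerate with p = 0 if the mean beats
#' chance and p = 1 otherwise.
#'
#' @param accuracies Numeric vector of per-subject mean accuracies (>= 2).
#' @param chance Chance level (default 0.5).
#' @param condition Metadata stored in the result.
#' @return A list of class `group_result`: `subject_accuracies`,
#'   `group_mean`, `chance`, `t`, `df`, `p_value`, `test_name`, `degenerate`.
#' @export
group_accuracy_test <- function(accuracies, chance = 0.5,
                                condition = NA_character_) {
  if (length(accuracies) < 2) {
    stop_sl("group_accuracy_test: need >= 2 subjects, got %d",
            length(accuracies))
  }
  stopifnot(all(accuracies >= 0 & accuracies <= 1))
  n <- length(accuracies)
  m <- mean(accuracies)
  s <- sd(accuracies)
  degenerate <- s == 0
  if (degenerate && m == chance) {
    # all subjects exactly at chance: no evidence either way
    tval <- 0
    p <- 0.5
  } else if (degenerate) {
    tval <- NA_real_
    p <- if (m > chance) 0 else 1
  } else {
    tval <- (m - chance) / (s / sqrt(n))
    p <- pt(tval, df = n - 1, lower.tail = FALSE)
  }
  structure(list(condition = condition, subject_accuracies = accuracies,
                 group_mean = m, chance = chance, t = tval, df = n - 1,
                 p_value = p, test_name = "one-sided one-sample t-test",
                 degenerate = degenerate),
            class = "group_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding %s (%s): mean accuracy %.3f over %d folds%s\n",
              x$condition, x$subject_id, x$mean_accuracy,
              length(x$fold_accuracies),
              if (any(x$selection_flags)) sprintf(" [%d fallback fold(s)]",
                                                  sum(x$selection_flags))
              else ""))
  invisible(x)
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("group %s: mean %.2f%% vs chance %.0f%%, t(%d) = %.2f, p = %.3g\n",
              x$condition, 100 * x$group_mean, 100 * x$chance, x$df,
              x$t, x$p_value))
  invisible(x)
}
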