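#' Pipeline configuration
#'
#' Assembles and validates the configuration for an end-to-end run. Defaults
#' mirror the experimental design the package emulates: 8 runs of 76 trials
#' at TR = 5.5 s, 2000 label permutations, selection threshold alpha = 0.05,
#' effective voxels at >= 5 of 8 folds, significant effective voxels at >= 3
#' subjects. Desk-scale exploration typically lowers `n_subjects` and
#' `n_perm`.
#'
#' @param seed Master seed; every random draw flows from it through named
#'   substreams.
#' @param n_subjects Number of simulated subjects (default 8).
#' @param n_runs Runs per subject (default 8).
#' @param n_perm Label permutations per fold (default 2000).
#' @param alpha Voxel-selection significance level (default 0.05).
#' @param min_folds EV threshold (default 5).
#' @param min_subjects SEV threshold (default 3).
#' @param conditions Discrimination conditions to decode.
#' @param pattern Named list forwarded to [make_pattern_spec()].
#' @param svm List of SVM settings (`C`).
#' @param standardize Standardize features with training statistics.
#' @param selection_method `"permutation"` or `"none"`.
#' @param output_dir Output directory (default: a fresh temporary directory).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 8L, n_runs = 8L,
                            n_perm = 2000L, alpha = 0.05, min_folds = 5L,
                            min_subjects = 3L,
                            conditions = sl_conditions(),
                            pattern = list(), svm = list(C = 1),
                            standardize = TRUE,
                            selection_method = "permutation",
                            output_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              n_runs = as.integer(n_runs), n_perm = as.integer(n_perm),
              alpha = alpha, min_folds = as.integer(min_folds),
              min_subjects = as.integer(min_subjects),
              conditions = conditions, pattern = pattern,
              svm = modifyList(list(C = 1), svm),
              standardize = isTRUE(standardize),
              selection_method = match.arg(selection_method,
                                           c("permutation", "none")),
              output_dir = output_dir %||%
                tempfile(pattern = "soundloc3d-run-"))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_runs >= 2,
            cfg$n_perm >= 2, cfg$alpha > 0, cfg$alpha <= 1,
            cfg$min_folds >= 1, cfg$min_folds <= cfg$n_runs,
            cfg$min_subjects >= 1, cfg$min_subjects <= cfg$n_subjects,
            cfg$svm$C > 0)
  bad <- setdiff(cfg$conditions, sl_conditions())
  if (length(bad) > 0) {
    stop_sl("unknown condition(s): %s", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON file whose keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_sl("config file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop_sl("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (!is.null(x$pattern)) x$pattern <- as.list(x$pattern)
  if (!is.null(x$svm)) x$svm <- as.list(x$svm)
  do.call(pipeline_config, x)
}

subject_dirname <- function(s) sprintf("sub-%02d", s)

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its outputs to,
#' `config$output_dir`, so chained stage invocations reproduce the one-shot
#' [run_pipeline()] exactly (all seeds derive from the config, never from
#' execution order). `stage_simulate` writes per-subject datasets;
#' `stage_glm` fits the per-run GLMs and writes 4D beta volumes with a JSON
#' sidecar; `stage_decode` runs voxel selection and leave-one-run-out
#' decoding per condition; `stage_aggregate` builds EV and SEV masks;
#' `stage_report` assembles the JSON report.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return The output directory (stages) or the report list
#'   (`stage_report`), invisibly.
#' @export
stage_simulate <- function(config, quiet = TRUE) {
  validate_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  spec <- make_pattern_spec(config$pattern, seed = config$seed)
  for (s in seq_len(config$n_subjects)) {
    if (!quiet) message("simulate: subject ", s)
    ds <- simulate_subject(spec, substream(config$seed, sprintf("subject%d", s)),
                           n_runs = config$n_runs,
                           subject_id = subject_dirname(s))
    write_dataset(ds, file.path(out, subject_dirname(s)))
  }
  jsonlite::write_json(config_echo(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# Config as echoed into reports: the machine-local output path is dropped so
# that identical config + seed yields a byte-identical report.
config_echo <- function(config) {
  ec <- unclass(config)
  ec$output_dir <- NULL
  if (length(ec$pattern) > 0) {
    ec$pattern <- ec$pattern[order(names(ec$pattern))]
  }
  ec
}

#' @rdname stage_simulate
#' @export
stage_glm <- function(config, quiet = TRUE) {
  out <- config$output_dir
  for (s in seq_len(config$n_subjects)) {
    sdir <- file.path(out, subject_dirname(s))
    ds <- read_dataset(sdir)
    gdir <- file.path(sdir, "glm")
    dir.create(gdir, showWarnings = FALSE)
    for (r in seq_along(ds$runs)) {
      if (!quiet) message("glm: subject ", s, " run ", r)
      run <- ds$runs[[r]]
      dm <- build_design_matrix(run$design)
      ri <- fit_run_glm(run$volume, dm, run_id = r)
      nifti_write(ri$betas, file.path(gdir, sprintf("run-%d_betas.nii.gz", r)),
                  voxel_size_mm = ds$pattern_spec$voxel_size_mm,
                  datatype = "float64")
      nifti_write(ri$residual_variance,
                  file.path(gdir, sprintf("run-%d_residvar.nii.gz", r)),
                  voxel_size_mm = ds$pattern_spec$voxel_size_mm,
                  datatype = "float64")
      jsonlite::write_json(list(run_id = r, location_ids = ri$location_ids,
                                df = ri$df),
                           file.path(gdir, sprintf("run-%d_betas.json", r)),
                           auto_unbox = TRUE)
    }
  }
  invisible(out)
}

read_subject_responses <- function(sdir, n_runs) {
  lapply(seq_len(n_runs), function(r) {
    bp <- file.path(sdir, "glm", sprintf("run-%d_betas.nii.gz", r))
    if (!file.exists(bp)) stop_sl("missing beta volume for run %d: %s", r, bp)
    nii <- nifti_read(bp)
    meta <- jsonlite::read_json(file.path(sdir, "glm",
                                          sprintf("run-%d_betas.json", r)),
                                simplifyVector = TRUE)
    structure(list(betas = nii$data, run_id = meta$run_id,
                   location_ids = as.integer(meta$location_ids)),
              class = "response_image")
  })
}

#' @rdname stage_simulate
#' @export
stage_decode <- function(config, quiet = TRUE) {
  out <- config$output_dir
  arr <- build_speaker_array()
  for (s in seq_len(config$n_subjects)) {
    sdir <- file.path(out, subject_dirname(s))
    spec <- read_pattern_spec(file.path(sdir, "pattern_spec.json"))
    responses <- read_subject_responses(sdir, config$n_runs)
    ddir <- file.path(sdir, "decoding")
    dir.create(ddir, showWarnings = FALSE)
    for (cond in config$conditions) {
      if (!quiet) message("decode: subject ", s, " ", cond)
      labeling <- condition_labels(arr, cond)
      res <- loro_cv(responses, labeling, spec$roi_mask,
                     selection_config = list(n_perm = config$n_perm,
                                             alpha = config$alpha,
                                             method = config$selection_method,
                                             standardize = config$standardize),
                     svm_config = config$svm,
                     seed = substream(config$seed,
                                      sprintf("decode.sub%d.%s", s, cond)),
                     n_runs = config$n_runs,
                     subject_id = subject_dirname(s))
      jsonlite::write_json(list(subject_id = res$subject_id,
                                condition = cond,
                                fold_accuracies = res$fold_accuracies,
                                mean_accuracy = res$mean_accuracy,
                                balanced_accuracies = res$balanced_accuracies,
                                n_test_per_fold = res$n_test_per_fold,
                                selection_flags = res$selection_flags),
                           file.path(ddir, sprintf("%s_result.json", cond)),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(res$selections[[1]])) {
        for (f in seq_along(res$selections)) {
          write_selection(res$selections[[f]],
                          file.path(ddir, sprintf("%s_fold-%d_selection.json",
                                                  cond, f)))
        }
      }
    }
  }
  invisible(out)
}

#' @rdname stage_simulate
#' @export
stage_aggregate <- function(config, quiet = TRUE) {
  out <- config$output_dir
  adir <- file.path(out, "aggregation")
  dir.create(adir, showWarnings = FALSE)
  spec <- read_pattern_spec(file.path(out, subject_dirname(1),
                                      "pattern_spec.json"))
  for (cond in config$conditions) {
    ev_masks <- list()
    for (s in seq_len(config$n_subjects)) {
      ddir <- file.path(out, subject_dirname(s), "decoding")
      sels <- lapply(seq_len(config$n_runs), function(f) {
        read_selection(file.path(ddir, sprintf("%s_fold-%d_selection.json",
                                               cond, f)))
      })
      ev <- effective_voxels(sels, min_folds = config$min_folds,
                             grid_shape = spec$grid_shape,
                             n_folds = config$n_runs,
                             subject_id = subject_dirname(s))
      write_mask_volume(ev, file.path(adir, sprintf("%s_%s_ev.nii.gz",
                                                    subject_dirname(s), cond)),
                        voxel_size_mm = spec$voxel_size_mm)
      ev_masks[[s]] <- ev
    }
    if (config$n_subjects >= config$min_subjects) {
      sev <- significant_effective_voxels(ev_masks,
                                          min_subjects = config$min_subjects)
      write_mask_volume(sev, file.path(adir, sprintf("%s_sev.nii.gz", cond)),
                        voxel_size_mm = spec$voxel_size_mm)
      jsonlite::write_json(
        list(condition = cond, sev_voxels = which(sev$mask),
             subject_counts_nonzero = sum(sev$subject_counts > 0),
             ev_voxels_per_subject = vapply(ev_masks,
                                            function(e) sum(e$mask),
                                            numeric(1))),
        file.path(adir, sprintf("%s_sev.json", cond)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(out)
}

#' @rdname stage_simulate
#' @export
stage_report <- function(config, quiet = TRUE) {
  out <- config$output_dir
  spec <- read_pattern_spec(file.path(out, subject_dirname(1),
                                      "pattern_spec.json"))
  decoding <- list()
  group <- list()
  aggregation <- list()
  for (cond in config$conditions) {
    per_subject <- lapply(seq_len(config$n_subjects), function(s) {
      jsonlite::read_json(file.path(out, subject_dirname(s), "decoding",
                                    sprintf("%s_result.json", cond)),
                          simplifyVector = TRUE)
    })
    decoding[[cond]] <- per_subject
    accs <- vapply(per_subject, function(x) x$mean_accuracy, numeric(1))
    group[[cond]] <- if (config$n_subjects >= 2) {
      unclass(group_accuracy_test(accs, condition = cond))
    } else {
      list(condition = cond, note = "group test requires >= 2 subjects")
    }
    sev_path <- file.path(out, "aggregation", sprintf("%s_sev.json", cond))
    if (file.exists(sev_path)) {
      sev_info <- jsonlite::read_json(sev_path, simplifyVector = TRUE)
      truth <- spec$condition_patterns[[cond]]$voxels
      sev_vox <- as.integer(sev_info$sev_voxels)
      aggregation[[cond]] <- list(
        n_sev = length(sev_vox),
        ev_voxels_per_subject = sev_info$ev_voxels_per_subject,
        recovery = list(
          n_truth = length(truth),
          sensitivity = if (length(truth) > 0)
            length(intersect(sev_vox, truth)) / length(truth) else NA,
          precision = if (length(sev_vox) > 0)
            length(intersect(sev_vox, truth)) / length(sev_vox) else NA))
    }
  }
  report <- list(package_version = as.character(packageVersion("soundloc3d")),
                 config = config_echo(config),
                 decoding = decoding, group = group,
                 aggregation = aggregation,
                 binomial_bound = list(
                   n_subjects = 8, p_success = 0.05, k_min = 3,
                   tail = binomial_tail(8, 0.05, 3)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- c("soundloc3d pipeline report",
           sprintf("subjects: %d, runs: %d, permutations: %d, alpha: %g",
                   config$n_subjects, config$n_runs, config$n_perm,
                   config$alpha))
  for (cond in names(group)) {
    g <- group[[cond]]
    if (!is.null(g$group_mean)) {
      txt <- c(txt, sprintf("%s: mean accuracy %.2f%% (chance 50%%), p = %.3g",
                            cond, 100 * g$group_mean, g$p_value))
    }
  }
  writeLines(txt, file.path(out, "summary.txt"))
  if (!quiet) writeLines(txt)
  invisible(report)
}

#' Run the full pipeline: simulate, fit, decode, aggregate, report
#'
#' Executes the five stages in order against `config$output_dir` and returns
#' the report. Identical config and seed produce an identical report.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return The report list (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stage_simulate(config, quiet)
  stage_glm(config, quiet)
  stage_decode(config, quiet)
  stage_aggregate(config, quiet)
  invisible(stage_report(config, quiet))
}
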