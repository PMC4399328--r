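# Shared fixtures, built in code and cached per test session. The "tiny"
# world uses a 12 x 12 x 6 grid (ROI of 528 voxels) so that selection and
# decoding tests run in seconds; the acceptance tests use the package's
# default 24 x 24 x 12 world.

sl_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = sl_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = sl_cache)
  }
  get(name, envir = sl_cache)
}

tiny_spec <- function(amplitude = 2, noise_sd = 1, seed = 11,
                      grid = c(12L, 12L, 6L), n_informative = 10L, ...) {
  make_pattern_spec(list(grid_shape = grid, n_informative = n_informative,
                         amplitudes = list(left_vs_right = amplitude,
                                           up_vs_down = amplitude,
                                           front_vs_back = amplitude),
                         noise_sd = noise_sd, ...),
                    seed = seed)
}

fit_responses <- function(ds) {
  lapply(seq_along(ds$runs), function(r) {
    fit_run_glm(ds$runs[[r]]$volume, build_design_matrix(ds$runs[[r]]$design),
                run_id = r)
  })
}

# Planted-pattern subject in the tiny world, used by several files.
tiny_subject <- function() {
  cached("tiny_subject", {
    spec <- tiny_spec()
    ds <- simulate_subject(spec, seed = 42, n_runs = 8)
    list(spec = spec, ds = ds, responses = fit_responses(ds))
  })
}

# Label-free feature table: rows carry no class information.
null_feature_table <- function(seed, n_rows = 24L, n_vox = 20L) {
  with_seed(seed, {
    X <- matrix(rnorm(n_rows * n_vox), n_rows, n_vox)
    structure(list(X = X,
                   y = factor(rep(c("a", "b"), length.out = n_rows),
                              levels = c("a", "b")),
                   run_ids = rep(1L, n_rows),
                   location_ids = seq_len(n_rows) - 1L,
                   voxel_index = seq_len(n_vox),
                   condition = "left_vs_right"),
              class = "feature_table")
  })
}

speaker_array_fixture <- function() cached("speaker_array", build_speaker_array())
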