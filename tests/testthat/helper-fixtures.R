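# Shared fixtures. Everything is generated in code; the heavier objects are
# built once per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# small, fast cohort: 30 Hz, one trial per type, short walks
tiny_cohort_config <- function(n_wa = 2, n_na = 2, seed = 1,
                               missing_tug_fraction = 0, ...) {
  cohort_config(n_wa, n_na, seed = seed, sample_rate_hz = 30,
                n_trials = 1, mwt_cycles = 5, tug_walk_cycles = 2,
                missing_tug_fraction = missing_tug_fraction, ...)
}

tiny_model_config <- function(seq_len = 12L, dropout = 0, ...) {
  model_config(seq_len = seq_len, n_channels = 48L, d_model = 16L,
               n_blocks = 1L, n_heads = 2L, ff_dim = 24L,
               dropout = dropout, ...)
}

# hand-built gait-cycle window with controllable content
mk_window <- function(len = 10, subject = "S1", label = "WA",
                      trial_type = "10MWT", trial_index = 1,
                      data = NULL, fill = 0.1) {
  if (is.null(data)) data <- matrix(fill, len, 48)
  colnames(data) <- channel_names()
  structure(list(subject_id = subject, trial_type = trial_type,
                 trial_index = as.integer(trial_index), side = "left",
                 start = 1L, end = nrow(data) + 1L, data = data,
                 label = label),
            class = "gait_cycle")
}

# a normalized, padded sample with constant interior
mk_sample <- function(len = 10, length_max = 20, subject = "S1",
                      label = "WA", value = 0.6) {
  w <- mk_window(len, subject, label, fill = value)
  w$normalized <- TRUE
  pad_window(w, length_max = length_max)
}

# small segmented cohort, cached
get_tiny_windows <- function() {
  if (is.null(.fixture_env$tiny_windows)) {
    cohort <- generate_cohort(tiny_cohort_config(2, 2, seed = 11))
    .fixture_env$tiny_windows <- segment_cohort(cohort)
  }
  .fixture_env$tiny_windows
}

# one small LOOCV run shared by the evaluation and acceptance tests
get_small_loocv <- function() {
  if (is.null(.fixture_env$small_loocv)) {
    w <- get_tiny_windows()
    tc <- train_config(epochs = 2, batch_size = 16, learning_rate = 1e-3,
                       warmup_steps = 10)
    mc <- model_config(n_blocks = 1L, ff_dim = 32L)
    .fixture_env$small_loocv <- run_loocv(w, mc, tc, seed = 42)
  }
  .fixture_env$small_loocv
}

# linearly separable two-class toy samples for training sanity checks
mk_separable_samples <- function(n_per_class = 30, len = 12,
                                 length_max = 12, seed = 99) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_per_class)) {
    for (lab in c("WA", "NA")) {
      base <- if (lab == "WA") 0.35 else 0.65
      w <- mk_window(len, subject = paste0(lab, i), label = lab,
                     data = matrix(stats::runif(len * 48, base - 0.1,
                                                base + 0.1), len, 48))
      w$normalized <- TRUE
      out[[length(out) + 1L]] <- pad_window(w, length_max = length_max)
    }
  }
  out
}
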