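# Shared fixtures. The heavier synthetic cohorts are built lazily and
# cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a clean deterministic configuration: one beat train, nothing else
noiseless_config <- function(duration_s = 10, hr = 60) {
  synthetic_config(
    duration_s = duration_s, n_channels = 1,
    heart_rate_bpm_mean = c(normotensive = hr, hypertensive = hr),
    heart_rate_bpm_sd = c(normotensive = 0, hypertensive = 0),
    beat_jitter_fraction = 0, resp_amplitude = 0, drift_amplitude = 0,
    noise_sd = 0, artifact_rate_per_min = 0, seed = 7L
  )
}

# class-separated study cohort: 30 recordings/class x 5 min, preprocessed,
# segmented into 30-s windows, summarised to the feature table
separated_feature_table <- function() {
  memo("separated_features", function() {
    cfg <- synthetic_config(duration_s = 300, seed = 20260901L)
    recs <- generate_dataset(cfg, n_per_class = 30L)
    pre <- lapply(recs, preprocess_recording)
    segs <- unlist(lapply(pre, segment_recording), recursive = FALSE)
    build_feature_table(segs)
  })
}

# null cohort: identical generators for both classes, 30 recordings/class
# x 2.5 min, so labels carry no information
null_feature_table <- function() {
  memo("null_features", function() {
    cfg <- null_config(synthetic_config(duration_s = 150, seed = 20260902L))
    recs <- generate_dataset(cfg, n_per_class = 30L)
    pre <- lapply(recs, preprocess_recording)
    segs <- unlist(lapply(pre, segment_recording), recursive = FALSE)
    build_feature_table(segs)
  })
}

# small separable two-cluster feature set for model unit tests
separable_clusters <- function(n = 200, d = 22, shift = 1.5, seed = 11) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * d), n, d) + outer(y, rep(shift, d))
  list(X = standardize_features(X)$train, y = y)
}

make_recording <- function(x, fs = 100) {
  bcg_recording(matrix(x, ncol = 1), sampling_rate_hz = fs,
                label = "unlabeled", subject_id = "test")
}
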