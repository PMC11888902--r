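two_channel_recording <- function(n, fs = 100, seed = 1) {
  set.seed(seed)
  bcg_recording(matrix(rnorm(2 * n), ncol = 2), sampling_rate_hz = fs,
                label = "hypertensive", subject_id = "seg01")
}

test_that("30-s windows at 100 Hz hold exactly 3000 samples", {
  rec <- two_channel_recording(9000)
  segs <- segment_recording(rec, window_s = 30)
  expect_length(segs, 3L)
  for (s in segs) expect_equal(nrow(s$samples), 3000L)
  expect_equal(vapply(segs, `[[`, integer(1), "start_sample"),
               c(0L, 3000L, 6000L))
  expect_length(segment_recording(two_channel_recording(3000)), 1L)
  # trailing remainder dropped
  expect_length(segment_recording(two_channel_recording(3500)), 1L)
  # shorter than one window: empty, not an error
  expect_length(segment_recording(two_channel_recording(2000)), 0L)
})

test_that("segments inherit label and carry traceable identifiers", {
  segs <- segment_recording(two_channel_recording(9000))
  expect_equal(unique(vapply(segs, `[[`, character(1), "label")),
               "hypertensive")
  expect_equal(vapply(segs, `[[`, character(1), "segment_id"),
               c("seg01_001_hypertensive", "seg01_002_hypertensive",
                 "seg01_003_hypertensive"))
})

test_that("summary statistics match their textbook values", {
  seg <- structure(list(source_id = "s", label = "normotensive",
                        start_sample = 0L,
                        samples = matrix(c(1, 2, 3, 4, 5), ncol = 1,
                                         dimnames = list(NULL, "ch1")),
                        sampling_rate_hz = 100, segment_id = "s_001"),
                   class = "bcg_segment")
  f <- extract_features(seg)
  expect_equal(unname(f[c("ch1_mean", "ch1_median", "ch1_range", "ch1_q1",
                          "ch1_q3", "ch1_iqr", "ch1_skewness")]),
               c(3, 3, 4, 2, 4, 2, 0))

  seg$samples <- matrix(rep(4.2, 100), ncol = 1,
                        dimnames = list(NULL, "ch1"))
  g <- extract_features(seg)
  expect_equal(unname(g[c("ch1_sd", "ch1_range", "ch1_skewness",
                          "ch1_kurtosis")]), c(0, 0, 0, 0))

  # single outlier channel: m2 = 16, m3 = 96 -> skew 1.5, excess kurt 0.25
  seg$samples <- matrix(c(0, 0, 0, 0, 10), ncol = 1,
                        dimnames = list(NULL, "ch1"))
  h <- extract_features(seg)
  expect_equal(unname(h["ch1_skewness"]), 1.5)
  expect_equal(unname(h["ch1_kurtosis"]), 0.25)
  expect_equal(unname(h[c("ch1_skewness", "ch1_kurtosis")]),
               unname(naive_channel_stats(c(0, 0, 0, 0, 10))[
                 c("skewness", "kurtosis")]))
})

test_that("features agree with the brute-force oracle and e1071", {
  skip_if_not_installed("e1071")
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(200, sd = runif(1, 0.1, 10))
    seg <- structure(list(source_id = "s", label = "normotensive",
                          start_sample = 0L,
                          samples = matrix(x, ncol = 1,
                                           dimnames = list(NULL, "ch1")),
                          sampling_rate_hz = 100, segment_id = "s"),
                     class = "bcg_segment")
    f <- extract_features(seg)
    o <- naive_channel_stats(x)
    expect_equal(as.numeric(f), unname(o), tolerance = 1e-10)
    expect_equal(unname(f["ch1_skewness"]), e1071::skewness(x, type = 1),
                 tolerance = 1e-10)
    expect_equal(unname(f["ch1_kurtosis"]), e1071::kurtosis(x, type = 1),
                 tolerance = 1e-10)
  }
})

test_that("order statistics obey their defining inequalities", {
  set.seed(7)
  for (i in 1:25) {
    x <- rt(100, df = 3)
    s <- extract_features(structure(
      list(source_id = "s", label = "normotensive", start_sample = 0L,
           samples = matrix(x, ncol = 1, dimnames = list(NULL, "ch1")),
           sampling_rate_hz = 100, segment_id = "s"),
      class = "bcg_segment"))
    expect_true(s["ch1_min"] <= s["ch1_q1"])
    expect_true(s["ch1_q1"] <= s["ch1_median"])
    expect_true(s["ch1_median"] <= s["ch1_q3"])
    expect_true(s["ch1_q3"] <= s["ch1_max"])
    expect_true(s["ch1_iqr"] >= 0)
    expect_true(s["ch1_min"] <= s["ch1_mean"] && s["ch1_mean"] <= s["ch1_max"])
  }
})

test_that("features transform correctly under affine maps", {
  set.seed(21)
  base_stats <- function(x) extract_features(structure(
    list(source_id = "s", label = "normotensive", start_sample = 0L,
         samples = matrix(x, ncol = 1, dimnames = list(NULL, "ch1")),
         sampling_rate_hz = 100, segment_id = "s"),
    class = "bcg_segment"))
  for (i in 1:10) {
    x <- rnorm(150)
    a <- runif(1, 0.5, 4)   # positive scale
    b <- runif(1, -10, 10)  # shift
    f0 <- base_stats(x)
    f1 <- base_stats(a * x + b)
    shift_eq <- c("ch1_mean", "ch1_median", "ch1_min", "ch1_max",
                  "ch1_q1", "ch1_q3")
    expect_equal(unname(f1[shift_eq]), unname(a * f0[shift_eq] + b),
                 tolerance = 1e-10)
    scale_eq <- c("ch1_sd", "ch1_range", "ch1_iqr")
    expect_equal(unname(f1[scale_eq]), unname(a * f0[scale_eq]),
                 tolerance = 1e-10)
    invar <- c("ch1_skewness", "ch1_kurtosis")
    expect_equal(unname(f1[invar]), unname(f0[invar]), tolerance = 1e-8)
  }
})

test_that("feature tables have stable shape, names and row order", {
  rec <- two_channel_recording(9000)
  rec2 <- two_channel_recording(9000, seed = 2)
  rec2$subject_id <- "seg02"
  rec2$label <- "normotensive"
  segs <- c(segment_recording(rec), segment_recording(rec2))
  tbl <- build_feature_table(segs)
  expect_equal(dim(tbl), c(6L, 22L + 3L))
  expect_equal(tbl$label, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_true(all(paste0("ch1_", c("mean", "sd", "median", "max", "min",
                                   "range", "q1", "q3", "iqr", "kurtosis",
                                   "skewness")) %in% names(tbl)))
  # shuffling segments permutes rows identically
  perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
  tbl2 <- build_feature_table(segs[perm])
  expect_equal(feature_matrix(tbl2), feature_matrix(tbl)[perm, ],
               ignore_attr = TRUE)
  expect_equal(tbl2$source_id, tbl$source_id[perm])
})

test_that("standardisation uses train-fitted parameters only", {
  train <- matrix(c(1, 3), ncol = 1)
  std <- standardize_features(train, test = matrix(c(2, 5), ncol = 1))
  expect_equal(std$train[, 1], c(-1, 1))   # population sd
  expect_equal(std$test[1, 1], 0)          # value at the train mean
  expect_equal(std$test[2, 1], 3)

  const <- standardize_features(matrix(c(4, 4, 4), ncol = 1))
  expect_equal(const$train[, 1], c(0, 0, 0))  # sd-1 convention
  expect_equal(const$scale[[1]], 1)
})
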