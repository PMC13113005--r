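test_that("slice_window applies the half-open interval and matching criterion", {
  stream <- tibble::tibble(timestamp = seq(0, 299.5, by = 0.5), mv = rnorm(600))
  w <- slice_window(stream, end_time = 299.5, width = 300)
  expect_s3_class(w, "voltage_window")
  expect_equal(w$n, 600)

  # sample exactly at end_time - width is excluded
  w2 <- slice_window(stream, end_time = 300, width = 300)
  expect_equal(w2$n, 599)
  expect_true(all(w2$times > 0 & w2$times <= 300))

  # nine samples in the window is a rejection, ten is not
  sparse <- tibble::tibble(timestamp = seq_len(9) * 10, mv = rnorm(9))
  expect_null(slice_window(sparse, end_time = 100, width = 300))
  sparse10 <- tibble::tibble(timestamp = seq_len(10) * 10, mv = rnorm(10))
  expect_false(is.null(slice_window(sparse10, end_time = 100, width = 300)))

  # window entirely before the stream, and empty streams, reject
  expect_null(slice_window(stream, end_time = -10, width = 300))
  expect_null(slice_window(tibble::tibble(timestamp = numeric(0),
                                          mv = numeric(0)), 100))
})

test_that("statistical features match hand-computed values", {
  w <- make_window(c(5, 5, 5, 5))
  f <- statistical_features(w)
  expect_equal(f$mean, 5)
  expect_equal(f$std, 0)
  expect_equal(f$range, 0)
  expect_equal(f$iqr, 0)
  expect_equal(f$cv, 0)
  expect_equal(f$rms, 5)

  f <- statistical_features(make_window(c(1, 2, 3, 4, 5)))
  expect_equal(f$mean, 3)
  expect_equal(f$range, 4)
  expect_equal(f$std, sqrt(2.5))
  expect_equal(f$rms, sqrt(11))
  expect_equal(f$cv, sqrt(2.5) / 3)
  expect_equal(f$iqr, 2)

  # zero mean leaves cv undefined
  expect_true(is.na(statistical_features(make_window(c(-1, 1)))$cv))
})

test_that("temporal features handle ramps, constants and alternation", {
  tt <- seq(0, 300, by = 1)
  f <- temporal_features(make_window(2 * tt, times = tt))
  expect_equal(f$trend_slope, 2)
  expect_equal(f$trend_r2, 1)
  expect_equal(f$direction_change_rate, 0)

  f0 <- temporal_features(make_window(rep(7, 50)))
  expect_equal(unname(unlist(f0)), rep(0, 5))

  # alternating 0/1 at 1 Hz over 10 s: change at every interior step
  f1 <- temporal_features(make_window(rep(c(0, 1), length.out = 11)))
  expect_equal(f1$mean_abs_change, 1)
  expect_equal(f1$direction_change_rate, 9 / 10)
})

test_that("spectral features recover known sinusoids", {
  # pure 1 Hz sinusoid at 120 Hz over 10 s
  tt <- seq(0, 10 - 1 / 120, by = 1 / 120)
  w <- make_window(sin(2 * pi * tt), times = tt)
  f <- spectral_features(w, sample_rate = 120)
  expect_equal(f$dominant_frequency, 1, tolerance = 1e-6)
  expect_gt(f$power_low_rel, 0.99)  # 1 Hz lies in [0.5, 2)

  # equal-amplitude 0.2 Hz + 10 Hz split evenly across their bands
  w2 <- make_window(sin(2 * pi * 0.2 * tt) + sin(2 * pi * 10 * tt),
                    times = tt)
  f2 <- spectral_features(w2, sample_rate = 120)
  expect_equal(f2$power_very_low_rel, 0.5, tolerance = 0.01)
  expect_equal(f2$power_high_rel, 0.5, tolerance = 0.01)

  # constant window: zero power, missing relatives
  fc <- spectral_features(make_window(rep(3, 16)), sample_rate = 1)
  expect_equal(fc$total_power, 0)
  expect_true(is.na(fc$dominant_frequency))
  expect_true(is.na(fc$power_mid_rel))
})

test_that("spectral features agree with a brute-force DFT oracle", {
  set.seed(41)
  for (n in c(64, 500, 1024)) {
    rate <- 8
    tt <- (seq_len(n) - 1) / rate
    v <- cumsum(rnorm(n)) + sin(2 * pi * 0.7 * tt)
    w <- make_window(v, times = tt)
    f <- spectral_features(w, band_edges = c(0, 0.2, 0.8, 1.6, 2.4, 4),
                           sample_rate = rate)

    P <- dft_periodogram_oracle(v)
    freq <- seq_along(P) * rate / n
    expect_equal(f$total_power, sum(P), tolerance = 1e-9)
    expect_equal(f$dominant_frequency, freq[which.max(P)], tolerance = 1e-9)
    idx <- findInterval(freq, c(0, 0.2, 0.8, 1.6, 2.4, 4),
                        rightmost.closed = TRUE)
    expect_equal(f$power_low_rel, sum(P[idx == 2]) / sum(P),
                 tolerance = 1e-9)
    expect_equal(f$power_very_high_rel, sum(P[idx == 5]) / sum(P),
                 tolerance = 1e-9)
  }
})

test_that("shape features respect symmetry, reflection parity and peaks", {
  sym <- make_window(c(1, 2, 2, 3, 3, 3, 4, 4, 5))
  expect_equal(shape_features(sym)$skewness, 0, tolerance = 1e-12)

  set.seed(7)
  w <- make_window(cumsum(rnorm(200)))
  f <- shape_features(w)
  fr <- shape_features(make_window(100 - w$values, times = w$times))
  expect_equal(fr$skewness, -f$skewness, tolerance = 1e-10)
  expect_equal(fr$kurtosis, f$kurtosis, tolerance = 1e-10)

  # single prominent triangular pulse on a gently sloped baseline
  base <- seq(0, 0.5, length.out = 41)
  pulse <- base
  pulse[19:23] <- pulse[19:23] + c(2, 4, 6, 4, 2)
  fp <- shape_features(make_window(pulse))
  expect_equal(fp$peak_count, 1)
  expect_equal(fp$peak_rate, 1 / 40)

  # constant window: moments missing, peaks zero
  f0 <- shape_features(make_window(rep(2, 10)))
  expect_true(is.na(f0$skewness) && is.na(f0$kurtosis))
  expect_equal(f0$peak_count, 0)
})

test_that("peak prominence matches a naive scan oracle", {
  naive_prom <- function(v, peaks) vapply(peaks, function(p) {
    left <- v[p]; j <- p - 1L
    while (j >= 1L && v[j] <= v[p]) {
      if (v[j] < left) left <- v[j]; j <- j - 1L
    }
    right <- v[p]; j <- p + 1L
    while (j <= length(v) && v[j] <= v[p]) {
      if (v[j] < right) right <- v[j]; j <- j + 1L
    }
    v[p] - max(left, right)
  }, numeric(1))
  set.seed(11)
  for (rep in 1:10) {
    v <- round(cumsum(rnorm(400)), 2)  # rounding forces ties
    mid <- 2:(length(v) - 1)
    peaks <- mid[v[mid] > v[mid - 1] & v[mid] > v[mid + 1]]
    expect_equal(plantmood:::peak_prominences(v, peaks), naive_prom(v, peaks))
  }
})

test_that("the canonical grid has twenty features and sane missing policy", {
  expect_length(plant_feature_names(), 20)
  expect_length(plant_feature_names(extras = TRUE), 22)

  set.seed(3)
  w <- make_window(cumsum(rnorm(240)), times = seq(0, 239) / 4)
  f <- extract_features(w, sample_rate = 4)
  expect_named(f, plant_feature_names(extras = TRUE))
  bands <- f[c("power_very_low_rel", "power_low_rel", "power_mid_rel",
               "power_high_rel", "power_very_high_rel")]
  expect_equal(sum(bands), 1, tolerance = 1e-9)

  fc <- extract_features(make_window(rep(4, 20)), sample_rate = 1)
  expect_equal(unname(fc["mean"]), 4)
  expect_equal(unname(fc["rms"]), 4)
  expect_equal(unname(fc[c("std", "range", "iqr", "jitter")]), rep(0, 4))
  expect_true(all(is.na(fc[c("power_low_rel", "dominant_frequency",
                             "skewness", "kurtosis")])))
})

test_that("features obey scale and reflection invariances", {
  set.seed(23)
  a <- 2.5
  C <- 400
  scale_inv <- c("cv", "trend_r2", "direction_change_rate", "skewness",
                 "kurtosis", "power_very_low_rel", "power_low_rel",
                 "power_mid_rel", "power_high_rel", "power_very_high_rel")
  scale_lin <- c("mean", "std", "range", "iqr", "rms", "trend_slope",
                 "jitter", "mean_abs_change")
  refl_inv <- c("std", "range", "iqr", "trend_r2", "total_power",
                "power_very_low_rel",
                "power_low_rel", "power_mid_rel", "power_high_rel",
                "power_very_high_rel", "direction_change_rate", "jitter",
                "mean_abs_change", "kurtosis")
  refl_neg <- c("trend_slope", "skewness")

  for (rep in 1:5) {
    tt <- sort(runif(300, 0, 60))
    v <- 50 + cumsum(rnorm(300)) + 3 * sin(2 * pi * tt / 11)
    w <- make_window(v, times = tt)
    f <- extract_features(w, sample_rate = 4)
    fs <- extract_features(make_window(a * v, times = tt), sample_rate = 4)
    fr <- extract_features(make_window(C - v, times = tt), sample_rate = 4)

    expect_equal(fs[scale_inv], f[scale_inv], tolerance = 1e-9)
    expect_equal(fs[scale_lin], a * f[scale_lin], tolerance = 1e-9)
    expect_equal(unname(fs["total_power"]), unname(a^2 * f["total_power"]),
                 tolerance = 1e-9)
    expect_equal(fr[refl_inv], f[refl_inv], tolerance = 1e-9)
    expect_equal(unname(fr[refl_neg]), unname(-f[refl_neg]),
                 tolerance = 1e-9)
    expect_equal(unname(fr["mean"]), unname(C - f["mean"]),
                 tolerance = 1e-9)
  }
})
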