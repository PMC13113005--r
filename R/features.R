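#' Canonical plant feature names
#'
#' The twenty canonical window features: six statistical (mean, std, range,
#' IQR, CV, RMS), five temporal (trend slope and R^2, direction change rate,
#' jitter, mean absolute change), seven spectral (total power, dominant
#' frequency, and relative power in five sub-bands), and two moment-shape
#' features (skewness, excess kurtosis). Peak count and peak rate are
#' computed as extras but sit outside the default screening grid.
#'
#' @param extras include `peak_count` and `peak_rate`.
#' @return Character vector of feature names.
#' @export
plant_feature_names <- function(extras = FALSE) {
  canon <- c(
    "mean", "std", "range", "iqr", "cv", "rms",
    "trend_slope", "trend_r2", "direction_change_rate", "jitter",
    "mean_abs_change",
    "total_power", "dominant_frequency",
    "power_very_low_rel", "power_low_rel", "power_mid_rel",
    "power_high_rel", "power_very_high_rel",
    "skewness", "kurtosis"
  )
  if (extras) c(canon, "peak_count", "peak_rate") else canon
}

#' Slice the voltage window preceding a time point
#'
#' Returns the samples in the half-open interval `(end_time - width,
#' end_time]`. A window containing fewer than `min_samples` samples is a
#' rejection (the matching criterion), signalled by returning `NULL` rather
#' than an error so that callers can log and continue.
#'
#' @param stream tibble with `timestamp` (sorted, epoch seconds) and `mv`.
#' @param end_time window end in epoch seconds (typically a mood reading
#'   time).
#' @param width window width in seconds.
#' @param min_samples matching criterion.
#' @return A `voltage_window` (list with `times`, `values`, `end_time`,
#'   `width`, `n`) or `NULL` on rejection.
#' @export
slice_window <- function(stream, end_time, width = 300, min_samples = 10) {
  stopifnot(width > 0)
  ts <- stream$timestamp
  if (length(ts) == 0) return(NULL)
  lo <- findInterval(end_time - width, ts) + 1L
  hi <- findInterval(end_time, ts)
  n <- hi - lo + 1L
  if (n < min_samples) return(NULL)
  structure(
    list(times = ts[lo:hi], values = stream$mv[lo:hi],
         end_time = end_time, width = width, n = n),
    class = "voltage_window"
  )
}

#' Statistical window features
#'
#' Mean, sample standard deviation (n - 1), range, IQR (linear-interpolation
#' percentiles), coefficient of variation (std / signed mean; `NA` when the
#' mean is exactly zero), and RMS.
#'
#' @param window a `voltage_window`.
#' @return Named list of six features.
#' @export
statistical_features <- function(window) {
  v <- window$values
  stopifnot(length(v) >= 2)
  m <- mean(v)
  s <- sd(v)
  q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  list(
    mean = m,
    std = s,
    range = max(v) - min(v),
    iqr = q[2] - q[1],
    cv = if (m == 0) NA_real_ else s / m,
    rms = sqrt(mean(v^2))
  )
}

#' Temporal window features
#'
#' Trend slope and R^2 from an OLS fit of value on time, direction change
#' rate (sign changes of consecutive non-zero first differences per second of
#' window span), jitter (sample SD of successive differences) and mean
#' absolute successive change. A constant window yields zeros for all five
#' (trend R^2 is defined as 0 when the value variance is 0).
#'
#' @param window a `voltage_window`.
#' @return Named list of five features, or `NULL` when the window's time span
#'   is zero.
#' @export
temporal_features <- function(window) {
  v <- window$values
  stopifnot(length(v) >= 3)
  tt <- window$times - window$times[1]
  dur <- tt[length(tt)]
  if (dur <= 0) return(NULL)
  if (var(v) == 0) {
    return(list(trend_slope = 0, trend_r2 = 0, direction_change_rate = 0,
                jitter = 0, mean_abs_change = 0))
  }
  slope <- cov(tt, v) / var(tt)
  r2 <- cor(tt, v)^2
  d <- diff(v)
  sgn <- sign(d)
  sgn <- sgn[sgn != 0]
  list(
    trend_slope = slope,
    trend_r2 = r2,
    direction_change_rate =
      if (length(sgn) < 2) 0 else sum(diff(sgn) != 0) / dur,
    jitter = if (length(d) >= 2) sd(d) else 0,
    mean_abs_change = mean(abs(d))
  )
}

# Linearly resample a window onto a uniform grid at (at least) the nominal
# rate. The grid size is rounded up to a 5-smooth number so the FFT never
# falls back to a slow large-prime transform.
uniform_resample <- function(window, sample_rate) {
  tt <- window$times - window$times[1]
  span <- tt[length(tt)]
  m <- max(8L, round(span * sample_rate) + 1L)
  m <- stats::nextn(m, factors = c(2, 3, 5))
  grid <- seq(0, span, length.out = m)
  list(x = approx(tt, window$values, xout = grid, ties = "ordered")$y,
       dt = span / (m - 1))
}

#' Spectral window features
#'
#' The window is linearly resampled onto a uniform grid at the nominal rate,
#' mean-removed, and transformed with the FFT. The periodogram ordinate at
#' frequency k/(m dt) is `|X_k|^2 / m` for `k = 1 .. floor(m/2)` (the
#' zero-frequency term is excluded throughout). Total power is the sum of all
#' ordinates; the dominant frequency is the ordinate-maximising frequency;
#' relative band powers divide the power inside each configured band by the
#' total. Band intervals are left-closed, and the final edge is closed so a
#' component exactly at the Nyquist frequency is counted.
#'
#' @param window a `voltage_window`.
#' @param band_edges 6 increasing edges in Hz bounding the 5 bands.
#' @param sample_rate nominal sampling rate in Hz for the uniform grid.
#' @return Named list: `total_power`, `dominant_frequency`, and the five
#'   relative band powers. A constant window has `total_power` 0 and missing
#'   dominant frequency and band powers.
#' @export
spectral_features <- function(window, band_edges = c(0, 0.5, 2, 8, 20, 60),
                              sample_rate = 120) {
  stopifnot(window$n >= 8, length(band_edges) == 6,
            all(diff(band_edges) > 0))
  rs <- uniform_resample(window, sample_rate)
  x <- rs$x - mean(rs$x)
  band_names <- c("power_very_low_rel", "power_low_rel", "power_mid_rel",
                  "power_high_rel", "power_very_high_rel")
  m <- length(x)
  nf <- floor(m / 2)
  if (all(x == 0)) {
    out <- c(list(total_power = 0, dominant_frequency = NA_real_),
             stats::setNames(rep(list(NA_real_), 5), band_names))
    return(out)
  }
  X <- fft(x)
  P <- Mod(X[2:(nf + 1)])^2 / m
  freq <- (1:nf) / (m * rs$dt)
  total <- sum(P)
  band_idx <- findInterval(freq, band_edges, rightmost.closed = TRUE)
  rel <- vapply(1:5, function(i) sum(P[band_idx == i]) / total, numeric(1))
  c(list(total_power = total, dominant_frequency = freq[which.max(P)]),
    stats::setNames(as.list(rel), band_names))
}

# Index of the nearest strictly greater value before (dir = -1) or after
# (dir = +1) each position, 0 / n + 1 when none exists. Monotone stack, O(n).
nearest_greater <- function(v, dir) {
  n <- length(v)
  idx <- if (dir < 0) seq_len(n) else rev(seq_len(n))
  out <- integer(n)
  stack <- integer(n)
  top <- 0L
  for (i in idx) {
    while (top > 0L && v[stack[top]] <= v[i]) top <- top - 1L
    out[i] <- if (top > 0L) stack[top] else if (dir < 0) 0L else n + 1L
    top <- top + 1L
    stack[top] <- i
  }
  out
}

# Sparse table for O(1) range-minimum queries (vectorised over queries).
rmq_build <- function(v) {
  n <- length(v)
  K <- max(1L, floor(log2(n)) + 1L)
  tab <- matrix(NA_real_, n, K)
  tab[, 1] <- v
  j <- 1L
  while (2^j <= n) {
    half <- 2^(j - 1L)
    i <- 1:(n - 2^j + 1L)
    tab[i, j + 1L] <- pmin(tab[i, j], tab[i + half, j])
    j <- j + 1L
  }
  tab
}

rmq_query <- function(tab, l, r) {
  k <- floor(log2(r - l + 1))
  pmin(tab[cbind(l, k + 1)], tab[cbind(r - 2^k + 1, k + 1)])
}

# Prominence of each local maximum: height above the higher of the two
# minima separating it from strictly higher ground (or the window edge).
peak_prominences <- function(v, peaks) {
  if (length(peaks) == 0) return(numeric(0))
  n <- length(v)
  pge <- nearest_greater(v, -1L)[peaks]
  nge <- nearest_greater(v, +1L)[peaks]
  tab <- rmq_build(v)
  # A peak's neighbours are strictly lower, so both ranges are non-empty.
  left <- rmq_query(tab, pge + 1L, peaks - 1L)
  right <- rmq_query(tab, peaks + 1L, pmin(nge, n + 1L) - 1L)
  v[peaks] - pmax(left, right)
}

#' Shape window features
#'
#' Skewness (third standardised moment) and excess kurtosis (fourth
#' standardised moment minus 3), both with n-denominator moments; missing for
#' zero-variance windows. Peak count is the number of strict local maxima
#' with prominence at least half the window's sample SD; peak rate divides by
#' the window's time span.
#'
#' @param window a `voltage_window`.
#' @param prominence_frac prominence threshold as a fraction of the sample
#'   SD.
#' @param include_peaks compute the peak metrics (skip for speed when only
#'   the canonical grid is needed).
#' @return Named list: `skewness`, `kurtosis`, and (when requested)
#'   `peak_count`, `peak_rate`.
#' @export
shape_features <- function(window, prominence_frac = 0.5,
                           include_peaks = TRUE) {
  v <- window$values
  stopifnot(length(v) >= 4)
  n <- length(v)
  dev <- v - mean(v)
  m2 <- mean(dev^2)
  dur <- window$times[n] - window$times[1]
  if (m2 == 0) {
    out <- list(skewness = NA_real_, kurtosis = NA_real_,
                peak_count = 0, peak_rate = 0)
    return(if (include_peaks) out else out[c("skewness", "kurtosis")])
  }
  out <- list(
    skewness = mean(dev^3) / m2^1.5,
    kurtosis = mean(dev^4) / m2^2 - 3
  )
  if (include_peaks) {
    mid <- 2:(n - 1)
    peaks <- mid[v[mid] > v[mid - 1] & v[mid] > v[mid + 1]]
    if (length(peaks) > 0) {
      prom <- peak_prominences(v, peaks)
      peaks <- peaks[prom >= prominence_frac * sd(v)]
    }
    out$peak_count <- length(peaks)
    out$peak_rate <- if (dur > 0) length(peaks) / dur else 0
  }
  out
}

#' Extract the full plant feature vector from a window
#'
#' Assembles the twenty canonical features (plus the two peak extras unless
#' disabled). Failures in any feature family are recorded as missing values
#' in the affected fields rather than aborting, so a study run never stops on
#' a degenerate window.
#'
#' @param window a `voltage_window` accepted by [slice_window()].
#' @param band_edges spectral band edges in Hz.
#' @param sample_rate nominal sampling rate in Hz.
#' @param include_peaks also compute `peak_count` / `peak_rate`.
#' @return Named numeric vector of features.
#' @export
extract_features <- function(window, band_edges = c(0, 0.5, 2, 8, 20, 60),
                             sample_rate = 120, include_peaks = TRUE) {
  names <- plant_feature_names(extras = include_peaks)
  out <- stats::setNames(rep(NA_real_, length(names)), names)
  fill <- function(vals) {
    if (!is.null(vals)) out[names(vals)] <<- unlist(vals)
  }
  try(fill(statistical_features(window)), silent = TRUE)
  try(fill(temporal_features(window)), silent = TRUE)
  try(fill(spectral_features(window, band_edges, sample_rate)), silent = TRUE)
  try(fill(shape_features(window, include_peaks = include_peaks)),
      silent = TRUE)
  out
}
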