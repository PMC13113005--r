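#' Configuration for a synthetic plant/mood study
#'
#' Builds the parameter set for the synthetic-study generator. The generator
#' emulates the statistical structure the downstream analysis assumes: a
#' positive per-day voltage baseline that differs between two electrode
#' "eras", circadian intra-day drift calibrated to a target share of signal
#' variance, AR(1)-correlated measurement noise, an era-dependent polarity
#' (reflection about a mid-rail constant), a latent within-day stress process
#' that couples into the signal mean and suppresses relative noise
#' variability, and sparse 0-2 mood readings at irregular 10-20 minute
#' intervals with dropouts.
#'
#' Days are indexed from 0; days with index `>= era_boundary_day` belong to
#' era "B". Per-day baselines are drawn uniformly from the configured era
#' range (or taken verbatim when an era entry has length 1). When
#' `gain_scaled` is `TRUE`, all signal components riding on the baseline
#' (circadian drift, stress coupling, noise) are multiplied by the day's
#' electrode gain `baseline / gain_reference`, reflecting how electrode
#' placement scales the whole differential measurement, not just its offset.
#'
#' @param n_days number of recording days.
#' @param day_length hours of recording per day.
#' @param sample_rate plant sampling rate in Hz.
#' @param start_hour local hour at which each day's recording starts.
#' @param start_date calendar date of day 0 (`Date` or string).
#' @param era_boundary_day first day index belonging to era B.
#' @param era_baseline named list `A`/`B`; each entry a single baseline in mV
#'   or a length-2 range from which per-day baselines are drawn.
#' @param era_polarity named vector `A`/`B` with values +1 or -1. Polarity -1
#'   reflects each sample's deviation from the day baseline about `midrail`.
#' @param midrail reflection offset C in mV used when polarity is -1; the
#'   reflected stream is `C + baseline - (v - baseline)`.
#' @param circadian_frac target share of within-day signal variance carried by
#'   the circadian component (with coupling off); used to derive the circadian
#'   amplitude when `circadian_amplitude` is `NULL`.
#' @param circadian_amplitude explicit circadian amplitude in mV, overriding
#'   `circadian_frac`.
#' @param circadian_peak_hour local hour at which the circadian component
#'   peaks.
#' @param noise_sd stationary standard deviation of the AR(1) noise in mV
#'   (per unit gain).
#' @param ar_coefficient AR(1) coefficient in (-1, 1); when `NULL` it is
#'   derived from `noise_corr_time` at the configured sample rate.
#' @param noise_corr_time noise autocorrelation time in seconds; used only
#'   when `ar_coefficient` is `NULL`.
#' @param alpha_mean stress-to-mean coupling in mV per unit stress (per unit
#'   gain).
#' @param beta_cv fractional suppression of the noise SD per unit stress, in
#'   `[0, 1)`; the noise is scaled by `1 - beta_cv * stress / 2`.
#' @param gain_scaled logical; scale circadian, coupling and noise by the
#'   day's electrode gain.
#' @param gain_reference baseline in mV corresponding to gain 1. The default
#'   (300 mV) keeps within-day deviations a modest fraction of the baseline,
#'   as in the motivating recordings, so relative-dispersion features are not
#'   dominated by mean shifts.
#' @param stress_walk_sd per-minute step SD of the latent stress random walk.
#' @param stress_start latent stress at the start of each day, before the
#'   day offset is added.
#' @param day_stress_offsets optional per-day additive offsets on latent
#'   stress (length `n_days`); drawn from `N(0, day_offset_sd)` when `NULL`.
#' @param day_offset_sd SD of the per-day latent stress offsets.
#' @param day_baselines optional per-day baselines in mV overriding the era
#'   ranges.
#' @param mood_noise_sd SD of the reading noise added to each mood score.
#' @param happiness_coupling,depression_coupling slope of happiness and
#'   depression on (latent stress - 1).
#' @param happiness_base,depression_base mean level of happiness/depression at
#'   latent stress 1.
#' @param reading_interval length-2 range (minutes) from which successive
#'   reading gaps are drawn uniformly.
#' @param dropout_prob probability that a scheduled reading is missed.
#' @param rolling_k trailing window (number of readings) for rolling mood
#'   variables.
#' @param window_width plant feature window width in seconds.
#' @param min_samples matching criterion: minimum plant samples per window.
#' @param band_edges spectral band edges in Hz (6 values bounding 5 bands).
#' @param seed integer seed controlling all randomness of the study.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_days = 10,
                       day_length = 4,
                       sample_rate = 120,
                       start_hour = 9,
                       start_date = as.Date("2026-02-20"),
                       era_boundary_day = 5,
                       era_baseline = list(A = c(25, 200), B = c(30, 1800)),
                       era_polarity = c(A = 1, B = -1),
                       midrail = 0,
                       circadian_frac = 0.14,
                       circadian_amplitude = NULL,
                       circadian_peak_hour = 14,
                       noise_sd = 8,
                       ar_coefficient = NULL,
                       noise_corr_time = 2,
                       alpha_mean = 14,
                       beta_cv = 0.15,
                       gain_scaled = TRUE,
                       gain_reference = 300,
                       stress_walk_sd = 0.04,
                       stress_start = 1,
                       day_stress_offsets = NULL,
                       day_offset_sd = 0.3,
                       day_baselines = NULL,
                       mood_noise_sd = 0.2,
                       happiness_coupling = -0.5,
                       depression_coupling = 0.5,
                       happiness_base = 1.2,
                       depression_base = 0.6,
                       reading_interval = c(10, 20),
                       dropout_prob = 0.2,
                       rolling_k = 3,
                       window_width = 300,
                       min_samples = 10,
                       band_edges = c(0, 0.5, 2, 8, 20, 60),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  if (is.null(cfg$ar_coefficient)) {
    cfg$ar_coefficient <- exp(-1 / (sample_rate * noise_corr_time))
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c("n_days", "day_length", "sample_rate", "start_hour",
                  "noise_sd", "alpha_mean", "beta_cv", "dropout_prob",
                  "midrail", "stress_walk_sd", "mood_noise_sd",
                  "ar_coefficient")
  for (f in num_fields) {
    if (!all(is.finite(cfg[[f]]))) {
      stop("sim_config field '", f, "' must be finite", call. = FALSE)
    }
  }
  stopifnot(
    cfg$sample_rate > 0,
    cfg$n_days >= 1,
    cfg$day_length > 0,
    cfg$start_hour + cfg$day_length <= 24,
    cfg$dropout_prob >= 0, cfg$dropout_prob < 1,
    cfg$beta_cv >= 0, cfg$beta_cv < 1,
    abs(cfg$ar_coefficient) < 1,
    all(cfg$era_polarity %in% c(-1, 1)),
    all(unlist(cfg$era_baseline) > 0),
    length(cfg$reading_interval) == 2,
    cfg$reading_interval[1] > 0,
    cfg$reading_interval[2] >= cfg$reading_interval[1]
  )
  invisible(cfg)
}

#' Electrode era of a day index
#'
#' @param cfg a [sim_config()].
#' @param day 0-based day index (vectorised).
#' @return "A" or "B" per day.
#' @export
era_for_day <- function(cfg, day) {
  ifelse(day >= cfg$era_boundary_day, "B", "A")
}

day_start_epoch <- function(cfg, day) {
  as.numeric(cfg$start_date) * 86400 + day * 86400 + cfg$start_hour * 3600
}

# Unit-amplitude circadian shape at given epoch timestamps.
circadian_unit <- function(cfg, timestamps) {
  hod <- (timestamps / 3600) %% 24
  cos(2 * pi * (hod - cfg$circadian_peak_hour) / 24)
}

#' Circadian amplitude implied by the configured variance fraction
#'
#' With stress coupling off, the generated signal is baseline + circadian +
#' AR(1) noise (per unit gain). The amplitude is chosen so that the circadian
#' component contributes `circadian_frac` of the within-day signal variance:
#' `var(circ) / (var(circ) + noise_sd^2) = circadian_frac`, where `var(circ)`
#' is evaluated over one day's recording grid (the recording covers only part
#' of the 24 h cycle, so the variance of the windowed sinusoid is computed
#' numerically, not assumed to be half the squared amplitude).
#'
#' @param cfg a [sim_config()].
#' @return Amplitude in mV (per unit gain).
#' @export
circadian_amplitude_for <- function(cfg) {
  if (!is.null(cfg$circadian_amplitude)) return(cfg$circadian_amplitude)
  f <- cfg$circadian_frac
  if (is.null(f) || f <= 0) return(0)
  grid <- day_start_epoch(cfg, 0) +
    seq(0, cfg$day_length * 3600, length.out = 4096)
  v_unit <- var(circadian_unit(cfg, grid))
  sqrt(f / (1 - f) * cfg$noise_sd^2 / v_unit)
}

day_baseline <- function(cfg, day) {
  if (!is.null(cfg$day_baselines)) return(cfg$day_baselines[day + 1])
  b <- cfg$era_baseline[[era_for_day(cfg, day)]]
  if (length(b) == 1) b else runif(1, b[1], b[2])
}

#' Simulate one day's plant voltage stream
#'
#' Generates `day_length * 3600 * sample_rate` samples at uniform spacing.
#' Per unit gain the signal is `baseline + circadian(t) + alpha_mean *
#' stress(t) + noise(t) * (1 - beta_cv * stress(t) / 2)`, where the noise is a
#' stationary AR(1) process with marginal SD `noise_sd`. When the day's era
#' has polarity -1 the deviation from baseline is reflected about the
#' configured mid-rail: `v -> midrail + baseline - (v - baseline)`.
#'
#' @param cfg a [sim_config()].
#' @param day 0-based day index.
#' @param stress latent stress: either a data frame with columns `timestamp`
#'   (epoch seconds) and `stress` (interpolated to sample resolution), or a
#'   single number used as a constant level.
#' @param seed integer seed for this day's noise and baseline draw.
#' @return A tibble with columns `timestamp` (epoch seconds) and `mv`.
#' @export
simulate_plant_stream <- function(cfg, day, stress, seed = cfg$seed) {
  validate_sim_config(cfg)
  stopifnot(day >= 0, day < cfg$n_days)
  set.seed(seed)
  n <- round(cfg$day_length * 3600 * cfg$sample_rate)
  t0 <- day_start_epoch(cfg, day)
  ts <- t0 + (seq_len(n) - 1) / cfg$sample_rate

  if (is.numeric(stress) && length(stress) == 1) {
    s <- rep(stress, n)
  } else {
    if (min(stress$timestamp) > ts[1] || max(stress$timestamp) < ts[n]) {
      stop("latent stress series does not cover the day at sample resolution")
    }
    s <- approx(stress$timestamp, stress$stress, xout = ts, rule = 2)$y
  }

  b <- day_baseline(cfg, day)
  gain <- if (cfg$gain_scaled) b / cfg$gain_reference else 1
  amp <- circadian_amplitude_for(cfg)
  circ <- amp * circadian_unit(cfg, ts)

  a <- cfg$ar_coefficient
  innov <- rnorm(n, 0, cfg$noise_sd * sqrt(1 - a^2))
  x0 <- rnorm(1, 0, cfg$noise_sd)
  noise <- as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
  noise <- noise * (1 - cfg$beta_cv * s / 2)

  v <- b + gain * (circ + cfg$alpha_mean * s + noise)
  if (cfg$era_polarity[[era_for_day(cfg, day)]] == -1) {
    v <- cfg$midrail + b - (v - b)
  }
  tibble::tibble(timestamp = ts, mv = v)
}

#' Simulate one day's latent stress and mood readings
#'
#' Latent stress is a Gaussian random walk at 1-minute resolution, reflected
#' into `[0, 2]` after adding the day's stress offset. Readings are scheduled
#' at successive gaps drawn uniformly from `reading_interval` minutes, each
#' independently missed with probability `dropout_prob`. Reading-level
#' happiness and depression are clipped noisy linear transforms of latent
#' stress with configurable sign and magnitude.
#'
#' @param cfg a [sim_config()].
#' @param day 0-based day index.
#' @param seed integer seed for this day's mood randomness.
#' @return A list with `readings` (tibble: `timestamp`, `happiness`,
#'   `stress`, `depression`) and `latent` (tibble: `timestamp`, `stress` at
#'   1-minute resolution).
#' @export
simulate_mood_series <- function(cfg, day, seed = cfg$seed) {
  validate_sim_config(cfg)
  stopifnot(day >= 0, day < cfg$n_days)
  set.seed(seed)
  t0 <- day_start_epoch(cfg, day)
  mins <- seq(0, cfg$day_length * 60)
  offset <- if (!is.null(cfg$day_stress_offsets)) {
    cfg$day_stress_offsets[day + 1]
  } else 0

  steps <- rnorm(length(mins) - 1, 0, cfg$stress_walk_sd)
  walk <- cfg$stress_start + c(0, cumsum(steps)) + offset
  latent <- tibble::tibble(timestamp = t0 + mins * 60,
                           stress = fold_range(walk, 0, 2))

  # Schedule readings: gap, reading, gap, reading ... until the day ends.
  max_n <- ceiling(cfg$day_length * 60 / cfg$reading_interval[1]) + 1
  gaps <- runif(max_n, cfg$reading_interval[1], cfg$reading_interval[2])
  sched <- cumsum(gaps)
  sched <- sched[sched <= cfg$day_length * 60]
  kept <- runif(length(sched)) >= cfg$dropout_prob
  times <- t0 + sched[kept] * 60

  n <- length(times)
  s_latent <- approx(latent$timestamp, latent$stress, xout = times, rule = 2)$y
  stress_read <- clip_range(s_latent + rnorm(n, 0, cfg$mood_noise_sd))
  happiness <- clip_range(cfg$happiness_base +
                            cfg$happiness_coupling * (s_latent - 1) +
                            rnorm(n, 0, cfg$mood_noise_sd))
  depression <- clip_range(cfg$depression_base +
                             cfg$depression_coupling * (s_latent - 1) +
                             rnorm(n, 0, cfg$mood_noise_sd))
  list(
    readings = tibble::tibble(timestamp = times, happiness = happiness,
                              stress = stress_read, depression = depression),
    latent = latent
  )
}

#' Simulate a full multi-day study with ground truth
#'
#' Draws per-day stress offsets and baselines, then simulates each day's
#' latent stress, mood readings and plant stream. All randomness is derived
#' deterministically from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `plant_study` with elements `stream` (one tibble
#'   covering all days), `readings`, `era_map` (tibble: `day` as `Date`,
#'   `era`), and `truth` (latent stress, per-day offsets and baselines,
#'   configured couplings and polarities, and the config itself).
#' @export
simulate_study <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  days <- seq_len(cfg$n_days) - 1
  offsets <- cfg$day_stress_offsets %||% rnorm(cfg$n_days, 0, cfg$day_offset_sd)
  baselines <- cfg$day_baselines %||% vapply(days, function(d) {
    b <- cfg$era_baseline[[era_for_day(cfg, d)]]
    if (length(b) == 1) b else runif(1, b[1], b[2])
  }, numeric(1))
  cfg_run <- cfg
  cfg_run$day_stress_offsets <- offsets
  cfg_run$day_baselines <- baselines

  streams <- vector("list", cfg$n_days)
  readings <- vector("list", cfg$n_days)
  latents <- vector("list", cfg$n_days)
  for (d in days) {
    mood <- simulate_mood_series(cfg_run, d, seed = cfg$seed + 10007L * (d + 1L))
    streams[[d + 1]] <- simulate_plant_stream(cfg_run, d, mood$latent,
                                              seed = cfg$seed + 20011L * (d + 1L))
    readings[[d + 1]] <- mood$readings
    latents[[d + 1]] <- mood$latent
  }
  era_map <- tibble::tibble(
    day = cfg$start_date + days,
    era = era_for_day(cfg, days)
  )
  structure(list(
    stream = dplyr::bind_rows(streams),
    readings = dplyr::bind_rows(readings),
    era_map = era_map,
    truth = list(
      latent_stress = dplyr::bind_rows(latents),
      alpha_mean = cfg$alpha_mean,
      beta_cv = cfg$beta_cv,
      day_stress_offsets = offsets,
      day_baselines = baselines,
      era_polarity = cfg$era_polarity,
      config = cfg_run
    )
  ), class = "plant_study")
}

#' @export
print.plant_study <- function(x, ...) {
  cat("<plant_study>\n")
  cat("  days:      ", nrow(x$era_map), " (",
      sum(x$era_map$era == "A"), " era A, ",
      sum(x$era_map$era == "B"), " era B)\n", sep = "")
  cat("  samples:   ", nrow(x$stream), "\n", sep = "")
  cat("  readings:  ", nrow(x$readings), "\n", sep = "")
  invisible(x)
}

#' Confounded-polarity demonstration configuration
#'
#' A study configuration that pairs an electrode polarity flip with day-level
#' confounding of stress and plant baseline: era A has low baselines, high
#' day-stress offsets and polarity +1; era B has high baselines, low
#' day-stress offsets and polarity -1, with a negative underlying
#' stress-to-mean coupling. Pooled correlations for the window mean are then
#' dominated by the day-level confound while the day-demeaned (fixed-effects)
#' estimate takes the sign of the gain-dominant era, producing a pooled-vs-FE
#' sign reversal (Simpson's paradox); the CV keeps a stable negative
#' association in both eras and both analyses. Used by the era diagnostics
#' and acceptance tests.
#'
#' @param seed integer seed.
#' @param sample_rate plant sampling rate in Hz (reduced by default: window
#'   statistics, not sample counts, carry the effect).
#' @param ... further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
simpson_config <- function(seed = 1L, sample_rate = 4, ...) {
  sim_config(
    seed = seed, sample_rate = sample_rate,
    alpha_mean = -30, beta_cv = 0.6, gain_reference = 300,
    era_polarity = c(A = 1, B = -1),
    era_baseline = list(A = c(25, 200), B = c(1200, 1800)),
    day_stress_offsets = c(rep(0.4, 5), rep(-0.4, 5)),
    ...
  )
}
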