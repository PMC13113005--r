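#' Era map from a boundary date
#'
#' @param days vector of `Date`s covered by the study.
#' @param boundary_date first date belonging to era B.
#' @return Tibble with `day` and `era` columns.
#' @export
era_map_from_boundary <- function(days, boundary_date) {
  days <- sort(unique(as.Date(days)))
  tibble::tibble(day = days,
                 era = ifelse(days >= as.Date(boundary_date), "B", "A"))
}

normalise_era_map <- function(era_map) {
  if (is.character(era_map) && !is.null(names(era_map))) {
    era_map <- tibble::tibble(day = as.Date(names(era_map)),
                              era = unname(era_map))
  }
  stopifnot(all(c("day", "era") %in% names(era_map)))
  era_map$day <- as.Date(era_map$day)
  era_map
}

#' Pair mood readings with their preceding plant windows
#'
#' For each mood reading, extracts the plant feature vector from the
#' `window_width`-second voltage window ending exactly at the reading's
#' timestamp (optionally shifted by `window_offset` seconds for lagged
#' analyses). Readings whose window contains fewer than `min_samples`
#' samples are rejected and logged, not errors. Each observation is labelled
#' with its local calendar day and electrode era.
#'
#' @param stream voltage tibble (`timestamp`, `mv`), sorted by time.
#' @param readings mood tibble (`timestamp`, `happiness`, `stress`,
#'   `depression`).
#' @param era_map tibble with `day` (`Date`) and `era`, or a named character
#'   vector keyed by date; must cover every reading day.
#' @param window_width window width in seconds.
#' @param min_samples matching criterion (minimum samples per window).
#' @param band_edges spectral band edges in Hz.
#' @param rolling_k trailing rolling window for mood variables, in readings.
#' @param sample_rate nominal plant sampling rate in Hz; inferred from the
#'   median sampling interval when `NULL`.
#' @param tz_offset seconds added to timestamps before taking the calendar
#'   date (single-site studies with a known UTC offset).
#' @param window_offset seconds added to each window end time (0 for the
#'   standard analysis; used by [lagged_screen()]).
#' @param include_peaks compute the peak-count extras.
#' @param saturation_rail optional rail voltage in mV; windows with more than
#'   `saturation_frac` of samples within `saturation_tol` of the rail are
#'   rejected (off by default).
#' @param saturation_frac,saturation_tol saturation filter parameters.
#' @return A `paired_dataset`: list with `observations` (one row per accepted
#'   reading: `timestamp`, `day`, `era`, `window_n`, ten mood variables,
#'   plant features), `rejections` (timestamp, reason, samples found) and the
#'   normalised `era_map`.
#' @export
build_paired_dataset <- function(stream, readings, era_map,
                                 window_width = 300, min_samples = 10,
                                 band_edges = c(0, 0.5, 2, 8, 20, 60),
                                 rolling_k = 3, sample_rate = NULL,
                                 tz_offset = 0, window_offset = 0,
                                 include_peaks = TRUE,
                                 saturation_rail = NULL,
                                 saturation_frac = 0.5,
                                 saturation_tol = 1) {
  era_map <- normalise_era_map(era_map)
  if (is.null(sample_rate)) {
    dt <- median(diff(stream$timestamp))
    sample_rate <- 1 / dt
  }
  moods <- build_mood_variables(readings, k = rolling_k)
  n <- nrow(moods)
  fnames <- plant_feature_names(extras = include_peaks)

  days <- as.Date(floor((moods$timestamp + tz_offset) / 86400),
                  origin = "1970-01-01")
  missing_days <- setdiff(unique(days), era_map$day)
  if (length(missing_days) > 0) {
    stop("era_map does not cover day(s): ",
         paste(as.Date(missing_days, origin = "1970-01-01"), collapse = ", "))
  }
  eras <- era_map$era[match(days, era_map$day)]

  feats <- matrix(NA_real_, n, length(fnames),
                  dimnames = list(NULL, fnames))
  accepted <- logical(n)
  rej_reason <- character(n)
  rej_n <- integer(n)
  for (i in seq_len(n)) {
    w <- slice_window(stream, moods$timestamp[i] + window_offset,
                      width = window_width, min_samples = min_samples)
    if (is.null(w)) {
      rej_reason[i] <- "matching_criterion"
      wi <- slice_window(stream, moods$timestamp[i] + window_offset,
                         width = window_width, min_samples = 0)
      rej_n[i] <- if (is.null(wi)) 0L else wi$n
      next
    }
    if (!is.null(saturation_rail) &&
        mean(abs(w$values - saturation_rail) <= saturation_tol) >
          saturation_frac) {
      rej_reason[i] <- "saturated"
      rej_n[i] <- w$n
      next
    }
    accepted[i] <- TRUE
    rej_n[i] <- w$n
    feats[i, ] <- extract_features(w, band_edges = band_edges,
                                   sample_rate = sample_rate,
                                   include_peaks = include_peaks)
  }

  obs <- dplyr::bind_cols(
    tibble::tibble(timestamp = moods$timestamp, day = days, era = eras,
                   window_n = rej_n),
    moods[, mood_variable_names()],
    tibble::as_tibble(feats)
  )[accepted, ]
  rejections <- tibble::tibble(
    timestamp = moods$timestamp[!accepted],
    reason = rej_reason[!accepted],
    samples_found = rej_n[!accepted]
  )
  structure(list(observations = obs, rejections = rejections,
                 era_map = era_map),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("<paired_dataset>\n")
  cat("  observations:", nrow(x$observations), "across",
      length(unique(x$observations$day)), "days\n")
  cat("  rejections:  ", nrow(x$rejections), "\n")
  invisible(x)
}

# Accept a paired_dataset or a bare observation tibble.
as_observations <- function(x) {
  if (inherits(x, "paired_dataset")) return(x$observations)
  stopifnot(is.data.frame(x), "day" %in% names(x))
  x
}
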