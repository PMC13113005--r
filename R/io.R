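parse_timestamps <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  iso <- is.na(num) & !is.na(x) & nzchar(x)
  if (any(iso)) {
    p1 <- as.numeric(strptime(x[iso], "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    p2 <- as.numeric(strptime(x[iso], "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
    num[iso] <- ifelse(is.na(p1), p2, p1)
  }
  num
}

#' Read a plant voltage CSV
#'
#' Expects columns `timestamp` (epoch seconds or ISO-8601) and `mv`
#' (millivolts); other column names can be supplied through `col_map`. Rows
#' with unparseable values are dropped with a message; the read aborts when
#' more than `max_bad_frac` of rows are bad. Duplicate timestamps are
#' collapsed to their mean with a logged count, and the stream is returned
#' sorted.
#'
#' @param path CSV file path.
#' @param col_map named character vector mapping `timestamp` and `mv` to the
#'   file's column names.
#' @param max_bad_frac abort threshold on the fraction of unparseable rows.
#' @return Tibble with `timestamp` (epoch seconds) and `mv`.
#' @export
read_voltage_csv <- function(path,
                             col_map = c(timestamp = "timestamp", mv = "mv"),
                             max_bad_frac = 0.01) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) stop("empty voltage file: ", path)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0) {
    stop("voltage file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ts <- parse_timestamps(raw[[col_map[["timestamp"]]]])
  mv <- suppressWarnings(as.numeric(raw[[col_map[["mv"]]]]))
  bad <- !is.finite(ts) | !is.finite(mv)
  if (mean(bad) > max_bad_frac) {
    stop("voltage file ", path, ": ", sum(bad), "/", length(bad),
         " unparseable rows exceeds the ", max_bad_frac * 100, "% limit")
  }
  if (any(bad)) message("dropped ", sum(bad), " unparseable row(s) from ", path)
  ts <- ts[!bad]
  mv <- mv[!bad]
  if (anyDuplicated(ts)) {
    n_dup <- length(ts) - length(unique(ts))
    agg <- tapply(mv, ts, mean)
    ts <- as.numeric(names(agg))
    mv <- as.numeric(agg)
    message("collapsed ", n_dup, " duplicate timestamp(s) in ", path)
  }
  o <- order(ts)
  tibble::tibble(timestamp = ts[o], mv = mv[o])
}

#' Write a plant voltage CSV
#'
#' @param stream voltage tibble (`timestamp`, `mv`).
#' @param path output path; timestamps are written as epoch seconds.
#' @export
write_voltage_csv <- function(stream, path) {
  readr::write_csv(stream[, c("timestamp", "mv")], path)
  invisible(path)
}

#' Read a mood readings CSV
#'
#' Expects columns `timestamp`, `happiness`, `stress`, `depression`. Scores
#' outside `[0, 2]` are clipped with a warning; rows with non-numeric scores
#' or unparseable timestamps are dropped with a message.
#'
#' @param path CSV file path.
#' @return Tibble of readings sorted by time.
#' @export
read_mood_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("timestamp", "happiness", "stress", "depression")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("mood file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ts <- parse_timestamps(raw$timestamp)
  scores <- lapply(raw[c("happiness", "stress", "depression")],
                   function(x) suppressWarnings(as.numeric(x)))
  bad <- !is.finite(ts) | Reduce(`|`, lapply(scores, function(x) !is.finite(x)))
  if (any(bad)) message("dropped ", sum(bad), " unparseable row(s) from ", path)
  out <- tibble::tibble(timestamp = ts, happiness = scores$happiness,
                        stress = scores$stress,
                        depression = scores$depression)[!bad, ]
  out_of_range <- vapply(out[c("happiness", "stress", "depression")],
                         function(x) sum(x < 0 | x > 2), numeric(1))
  if (sum(out_of_range) > 0) {
    warning("clipped ", sum(out_of_range), " score(s) outside [0, 2] in ",
            path, call. = FALSE)
    out[c("happiness", "stress", "depression")] <-
      lapply(out[c("happiness", "stress", "depression")], clip_range)
  }
  out[order(out$timestamp), ]
}

#' Write a mood readings CSV
#'
#' @param readings mood tibble.
#' @param path output path.
#' @export
write_mood_csv <- function(readings, path) {
  readr::write_csv(
    readings[, c("timestamp", "happiness", "stress", "depression")], path)
  invisible(path)
}

#' Write / read the paired observation table
#'
#' One row per paired observation: day, era, window sample count, the ten
#' mood variables and the plant features.
#'
#' @param x a `paired_dataset` or observation tibble.
#' @param path TSV path.
#' @return `write_observations_tsv` returns the path; `read_observations_tsv`
#'   returns the observation tibble (usable wherever a `paired_dataset` is
#'   accepted).
#' @export
write_observations_tsv <- function(x, path) {
  readr::write_tsv(as_observations(x), path)
  invisible(path)
}

#' @rdname write_observations_tsv
#' @export
read_observations_tsv <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  obs$day <- as.Date(obs$day)
  obs
}

#' Write a screen report as TSV
#'
#' Columns mirror the screening table: mood, feature, level, n, r, pooled r,
#' delta of absolute coefficients, p, and the correction flags.
#'
#' @param report a `screen_report`.
#' @param path TSV path.
#' @export
write_screen_tsv <- function(report, path) {
  readr::write_tsv(report$results, path)
  invisible(path)
}

#' Write the per-day era table as TSV
#'
#' @param per_day output of [per_day_correlations()].
#' @param path TSV path.
#' @export
write_per_day_tsv <- function(per_day, path) {
  readr::write_tsv(per_day, path)
  invisible(path)
}

#' Write a lag profile as TSV
#'
#' @param profile output of [lagged_screen()].
#' @param path TSV path.
#' @export
write_lag_tsv <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Recognised keys are the arguments of [sim_config()] plus the analysis
#' thresholds (`window_width`, `min_samples`, `band_edges`, `rolling_k`,
#' `q`, `alpha`, `offsets`, `tz_offset`, `era_boundary_date`). Unknown keys
#' are rejected to catch typos.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c(names(formals(sim_config)),
               "q", "alpha", "offsets", "tz_offset", "era_boundary_date")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  cfg
}

#' Write the simulation ground truth as JSON
#'
#' Stores the configured couplings, per-day stress offsets and baselines and
#' the era polarities (not the full latent series) for recovery checks.
#'
#' @param truth the `truth` element of a [simulate_study()] result.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    alpha_mean = truth$alpha_mean,
    beta_cv = truth$beta_cv,
    day_stress_offsets = truth$day_stress_offsets,
    day_baselines = truth$day_baselines,
    era_polarity = as.list(truth$era_polarity),
    seed = truth$config$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
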