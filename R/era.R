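#' Per-day within-day correlations for one mood variable
#'
#' Computes the plain Pearson correlation between a mood variable and each
#' requested plant feature separately within every day. A day is evaluable
#' for a feature when it has at least `min_n` observations and both variables
#' have non-zero variance that day (variance above `var_tol`, to avoid
#' float-noise false positives); otherwise the coefficient is reported
#' missing.
#'
#' @param x a `paired_dataset` or observation tibble with `day` and `era`.
#' @param mood mood variable name.
#' @param features plant feature names.
#' @param min_n evaluability threshold on per-day observations.
#' @param var_tol absolute tolerance on the per-day variance.
#' @return Tibble with one row per day and feature: `day`, `era`, `n`,
#'   `feature`, `r`, `evaluable`.
#' @export
per_day_correlations <- function(x, mood = "stress_rolling",
                                 features = c("mean", "cv", "std"),
                                 min_n = 3, var_tol = 1e-12) {
  obs <- as_observations(x)
  parts <- split(obs, as.character(obs$day))
  rows <- lapply(parts, function(d) {
    lapply(features, function(fe) {
      xv <- d[[mood]]
      yv <- d[[fe]]
      ok <- is.finite(xv) & is.finite(yv)
      n <- sum(ok)
      evaluable <- n >= min_n &&
        n >= 2 && var(xv[ok]) > var_tol && var(yv[ok]) > var_tol
      tibble::tibble(
        day = d$day[1], era = d$era[1], n = nrow(d), feature = fe,
        r = if (evaluable) cor(xv[ok], yv[ok]) else NA_real_,
        evaluable = evaluable
      )
    })
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  out[order(out$day), ]
}

#' Sign consistency of per-day correlations across electrode eras
#'
#' Counts negative and positive evaluable per-day coefficients for one
#' feature, within each era and overall, and issues a verdict:
#' `"era-invariant"` when the majority sign agrees between the two eras
#' (the hallmark of a polarity-insensitive metric such as CV),
#' `"era-dependent"` when the majority signs differ (as for the mean of an
#' AC-coupled differential signal), and `"indeterminate"` when either era
#' has no evaluable day or its signs tie.
#'
#' @param per_day output of [per_day_correlations()].
#' @param feature feature to summarise.
#' @return An `era_summary`: list with per-era counts, overall counts, the
#'   majority signs and the verdict.
#' @export
sign_consistency <- function(per_day, feature) {
  d <- per_day[per_day$feature == feature & per_day$evaluable, ]
  stopifnot(nrow(d) >= 1)
  count_era <- function(rows) {
    c(negative = sum(rows$r < 0), positive = sum(rows$r > 0),
      evaluable = nrow(rows))
  }
  eras <- sort(unique(per_day$era))
  counts <- lapply(stats::setNames(eras, eras),
                   function(e) count_era(d[d$era == e, ]))
  majority <- vapply(counts, function(ct) {
    if (ct[["evaluable"]] == 0 || ct[["negative"]] == ct[["positive"]]) {
      NA_character_
    } else if (ct[["negative"]] > ct[["positive"]]) "negative" else "positive"
  }, character(1))
  verdict <- if (anyNA(majority)) {
    "indeterminate"
  } else if (length(unique(majority)) == 1) {
    "era-invariant"
  } else {
    "era-dependent"
  }
  structure(list(
    feature = feature,
    per_era = counts,
    overall = count_era(d),
    majority_sign = majority,
    verdict = verdict
  ), class = "era_summary")
}

#' @export
print.era_summary <- function(x, ...) {
  cat("<era_summary> ", x$feature, ": ", x$verdict, "\n", sep = "")
  for (e in names(x$per_era)) {
    ct <- x$per_era[[e]]
    cat("  era ", e, ": ", ct[["negative"]], " negative / ",
        ct[["positive"]], " positive of ", ct[["evaluable"]],
        " evaluable days\n", sep = "")
  }
  invisible(x)
}

#' Reflect a voltage stream about a constant
#'
#' Maps every sample `v` to `C - v`. A diagnostic utility for polarity
#' invariance checks: correlations against the window mean (and other odd
#' statistics such as trend slope and skewness) negate exactly under
#' reflection, while even statistics (std, range, IQR, total power, jitter,
#' mean absolute change, kurtosis) are unchanged.
#'
#' @param stream voltage tibble (`timestamp`, `mv`).
#' @param C reflection constant in mV.
#' @return The reflected stream.
#' @export
polarity_reflect <- function(stream, C) {
  stream$mv <- C - stream$mv
  stream
}
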