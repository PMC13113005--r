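#' Names of the ten mood variables
#'
#' Three raw scores (happiness, stress, depression), two composites
#' (negative affect, wellbeing) and the five trailing rolling averages.
#'
#' @return Character vector of length 10.
#' @export
mood_variable_names <- function() {
  base <- c("happiness", "stress", "depression", "negative_affect",
            "wellbeing")
  c(base, paste0(base, "_rolling"))
}

#' Composite mood scores
#'
#' Negative affect is the mean of stress and depression, keeping composites
#' on the same 0-2 scale as the raw scores; wellbeing is happiness minus
#' negative affect. Pearson correlations are invariant to the affine scaling
#' of these combinations.
#'
#' @param happiness,stress,depression scores on the 0-2 scale (vectorised).
#' @return A list with `negative_affect` and `wellbeing`.
#' @export
mood_composites <- function(happiness, stress, depression) {
  na <- (stress + depression) / 2
  list(negative_affect = na, wellbeing = happiness - na)
}

#' Trailing rolling mean
#'
#' Value at position i is the mean of the last `min(k, i)` values up to and
#' including i (an expanding window until k values are available).
#'
#' @param x time-ordered numeric vector.
#' @param k trailing window length in readings.
#' @return Numeric vector of the same length as `x`.
#' @export
rolling_trailing <- function(x, k = 3) {
  stopifnot(k >= 1)
  if (length(x) == 0) return(numeric(0))
  vapply(seq_along(x),
         function(i) mean(x[max(1, i - k + 1):i]),
         numeric(1))
}

#' Build the ten mood variables from raw readings
#'
#' Orders readings by time, forms the two composites, and appends the five
#' trailing rolling averages. Rolling windows do not reset at day boundaries;
#' the day-demeaning applied downstream absorbs day-level offsets.
#'
#' @param readings tibble with `timestamp`, `happiness`, `stress`,
#'   `depression`.
#' @param k trailing rolling window in readings.
#' @return Tibble with `timestamp` plus the ten mood variables.
#' @export
build_mood_variables <- function(readings, k = 3) {
  r <- readings[order(readings$timestamp), ]
  comp <- mood_composites(r$happiness, r$stress, r$depression)
  out <- tibble::tibble(
    timestamp = r$timestamp,
    happiness = r$happiness,
    stress = r$stress,
    depression = r$depression,
    negative_affect = comp$negative_affect,
    wellbeing = comp$wellbeing
  )
  for (v in c("happiness", "stress", "depression", "negative_affect",
              "wellbeing")) {
    out[[paste0(v, "_rolling")]] <- rolling_trailing(out[[v]], k)
  }
  out
}
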