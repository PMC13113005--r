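#' Lagged mood-plant correlation profiles
#'
#' For each temporal offset, plant features are recomputed from scratch on
#' the window ending at `reading time + offset` (the window is shifted, not
#' widened), the matching criterion is re-applied per offset, and the
#' requested mood-by-feature cells are correlated at the requested analysis
#' level. A negative offset means the plant window ends before the mood
#' reading; offset 0 reproduces the corresponding unshifted screen cell
#' exactly.
#'
#' @param stream voltage tibble (`timestamp`, `mv`).
#' @param readings mood readings tibble.
#' @param era_map era map covering all reading days.
#' @param offsets offsets in minutes.
#' @param level analysis level (1 = pooled, 2 = day-demeaned).
#' @param moods mood variables to profile.
#' @param features plant features to profile.
#' @param ... further arguments passed to [build_paired_dataset()]
#'   (window width, matching criterion, band edges, sample rate, ...).
#' @return Tibble with one row per (mood, feature, offset): `r` and `n`
#'   (`n = 0` with missing `r` when no window survives at an offset).
#' @export
lagged_screen <- function(stream, readings, era_map,
                          offsets = c(-15, -10, -5, 0, 5, 10, 15),
                          level = 2,
                          moods = "stress_rolling",
                          features = c("mean", "std", "cv"),
                          ...) {
  stopifnot(level %in% c(1, 2))
  profiles <- lapply(offsets, function(off) {
    ds <- build_paired_dataset(stream, readings, era_map,
                               window_offset = off * 60, ...)
    obs <- if (nrow(ds$observations) == 0) {
      NULL
    } else if (level == 2) {
      tryCatch(demean_by_day(ds), error = function(e) NULL)
    } else {
      ds$observations
    }
    if (is.null(obs)) {
      return(tibble::tibble(
        mood = rep(moods, each = length(features)),
        feature = rep(features, times = length(moods)),
        offset = off, r = NA_real_, n = 0L
      ))
    }
    cells <- expand.grid(feature = features, mood = moods,
                         stringsAsFactors = FALSE)
    dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
      pr <- pearson_r(obs[[cells$mood[i]]], obs[[cells$feature[i]]])
      tibble::tibble(mood = cells$mood[i], feature = cells$feature[i],
                     offset = off, r = pr$r, n = pr$n)
    }))
  })
  dplyr::bind_rows(profiles)
}
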