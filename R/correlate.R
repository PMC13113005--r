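#' Pearson correlation on pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @param min_n minimum complete pairs required to report a coefficient.
#' @return A list with `r` (NA when undefined), `n` (complete pairs) and
#'   `reason` (`"ok"`, `"too_few_pairs"` or `"zero_variance"`).
#' @export
pearson_r <- function(x, y, min_n = 3) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n) {
    return(list(r = NA_real_, n = n, reason = "too_few_pairs"))
  }
  if (var(x[ok]) == 0 || var(y[ok]) == 0) {
    return(list(r = NA_real_, n = n, reason = "zero_variance"))
  }
  list(r = cor(x[ok], y[ok]), n = n, reason = "ok")
}

#' Two-sided p-value for a Pearson coefficient
#'
#' Uses the exact t transform `t = r * sqrt(df / (1 - r^2))` referred to the
#' t distribution with `df` degrees of freedom (default `n - 2`). An exact
#' fit (`|r| = 1`) returns p = 0. For day-demeaned or day-detrended data the
#' default keeps `df = n - 2`, i.e. degrees of freedom absorbed by the
#' per-day transformations are not deducted; pass `df` explicitly to use a
#' corrected convention.
#'
#' @param r Pearson coefficient.
#' @param n number of complete pairs.
#' @param df degrees of freedom; default `n - 2`.
#' @return Two-sided p-value (`NA` when `r` is missing or `df < 1`).
#' @export
cor_p_value <- function(r, n, df = NULL) {
  df <- df %||% (n - 2)
  if (is.na(r) || df < 1) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tt), df)
}

# Shared day-wise transformation scaffold: keeps days with at least
# `min_per_day` rows (and passing `day_ok`), applies `f` to each analysis
# column within each retained day.
transform_by_day <- function(x, min_per_day, f, vars = NULL,
                             day_ok = function(d) TRUE) {
  obs <- as_observations(x)
  vars <- vars %||% intersect(names(obs),
                              c(mood_variable_names(),
                                plant_feature_names(extras = TRUE)))
  keep_days <- character(0)
  dropped <- character(0)
  parts <- split(obs, as.character(obs$day))
  for (d in names(parts)) {
    if (nrow(parts[[d]]) >= min_per_day && isTRUE(day_ok(parts[[d]]))) {
      keep_days <- c(keep_days, d)
      parts[[d]][vars] <- lapply(parts[[d]][vars], f, day = parts[[d]])
    } else {
      dropped <- c(dropped, d)
    }
  }
  out <- dplyr::bind_rows(parts[keep_days])
  out <- out[order(out$timestamp), ]
  attr(out, "dropped_days") <- dropped
  out
}

#' Day-demean every analysis variable (within-day fixed effects)
#'
#' Subtracts each day's mean from every mood variable and plant feature, so
#' downstream correlations reflect only within-day co-variation; all
#' day-constant confounds (electrode baseline, weather, sleep) are absorbed
#' by construction. Days contributing fewer than `min_per_day` observations
#' are dropped and listed in the `dropped_days` attribute.
#'
#' @param x a `paired_dataset` or observation tibble.
#' @param min_per_day inclusion rule (default 2 observations per day).
#' @param vars columns to transform; defaults to all mood and feature
#'   columns.
#' @return Transformed observation tibble with a `dropped_days` attribute.
#' @export
demean_by_day <- function(x, min_per_day = 2, vars = NULL) {
  out <- transform_by_day(x, min_per_day,
                          function(v, day) v - mean(v, na.rm = TRUE),
                          vars = vars)
  if (nrow(out) == 0) stop("no day satisfies the inclusion rule")
  out
}

#' Remove a linear within-day time trend from every analysis variable
#'
#' Within each day, replaces each variable by its residual from an OLS fit on
#' within-day observation time (intercept included, so residuals are also
#' day-centred). This controls for smooth intra-day drift such as the
#' circadian component of the plant signal. Days with fewer than
#' `min_per_day` observations, or with degenerate (constant) observation
#' times, are dropped and logged.
#'
#' @inheritParams demean_by_day
#' @param min_per_day inclusion rule (default 3 observations per day).
#' @return Transformed observation tibble with a `dropped_days` attribute.
#' @export
detrend_by_day <- function(x, min_per_day = 3, vars = NULL) {
  detrend <- function(v, day) {
    tt <- day$timestamp - mean(day$timestamp)
    ok <- is.finite(v)
    if (sum(ok) < 2) return(v)
    beta <- cov(tt[ok], v[ok]) / var(tt[ok])
    alpha <- mean(v[ok]) - beta * mean(tt[ok])
    v - (alpha + beta * tt)
  }
  out <- transform_by_day(x, min_per_day, detrend,
                          vars = vars,
                          day_ok = function(d) var(d$timestamp) > 0)
  if (nrow(out) == 0) stop("no day satisfies the inclusion rule")
  out
}

#' Benjamini-Hochberg step-up survivor flags
#'
#' Step-up rule over a grid of `m` tests: sort the supplied p-values
#' ascending, find the largest k with `p_(k) <= k q / m`, and flag the k
#' smallest. `m` may exceed the number of supplied p-values, in which case
#' uncomputed tests count toward the correction as non-discoveries. Ties
#' share the larger rank's decision.
#'
#' @param p p-values in `[0, 1]` (`NA` allowed; never flagged).
#' @param m total test count (`>= length(p)` after NA removal).
#' @param q FDR level.
#' @return Logical vector of survivor flags aligned with `p`.
#' @export
bh_fdr <- function(p, m = length(p), q = 0.05) {
  stopifnot(m >= sum(!is.na(p)), q > 0, q < 1)
  adj <- stats::p.adjust(p, method = "BH", n = m)
  flags <- !is.na(adj) & adj <= q
  flags
}

#' Bonferroni survivor flags
#'
#' Flags `p <= alpha / m` (boundary values survive).
#'
#' @inheritParams bh_fdr
#' @param alpha family-wise error level.
#' @return Logical vector of survivor flags aligned with `p`.
#' @export
bonferroni <- function(p, m = length(p), alpha = 0.05) {
  stopifnot(m >= sum(!is.na(p)), alpha > 0, alpha < 1)
  !is.na(p) & p <= alpha / m
}

#' Three-level mood-by-feature correlation screen
#'
#' Correlates every mood variable with every plant feature on the dataset
#' transformed for the requested level: level 1 is the pooled analysis on
#' raw values (all observations, including single-observation days); level 2
#' day-demeans every variable (within-day fixed effects; days need
#' `min_per_day >= 2`); level 3 additionally removes the linear within-day
#' time trend (days need `min_per_day >= 3`). Each cell reports its own
#' pairwise-complete n, a t-based two-sided p-value, the level-1 pooled
#' companion coefficient on the same untransformed data, and
#' `delta_abs_r = |r| - |pooled r|`. BH FDR and Bonferroni flags are set with
#' `m` equal to the full grid size regardless of how many cells were
#' computable.
#'
#' @param x a `paired_dataset` or observation tibble.
#' @param level analysis level, 1, 2 or 3.
#' @param q FDR level for the BH flags.
#' @param alpha family-wise level for the Bonferroni flags.
#' @param moods mood variables to screen (default: all ten).
#' @param features plant features to screen (default: the twenty canonical).
#' @param df_method `"residual"` uses `df = n - 2` at every level;
#'   `"absorbed"` deducts the day means (or day trends) absorbed at levels 2
#'   and 3, using `df = n - d - 1` (level 2) or `n - 2 d - 1` (level 3) with
#'   d the number of retained days.
#' @param min_per_day override the level's day-inclusion rule.
#' @return A `screen_report`: list with `results` (one row per cell), the
#'   grid size `m`, survivor counts and the dropped-day log.
#' @export
correlation_screen <- function(x, level = 2, q = 0.05, alpha = 0.05,
                               moods = mood_variable_names(),
                               features = plant_feature_names(),
                               df_method = c("residual", "absorbed"),
                               min_per_day = NULL) {
  df_method <- match.arg(df_method)
  stopifnot(level %in% 1:3)
  base <- as_observations(x)
  trans <- switch(as.character(level),
    "1" = base,
    "2" = demean_by_day(x, min_per_day = min_per_day %||% 2),
    "3" = detrend_by_day(x, min_per_day = min_per_day %||% 3)
  )
  d_days <- length(unique(trans$day))
  m <- length(moods) * length(features)

  cells <- expand.grid(feature = features, mood = moods,
                       stringsAsFactors = FALSE)[, c("mood", "feature")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    mo <- cells$mood[i]
    fe <- cells$feature[i]
    pr <- pearson_r(trans[[mo]], trans[[fe]])
    df <- if (df_method == "residual" || level == 1) {
      pr$n - 2
    } else if (level == 2) {
      pr$n - d_days - 1
    } else {
      pr$n - 2 * d_days - 1
    }
    pooled <- if (level == 1) pr else pearson_r(base[[mo]], base[[fe]])
    tibble::tibble(
      mood = mo, feature = fe, level = level,
      n = pr$n, r = pr$r,
      p = cor_p_value(pr$r, pr$n, df = df),
      pooled_r = pooled$r,
      delta_abs_r = abs(pr$r) - abs(pooled$r),
      reason = pr$reason
    )
  })
  results <- dplyr::bind_rows(res)
  results$bh_significant <- bh_fdr(results$p, m = m, q = q)
  results$bonferroni_significant <- bonferroni(results$p, m = m,
                                               alpha = alpha)
  structure(list(
    results = results,
    level = level, m = m, q = q, alpha = alpha,
    n_computable = sum(!is.na(results$p)),
    n_significant = sum(results$p < 0.05, na.rm = TRUE),
    n_bh = sum(results$bh_significant),
    n_bonferroni = sum(results$bonferroni_significant),
    dropped_days = attr(trans, "dropped_days") %||% character(0)
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> level ", x$level, ": ", x$m, " tests (",
      x$n_computable, " computable)\n", sep = "")
  cat("  p < 0.05: ", x$n_significant,
      " | BH q=", x$q, ": ", x$n_bh,
      " | Bonferroni a=", x$alpha, ": ", x$n_bonferroni, "\n", sep = "")
  if (length(x$dropped_days) > 0) {
    cat("  dropped days:", paste(x$dropped_days, collapse = ", "), "\n")
  }
  invisible(x)
}
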