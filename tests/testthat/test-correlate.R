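test_that("pearson_r matches hand-computed coefficients and guards", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)

  expect_true(is.na(pearson_r(1:2, 2:1)$r))               # too few pairs
  expect_equal(pearson_r(1:2, 2:1)$reason, "too_few_pairs")
  expect_equal(pearson_r(rep(1, 5), 1:5)$reason, "zero_variance")

  # pairwise-complete deletion with per-cell n
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, 4, 6, NA, 10)
  pr <- pearson_r(x, y)
  expect_equal(pr$n, 3)
  expect_equal(pr$r, 1)
})

test_that("t-based p-values behave at the anchors", {
  expect_equal(cor_p_value(0, 30), 1)
  expect_equal(cor_p_value(1, 30), 0)
  expect_equal(cor_p_value(-1, 30), 0)
  expect_true(is.na(cor_p_value(NA_real_, 30)))
  # agrees with cor.test on a worked case
  set.seed(2)
  x <- rnorm(25); y <- x + rnorm(25, 0, 2)
  ct <- cor.test(x, y)
  expect_equal(cor_p_value(unname(ct$estimate), 25), ct$p.value)
  # explicit df overrides the residual convention
  expect_lt(cor_p_value(0.3, 40), cor_p_value(0.3, 40, df = 20))
})

test_that("day-demeaning centres every variable within each day", {
  ds <- make_test_dataset(seed = 21, n_days = 4, day_length = 2)
  dm <- demean_by_day(ds)
  vars <- c(mood_variable_names(), plant_feature_names())
  for (d in unique(dm$day)) {
    sums <- colSums(dm[dm$day == d, vars], na.rm = TRUE)
    expect_true(all(abs(sums) < 1e-9))
  }
  # a single isolated day reduces to simple centering
  one <- ds$observations[ds$observations$day == ds$observations$day[1], ]
  dm1 <- demean_by_day(one)
  expect_equal(dm1$stress, one$stress - mean(one$stress))
})

test_that("level-2 results are invariant to per-day constant shifts", {
  ds <- make_test_dataset(seed = 22, n_days = 4, day_length = 2)
  obs <- ds$observations
  set.seed(1)
  shifted <- obs
  for (d in unique(obs$day)) {
    idx <- shifted$day == d
    shifted$stress[idx] <- shifted$stress[idx] + rnorm(1, 0, 50)
    shifted$mean[idx] <- shifted$mean[idx] + rnorm(1, 0, 500)
  }
  r0 <- correlation_screen(obs, level = 2)$results
  r1 <- correlation_screen(shifted, level = 2)$results
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
  expect_equal(r1$p, r0$p, tolerance = 1e-12)
})

test_that("day-detrending leaves residuals orthogonal to within-day time", {
  ds <- make_test_dataset(seed = 23, n_days = 4, day_length = 2)
  dt <- detrend_by_day(ds)
  for (d in unique(dt$day)) {
    rows <- dt[dt$day == d, ]
    tt <- rows$timestamp - mean(rows$timestamp)
    expect_lt(abs(sum(tt * rows$stress)), 1e-6)
    expect_lt(abs(sum(tt * rows$mean)), 1e-6)
    expect_lt(abs(sum(rows$stress)), 1e-9)
  }
  # a variable exactly linear in time ends up with zero variance
  obs <- ds$observations
  obs$happiness <- 3 + 0.001 * obs$timestamp
  dt2 <- detrend_by_day(obs)
  expect_lt(max(abs(dt2$happiness)), 1e-6)
  pr <- pearson_r(dt2$happiness, dt2$mean)
  expect_true(is.na(pr$r) || abs(pr$r) < 1)
})

test_that("a shared within-day trend inflates level 2 but not level 3", {
  ds <- make_test_dataset(seed = 24, alpha_mean = 0, beta_cv = 0)
  obs <- ds$observations
  # inject a common linear daily drift into both stress_rolling and mean
  for (d in unique(obs$day)) {
    idx <- obs$day == d
    tt <- obs$timestamp[idx] - min(obs$timestamp[idx])
    obs$stress_rolling[idx] <- obs$stress_rolling[idx] + 4e-4 * tt
    obs$mean[idx] <- obs$mean[idx] + 0.01 * tt
  }
  cell <- function(res) res[res$mood == "stress_rolling" &
                              res$feature == "mean", ]
  l2 <- cell(correlation_screen(obs, level = 2)$results)
  l3 <- cell(correlation_screen(obs, level = 3)$results)
  expect_gt(abs(l2$r), 0.5)
  expect_lt(abs(l3$r), abs(l2$r) / 2)
})

test_that("level-3 correlation vanishes for variables sharing only a trend", {
  # two variables that co-vary only through a common linear daily trend
  set.seed(30)
  days <- rep(as.Date("2026-02-20") + 0:4, each = 12)
  tt <- rep(seq(0, 11) * 900, 5)
  obs <- tibble::tibble(
    timestamp = as.numeric(days) * 86400 + 9 * 3600 + tt,
    day = days, era = "A",
    x = 2e-4 * tt + rnorm(60, 0, 0.05),
    y = -3e-3 * tt + rnorm(60, 0, 0.8)
  )
  dt <- detrend_by_day(obs, vars = c("x", "y"))
  # residual correlation against a brute-force per-day lm residual oracle
  res_oracle <- unlist(lapply(split(obs, obs$day), function(d) {
    resid(lm(x ~ timestamp, data = d))
  }))
  expect_equal(dt$x, unname(res_oracle), tolerance = 1e-6)
  expect_lt(abs(pearson_r(dt$x, dt$y)$r), 0.3)
})

test_that("BH and Bonferroni follow the step-up and threshold rules", {
  # all p = 1: nothing survives
  expect_false(any(bh_fdr(rep(1, 10), m = 200)))
  # boundary convention: p equal to alpha / m survives Bonferroni
  expect_true(bonferroni(c(0.05 / 200), m = 200))
  expect_false(bonferroni(c(0.05 / 200 + 1e-12), m = 200))

  set.seed(33)
  for (rep in 1:25) {
    p <- round(runif(19, 0, 0.06), 4)
    m <- sample(c(19, 50, 200), 1)
    expect_equal(bh_fdr(p, m = m, q = 0.05),
                 bh_stepup_oracle(p, m = m, q = 0.05))
    # monotonicity in q and Bonferroni dominance
    expect_true(all(bh_fdr(p, m = m, q = 0.05) <= bh_fdr(p, m = m, q = 0.1)))
    expect_true(all(bonferroni(p, m = m, alpha = 0.05) <=
                      bh_fdr(p, m = m, q = 0.05)))
  }
})

test_that("the default screen spans the full 200-cell grid", {
  ds <- make_test_dataset(seed = 25)
  for (lv in 1:3) {
    rep <- correlation_screen(ds, level = lv)
    expect_equal(rep$m, 200)
    expect_equal(nrow(rep$results), 200)
    expect_setequal(unique(rep$results$mood), mood_variable_names())
    expect_setequal(unique(rep$results$feature), plant_feature_names())
    expect_true(all(abs(rep$results$r) <= 1, na.rm = TRUE))
    expect_true(all(rep$results$p >= 0 & rep$results$p <= 1, na.rm = TRUE))
    expect_true(all(rep$results$n[!is.na(rep$results$r)] >= 3))
  }
  # delta_abs_r is zero at level 1 and |r| - |pooled r| at level 2
  l1 <- correlation_screen(ds, level = 1)$results
  expect_true(all(abs(l1$delta_abs_r) < 1e-12, na.rm = TRUE))
  l2 <- correlation_screen(ds, level = 2)$results
  expect_equal(l2$delta_abs_r, abs(l2$r) - abs(l2$pooled_r))
  expect_equal(l2$pooled_r, l1$r)
})

test_that("absorbed-df p-values are more conservative at level 2", {
  ds <- make_test_dataset(seed = 26)
  res <- correlation_screen(ds, level = 2)$results
  resa <- correlation_screen(ds, level = 2, df_method = "absorbed")$results
  comparable <- !is.na(res$p) & res$p < 0.99
  expect_true(all(resa$p[comparable] >= res$p[comparable]))
})
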