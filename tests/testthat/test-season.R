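make_monthly <- function(percent, years = 2016:2023) {
  data.frame(year = rep(years, each = 12), month = rep(1:12, length(years)),
             n_recording_days = 30, n_present_days = NA,
             percent_present = percent)
}

test_that("monthly percent presence uses recording days as denominator", {
  days <- seq(as.Date("2020-01-01"), as.Date("2020-01-31"), by = "day")
  log <- data.frame(day_id = days, recorded = TRUE)
  calls <- data.frame(day_id = days, present = c(rep(TRUE, 10), rep(FALSE, 21)))
  m <- monthly_percent_presence(calls, log)
  expect_equal(m$percent_present, 100 * 10 / 31, tolerance = 1e-12)

  # non-recording days don't count: 28 recorded of 31, 14 present -> 50%
  log2 <- log; log2$recorded[29:31] <- FALSE
  calls2 <- data.frame(day_id = days[1:28], present = rep(c(TRUE, FALSE), 14))
  m2 <- monthly_percent_presence(calls2, log2)
  expect_equal(m2$percent_present, 50)
  expect_equal(m2$n_recording_days, 28L)

  # zero present days
  calls3 <- data.frame(day_id = days, present = FALSE)
  expect_equal(monthly_percent_presence(calls3, log)$percent_present, 0)

  # a call on a non-recording day is an inconsistency
  expect_error(monthly_percent_presence(calls2, transform(log, recorded = FALSE)),
               "non-recording")
})

test_that("3-month running mean averages neighbors and shrinks variance", {
  expect_equal(running_mean3(c(30, 60, 30)), c(45, 40, 45))
  expect_equal(running_mean3(rep(7, 10)), rep(7, 10))
  set.seed(1)
  x <- rnorm(120)
  expect_lte(var(running_mean3(x)), var(x))
})

test_that("seasonal model recovers a pure seasonal signal almost perfectly", {
  mu <- 45 + 14 * cos(2 * pi * (1:12 - 1) / 12)
  monthly <- make_monthly(rep(mu, 8))
  fit <- fit_seasonal_model(monthly)
  expect_gt(fit$deviance_explained, 0.99)
  expect_lt(fit$p_value, 1e-6)
  expect_equal(which.max(fit$fitted_monthly_curve), 1)
  expect_error(fit_seasonal_model(make_monthly(rep(mu, 1), years = 2016)),
               "24 months")
})

test_that("seasonal model has power against modest cycles and calibrated nulls", {
  set.seed(42)
  mu <- 45 + 14 * cos(2 * pi * (1:12 - 1) / 12)
  p_alt <- replicate(100, {
    y <- rep(mu, 8) + rnorm(96, 0, 14)  # amplitude = 1 noise SD
    fit_seasonal_model(make_monthly(y))$p_value
  })
  expect_gte(mean(p_alt < 0.01), 0.95)

  p_null <- replicate(100, {
    fit_seasonal_model(make_monthly(rnorm(96, 45, 10)))$p_value
  })
  expect_gt(median(p_null), 0.05)
  alt_fit <- fit_seasonal_model(make_monthly(rep(mu, 8) + rnorm(96, 0, 14)))
  null_fit <- fit_seasonal_model(make_monthly(rnorm(96, 45, 10)))
  expect_gt(alt_fit$deviance_explained, null_fit$deviance_explained)
})

test_that("deviance explained increases with true seasonal amplitude", {
  set.seed(7)
  med_dev <- vapply(c(0, 7, 14, 28), function(A) {
    median(replicate(20, {
      mu <- 45 + A * cos(2 * pi * (1:12 - 1) / 12)
      fit_seasonal_model(make_monthly(rep(mu, 8) + rnorm(96, 0, 10)))$deviance_explained
    }))
  }, numeric(1))
  expect_true(all(diff(med_dev) > 0))
})

test_that("ICI classes partition positive values with closed boundaries", {
  expect_equal(as.character(classify_ici(c(0.5, 1.0, 0.7))),
               c("small", "large", "intermediate"))
  expect_equal(as.character(classify_ici(c(0.6, 0.8))),
               c("intermediate", "intermediate"))
  x <- runif(500, 0.01, 3)
  cls <- classify_ici(x)
  expect_false(any(is.na(cls)))
  expect_error(classify_ici(c(1, -2)), "positive")
})

test_that("monthly ICI densities integrate to one and find planted modes", {
  trapz <- deepclick:::.trapz
  one_mode <- data.frame(mean_ici = rnorm(300, 1.0, 0.02), month = 1, year = 2020)
  d <- ici_monthly_distribution(one_mode)
  expect_equal(trapz(d$ici, d$density), 1, tolerance = 1e-6)
  expect_lt(abs(d$ici[which.max(d$density)] - 1.0), 0.05)

  set.seed(3)
  two_modes <- data.frame(
    mean_ici = c(rnorm(400, 0.5, 0.03), rnorm(400, 1.0, 0.03)),
    month = 2, year = 2020)
  d2 <- ici_monthly_distribution(two_modes)
  m1 <- max(d2$density[abs(d2$ici - 0.5) < 0.1])
  m2 <- max(d2$density[abs(d2$ici - 1.0) < 0.1])
  expect_lt(abs(m1 - m2) / max(m1, m2), 0.25)

  tri <- data.frame(
    mean_ici = c(rnorm(300, 0.5, 0.03), rnorm(300, 0.9, 0.03),
                 rnorm(300, 1.4, 0.03)),
    month = 3, year = 2020)
  d3 <- ici_monthly_distribution(tri)
  dens <- d3$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  peaks <- peaks[dens[peaks] > 0.2 * max(dens)]
  expect_equal(length(peaks), 3)
})

test_that("log-ICI ANOVA reproduces the month/year df convention", {
  set.seed(8)
  grid <- expand.grid(month = 1:12, year = 2015:2022)
  seqs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(mean_ici = rlnorm(5, -0.3, 0.3), month = grid$month[i],
               year = grid$year[i])
  }))
  out <- anova_log_ici(seqs)
  expect_equal(out$month$df[1], 11)
  expect_equal(out$year$df[1], 7)
  expect_equal(out$df_residual, 77)  # complete 12 x 8 design: 95 - 11 - 7
  expect_gte(out$month$p, 0)

  # identical cell means: F = 0 by convention
  flat <- transform(expand.grid(month = 1:3, year = 1:2), mean_ici = 1)
  out_flat <- anova_log_ici(flat)
  expect_equal(out_flat$month$F, 0)
  expect_equal(out_flat$year$F, 0)
})

test_that("log-ICI ANOVA month test has calibrated type-I error under the null", {
  set.seed(99)
  pvals <- replicate(500, {
    seqs <- transform(expand.grid(month = 1:12, year = 1:8),
                      mean_ici = rlnorm(96, -0.3, 0.25))
    anova_log_ici(seqs)$month$p
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("ICI-presence regression recovers exact lines and rejects degeneracy", {
  x <- seq(0.5, 1.5, length.out = 12)
  fit <- regress_ici_presence(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_lt(fit$p_value, 1e-10)
  expect_error(regress_ici_presence(rep(1, 12), rnorm(12)), "constant")
  expect_error(regress_ici_presence(c(1, 2), c(1, 2)), "3 paired")
  # null calibration: slope p roughly uniform
  set.seed(5)
  pv <- replicate(400, regress_ici_presence(runif(12, 0.5, 1.5),
                                            rnorm(12, 45, 10))$p_value)
  expect_gt(min(mean(pv < 0.5), 1 - mean(pv < 0.5)), 0.4)
})
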