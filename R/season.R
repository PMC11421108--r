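#' Monthly percent of recording days with presence
#'
#' Aggregates daily presence calls to the monthly percent of *recording*
#' days with at least one qualifying click sequence. The denominator is
#' the number of days with usable audio, not the calendar month length;
#' months without any recording day are emitted with `NA` percent.
#'
#' @param daily_calls data.frame with `day_id` (Date) and `present`
#'   (logical), one row per called day.
#' @param recording_log data.frame with `day_id` (Date) and `recorded`
#'   (logical) marking which calendar days have usable audio.
#' @return data.frame with `year`, `month`, `n_recording_days`,
#'   `n_present_days`, `percent_present`.
#' @export
monthly_percent_presence <- function(daily_calls, recording_log) {
  .assert(all(c("day_id", "present") %in% names(daily_calls)),
          "daily_calls needs columns day_id, present")
  .assert(all(c("day_id", "recorded") %in% names(recording_log)),
          "recording_log needs columns day_id, recorded")
  daily_calls$day_id <- as.Date(daily_calls$day_id)
  recording_log$day_id <- as.Date(recording_log$day_id)
  rec_days <- recording_log$day_id[recording_log$recorded]
  bad <- setdiff(daily_calls$day_id, rec_days)
  .assert(length(bad) == 0,
          paste0("daily call on non-recording day: ",
                 paste(format(as.Date(bad, origin = "1970-01-01")), collapse = ", ")))

  rng <- range(recording_log$day_id)
  first <- as.Date(format(rng[1], "%Y-%m-01"))
  months <- seq(first, rng[2], by = "month")
  ym <- format(months, "%Y-%m")
  rec_ym <- format(rec_days, "%Y-%m")
  pres_ym <- format(daily_calls$day_id[daily_calls$present], "%Y-%m")

  n_rec <- as.integer(table(factor(rec_ym, levels = ym)))
  n_pres <- as.integer(table(factor(pres_ym, levels = ym)))
  data.frame(year = as.integer(format(months, "%Y")),
             month = as.integer(format(months, "%m")),
             n_recording_days = n_rec, n_present_days = n_pres,
             percent_present = ifelse(n_rec > 0, 100 * n_pres / n_rec, NA_real_))
}

#' Centered 3-month running mean
#'
#' Endpoints use the two available neighbors. Preserves the bounds of the
#' input (the output of a mean never exceeds the input range).
#'
#' @param series numeric vector in chronological order.
#' @return smoothed vector of the same length.
#' @export
running_mean3 <- function(series) {
  n <- length(series)
  if (n == 0) return(series)
  vapply(seq_len(n), function(i) {
    mean(series[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
}

#' Seasonal model of monthly percent presence
#'
#' Fits percent presence as a cyclic smooth of month (period 12, modest
#' basis dimension so the smooth can express a single annual peak and
#' trough) with a year-level random intercept, via [mgcv::gam()]. Reports
#' deviance explained relative to the intercept-only model and the
#' approximate p-value for the month smooth.
#'
#' @param monthly data.frame from [monthly_percent_presence()] (needs
#'   `year`, `month`, `percent_present`); months with `NA` percent (no
#'   recording days) are dropped rather than imputed.
#' @param k basis dimension of the cyclic smooth.
#' @return object of class `seasonal_fit`: list with `deviance_explained`,
#'   `p_value`, `fitted_monthly_curve` (12 values at the average year
#'   level), and the fitted `model`.
#' @export
fit_seasonal_model <- function(monthly, k = 6) {
  .assert(all(c("year", "month", "percent_present") %in% names(monthly)),
          "monthly needs columns year, month, percent_present")
  d <- monthly[!is.na(monthly$percent_present), , drop = FALSE]
  .assert(nrow(d) >= 24, "need at least 24 months of data")
  .assert(length(unique(d$year)) >= 2, "need data spanning at least 2 years")
  d$year_f <- factor(d$year)
  fit <- mgcv::gam(percent_present ~ s(month, bs = "cc", k = k) +
                     s(year_f, bs = "re"),
                   data = d, method = "REML",
                   knots = list(month = c(0.5, 12.5)))
  sm <- summary(fit)
  newd <- data.frame(month = 1:12, year_f = factor(d$year[1], levels(d$year_f)))
  curve <- as.numeric(mgcv::predict.gam(fit, newdata = newd,
                                        exclude = "s(year_f)"))
  structure(list(deviance_explained = as.numeric(sm$dev.expl),
                 p_value = as.numeric(sm$s.table["s(month)", "p-value"]),
                 fitted_monthly_curve = curve, model = fit),
            class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf("seasonal fit: %.1f%% deviance explained, month-smooth p = %.3g\n",
              100 * x$deviance_explained, x$p_value))
  invisible(x)
}
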