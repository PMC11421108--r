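#' Classify mean ICI into demographic size classes
#'
#' Inter-click interval correlates with body size in this sexually
#' dimorphic species: long ICIs (> 0.8 s) indicate large adult males,
#' short ICIs (< 0.6 s) females and juveniles. Boundary values fall in
#' the intermediate class (the named classes use strict inequalities).
#'
#' @param mean_ici positive mean ICI values (s); vectorized.
#' @return factor with levels `small`, `intermediate`, `large`.
#' @export
classify_ici <- function(mean_ici) {
  .assert(is.numeric(mean_ici) && all(mean_ici > 0), "mean_ici must be positive")
  out <- ifelse(mean_ici < 0.6, "small",
                ifelse(mean_ici > 0.8, "large", "intermediate"))
  factor(out, levels = c("small", "intermediate", "large"))
}

# trapezoid integral used to renormalize gridded densities to unit area
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Monthly relative density of sequence ICIs
#'
#' Kernel density of mean ICI per calendar month, normalized to unit area
#' on a common grid, together with the mean, minimum and maximum of the
#' per-year densities for the same calendar month (the across-year spread
#' of the seasonal ICI distribution).
#'
#' @param sequences data.frame with `mean_ici`, `month` and optionally
#'   `year` per detected sequence.
#' @param grid evaluation grid of ICI values (s).
#' @param bw kernel bandwidth (s).
#' @return data.frame with `month`, `ici`, `density` (pooled, unit area
#'   per month), `density_mean`, `density_min`, `density_max` (across
#'   years; `NA` when no `year` column is given). Months without
#'   sequences are absent.
#' @export
ici_monthly_distribution <- function(sequences,
                                     grid = seq(0.2, 2.3, length.out = 211),
                                     bw = 0.05) {
  .assert(all(c("mean_ici", "month") %in% names(sequences)),
          "sequences needs columns mean_ici, month")
  dens_on_grid <- function(v) {
    if (length(v) == 1) v <- rep(v, 2)  # density() needs >= 2 points
    d <- density(v, bw = bw, from = min(grid), to = max(grid), n = length(grid))
    y <- approx(d$x, d$y, xout = grid)$y
    y / .trapz(grid, y)
  }
  months <- sort(unique(sequences$month))
  out <- lapply(months, function(m) {
    sel <- sequences[sequences$month == m, , drop = FALSE]
    pooled <- dens_on_grid(sel$mean_ici)
    if ("year" %in% names(sel) && length(unique(sel$year)) > 1) {
      per_year <- vapply(split(sel$mean_ici, sel$year), dens_on_grid,
                         numeric(length(grid)))
      dmean <- rowMeans(per_year); dmin <- apply(per_year, 1, min)
      dmax <- apply(per_year, 1, max)
    } else {
      dmean <- dmin <- dmax <- rep(NA_real_, length(grid))
    }
    data.frame(month = m, ici = grid, density = pooled,
               density_mean = dmean, density_min = dmin, density_max = dmax)
  })
  do.call(rbind, out)
}

#' Two-way ANOVA of log ICI on month and year
#'
#' Tests for seasonal and interannual shifts in the ICI distribution (and
#' hence demographics). Per-sequence natural-log ICIs are aggregated to
#' month-by-year cell means before testing, then a two-way ANOVA without
#' interaction is fitted; with a complete 12 x 8 design the month and year
#' terms carry 11 and 7 degrees of freedom. Type II sums of squares are
#' used so factor order is irrelevant on unbalanced (missing-cell)
#' designs. A factor whose sum of squares is exactly zero (identical cell
#' means) reports F = 0, p = 1.
#'
#' @param sequences data.frame with `mean_ici`, `month`, `year`.
#' @return list with components `month` and `year`, each `list(F, df, p)`,
#'   plus `df_residual` and the aggregated `cell_means`.
#' @export
anova_log_ici <- function(sequences) {
  .assert(all(c("mean_ici", "month", "year") %in% names(sequences)),
          "sequences needs columns mean_ici, month, year")
  .assert(all(sequences$mean_ici > 0), "mean_ici must be positive")
  cells <- aggregate(log(sequences$mean_ici),
                     by = list(month = sequences$month, year = sequences$year),
                     FUN = mean)
  names(cells)[3] <- "log_ici"
  .assert(length(unique(cells$month)) >= 2 && length(unique(cells$year)) >= 2,
          "need at least 2 levels of month and of year")
  cells$month_f <- factor(cells$month)
  cells$year_f <- factor(cells$year)
  fit <- lm(log_ici ~ month_f + year_f, data = cells)
  .assert(fit$df.residual > 0, "singular design: no residual degrees of freedom")
  df_m <- nlevels(cells$month_f) - 1L
  df_y <- nlevels(cells$year_f) - 1L
  if (var(cells$log_ici) < 1e-20) {
    # identical cell means: zero sums of squares everywhere -> F = 0
    zero <- function(df) list(F = 0, df = c(df, fit$df.residual), p = 1)
    return(list(month = zero(df_m), year = zero(df_y),
                df_residual = fit$df.residual, cell_means = cells))
  }
  ss_res <- sum(fit$residuals^2)
  av <- car::Anova(fit, type = 2)
  term <- function(name) {
    i <- match(name, rownames(av))
    ss <- av[i, "Sum Sq"]; df <- av[i, "Df"]
    if (ss < 1e-12) return(list(F = 0, df = c(df, fit$df.residual), p = 1))
    Fv <- (ss / df) / (ss_res / fit$df.residual)
    list(F = Fv, df = c(df, fit$df.residual),
         p = pf(Fv, df, fit$df.residual, lower.tail = FALSE))
  }
  list(month = term("month_f"), year = term("year_f"),
       df_residual = fit$df.residual, cell_means = cells)
}

#' Linear regression of monthly percent presence on monthly mean ICI
#'
#' Ordinary least squares test for an association between the demographic
#' composition proxy (mean ICI) and how often whales are present.
#'
#' @param mean_ici monthly mean ICI values (s), the predictor.
#' @param percent_present paired monthly percent presence, the response.
#' @return list with `slope`, `intercept`, `p_value`, `r_squared`.
#' @export
regress_ici_presence <- function(mean_ici, percent_present) {
  .assert(length(mean_ici) == length(percent_present), "inputs must be paired")
  keep <- complete.cases(mean_ici, percent_present)
  x <- mean_ici[keep]; y <- percent_present[keep]
  .assert(length(x) >= 3, "need at least 3 paired monthly values")
  .assert(var(x) > 0, "degenerate predictor: mean ICI is constant")
  fit <- lm(y ~ x)
  # exact-line input is legal; silence the perfect-fit note from summary.lm
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p_value = unname(cf["x", "Pr(>|t|)"]),
       r_squared = sm$r.squared)
}
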