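#' Simulation domain with two acoustic listening ranges
#'
#' An abstract 2-D arena (not a geographic projection) with a southern and
#' a northern circular listening range on the latitude (y) axis. Detection
#' at a station on a given day means at least one agent inside its disc.
#'
#' @param x_max,y_max domain extent in arbitrary length units.
#' @param south,north station centres, `c(x, y)`.
#' @param radius listening-range radius. The default (110 units) puts the
#'   daily detection probability of a fully dispersed 100-agent population
#'   near 0.7 and that of a remote localized aggregation near 0, so
#'   simulated monthly percentages span the same mid-range scale as
#'   empirical presence series rather than saturating.
#' @return object of class `sim_domain`.
#' @export
sim_domain <- function(x_max = 1000, y_max = 3000,
                       south = c(500, 750), north = c(500, 2250),
                       radius = 110) {
  .assert(radius > 0, "radius must be > 0")
  inside <- function(c) all(c >= radius) && c[1] <= x_max - radius && c[2] <= y_max - radius
  .assert(inside(south) && inside(north), "both stations must lie fully inside the domain")
  .assert(sum((south - north)^2) > (2 * radius)^2, "station discs must be disjoint")
  structure(list(x_max = x_max, y_max = y_max,
                 stations = list(south = south, north = north),
                 radius = radius),
            class = "sim_domain")
}

# month lengths on the simulation's 365-day calendar
.SIM_MONTH_LEN <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
.SIM_MONTH_END <- cumsum(.SIM_MONTH_LEN)

.month_of_doy <- function(doy) findInterval(doy - 1, c(0, .SIM_MONTH_END))

# wrapped Cauchy turning angles, mean 0, concentration rho in [0, 1)
.rwcauchy <- function(n, rho) {
  if (rho <= 0) return(runif(n, -pi, pi))
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (runif(n) - 0.5)))
}

# circular blend of two headings with weight w on the second
.blend_heading <- function(h1, h2, w) {
  atan2((1 - w) * sin(h1) + w * sin(h2), (1 - w) * cos(h1) + w * cos(h2))
}

# reflect positions into [0, m]
.fold <- function(p, m) {
  p <- p %% (2 * m)
  ifelse(p > m, 2 * m - p, p)
}

#' Movement strategy configuration
#'
#' Decision rules and parameters for the four hypothesized movement
#' strategies. Step lengths are gamma-distributed (shape 2) and turning
#' angles wrapped Cauchy, the standard correlated-random-walk
#' parameterization; strategy-specific overlays are:
#' \describe{
#'   \item{resource_tracking}{heading biased up the gradient of a
#'     Gaussian ridge in latitude whose peak oscillates annually between
#'     the two station latitudes (amplitude `ridge_amplitude`, sd
#'     `ridge_sd`); the ridge is phased to lead the tracking population
#'     by about two months, so the emergent detection peak at the
#'     southern station falls in mid winter.}
#'   \item{nomadic}{heading biased toward a static-in-season multi-patch
#'     Gaussian resource whose patch centres relocate at random
#'     aperiodic epochs (exponential waiting times), producing irregular,
#'     aseasonal aggregation.}
#'   \item{to_and_fro}{direct, persistent transits between the two
#'     station neighbourhoods during fixed migration windows
#'     (northbound in spring, southbound in autumn), localized
#'     small-step residence otherwise.}
#'   \item{partial}{males follow the to-and-fro rules; females reside
#'     near the southern station year-round.}
#' }
#'
#' @param strategy one of `"nomadic"`, `"to_and_fro"`, `"partial"`,
#'   `"resource_tracking"`.
#' @param step_scale mean daily step length (length units/day); defaults
#'   per strategy (40 resource tracking, 200 wide-ranging nomadic, 60
#'   migratory).
#' @param turn_concentration wrapped Cauchy concentration in `[0, 1)` for
#'   undirected movement; defaults per strategy (0.5 for wide-ranging
#'   nomads, 0.3 otherwise).
#' @param taxis_strength weight in `[0, 1]` of the resource-gradient
#'   direction in the heading blend; defaults per strategy (0.35 for
#'   resource tracking, 0.1 for nomadic local enhancement, 0 for the
#'   migratory strategies).
#' @param migration_windows list with `north` and `south` day-of-year
#'   intervals for the transit phases (migratory strategies).
#' @param migration_concentration wrapped Cauchy concentration during
#'   transit.
#' @param residence_step_frac residence step length as a fraction of
#'   `step_scale`.
#' @param home_radius distance beyond which a resident agent turns back
#'   toward its residence centre.
#' @param ridge_amplitude,ridge_sd,ridge_phase seasonal ridge geometry
#'   (resource tracking).
#' @param n_patches,patch_sd,patch_mean_life nomadic patch layout: number
#'   of patches, patch width, and mean days between relocations of a
#'   patch.
#' @param resource_seed integer seed for the nomadic patch timeline; when
#'   `NULL`, [run_simulation()] derives one from its own seed.
#' @param horizon_days length of the patch timeline to pre-draw.
#' @return object of class `strategy_config`.
#' @export
strategy_config <- function(strategy = c("nomadic", "to_and_fro", "partial",
                                         "resource_tracking"),
                            step_scale = NULL,
                            turn_concentration = NULL,
                            taxis_strength = NULL,
                            migration_windows = list(north = c(98, 143),
                                                     south = c(277, 322)),
                            migration_concentration = 0.9,
                            residence_step_frac = 0.2,
                            home_radius = 100,
                            ridge_amplitude = 750, ridge_sd = 1150,
                            ridge_phase = 30,
                            n_patches = 8, patch_sd = 150,
                            patch_mean_life = 60,
                            resource_seed = NULL, horizon_days = 3650) {
  strategy <- match.arg(strategy)
  step_scale <- step_scale %||% switch(strategy, nomadic = 200,
                                       resource_tracking = 40, 60)
  turn_concentration <- turn_concentration %||%
    switch(strategy, nomadic = 0.5, 0.3)
  taxis_strength <- taxis_strength %||%
    switch(strategy, nomadic = 0.1, resource_tracking = 0.38, 0)
  .assert(step_scale > 0, "step_scale must be > 0")
  .assert(turn_concentration >= 0 && turn_concentration < 1,
          "turn_concentration must lie in [0, 1)")
  .assert(ridge_sd > 0, "ridge_sd must be > 0")
  .assert(ridge_amplitude >= 0, "ridge_amplitude must be >= 0")
  cfg <- structure(list(strategy = strategy, step_scale = step_scale,
                        step_shape = 2,
                        turn_concentration = turn_concentration,
                        taxis_strength = taxis_strength,
                        migration_windows = migration_windows,
                        migration_concentration = migration_concentration,
                        residence_step_frac = residence_step_frac,
                        home_radius = home_radius,
                        ridge_amplitude = ridge_amplitude,
                        ridge_sd = ridge_sd, ridge_phase = ridge_phase,
                        n_patches = n_patches, patch_sd = patch_sd,
                        patch_mean_life = patch_mean_life,
                        resource_seed = resource_seed,
                        horizon_days = horizon_days,
                        patch_timeline = NULL),
                   class = "strategy_config")
  if (strategy == "nomadic" && !is.null(resource_seed)) {
    cfg$patch_timeline <- .build_patch_timeline(cfg, sim_domain())
  }
  cfg
}

#' @export
print.strategy_config <- function(x, ...) {
  cat(sprintf("strategy config: %s (step_scale %g, turn concentration %g)\n",
              x$strategy, x$step_scale, x$turn_concentration))
  invisible(x)
}

# per-patch independent relocation clocks: list of (break days, centres)
.build_patch_timeline <- function(cfg, domain) {
  set.seed(cfg$resource_seed)
  lapply(seq_len(cfg$n_patches), function(i) {
    breaks <- 0
    while (tail(breaks, 1) < cfg$horizon_days) {
      breaks <- c(breaks, tail(breaks, 1) + rexp(1, 1 / cfg$patch_mean_life))
    }
    n_epochs <- length(breaks)
    list(breaks = breaks,
         centres = cbind(runif(n_epochs, 0, domain$x_max),
                         runif(n_epochs, 0, domain$y_max)))
  })
}

.current_patches <- function(cfg, day) {
  .assert(!is.null(cfg$patch_timeline),
          "nomadic config has no patch timeline; supply resource_seed")
  t(vapply(cfg$patch_timeline, function(p) {
    p$centres[findInterval(day, p$breaks), ]
  }, numeric(2)))
}

# latitude of the seasonal ridge peak on a given day of year
.ridge_peak <- function(doy, cfg, y_mid = 1500) {
  y_mid + cfg$ridge_amplitude * sin(2 * pi * (doy - cfg$ridge_phase) / 365)
}

#' Resource value and gradient at positions
#'
#' The resource field a taxis strategy perceives: for
#' `resource_tracking`, a Gaussian ridge in latitude (uniform in x) whose
#' peak oscillates annually; for `nomadic`, a Gaussian mixture over the
#' current patch centres. Values are relative (max about 1); gradients
#' are in value per length unit.
#'
#' @param position numeric `c(x, y)` or an n x 2 matrix.
#' @param day_of_year day within the year, 1--365 (nomadic patch lookup
#'   uses the absolute simulation `day` when supplied).
#' @param cfg a [strategy_config()] for a taxis strategy.
#' @param day absolute simulation day for the nomadic patch timeline;
#'   defaults to `day_of_year`.
#' @param domain a [sim_domain()] (sets the ridge midline).
#' @return list with `value` (length n) and `gradient` (n x 2 matrix).
#' @export
resource_value <- function(position, day_of_year, cfg, day = day_of_year,
                           domain = sim_domain()) {
  .assert(cfg$strategy %in% c("resource_tracking", "nomadic"),
          "resource_value applies to taxis strategies only")
  pos <- if (is.null(dim(position))) matrix(position, ncol = 2) else position
  x <- pos[, 1]; y <- pos[, 2]
  if (cfg$strategy == "resource_tracking") {
    peak <- .ridge_peak(day_of_year, cfg, domain$y_max / 2)
    v <- exp(-(y - peak)^2 / (2 * cfg$ridge_sd^2))
    grad <- cbind(0, v * (peak - y) / cfg$ridge_sd^2)
  } else {
    centres <- .current_patches(cfg, day)
    v <- 0; gx <- 0; gy <- 0
    for (i in seq_len(nrow(centres))) {
      dx <- centres[i, 1] - x; dy <- centres[i, 2] - y
      vi <- exp(-(dx^2 + dy^2) / (2 * cfg$patch_sd^2))
      v <- v + vi
      gx <- gx + vi * dx / cfg$patch_sd^2
      gy <- gy + vi * dy / cfg$patch_sd^2
    }
    grad <- cbind(gx, gy)
  }
  list(value = v, gradient = grad)
}

# movement phase of a migratory agent on a given day of year
.tofro_phase <- function(doy, windows) {
  if (doy >= windows$north[1] && doy <= windows$north[2]) "mig_north"
  else if (doy >= windows$south[1] && doy <= windows$south[2]) "mig_south"
  else if (doy > windows$north[2] && doy < windows$south[1]) "res_north"
  else "res_south"
}

# vectorized one-day update of agent state (x, y, heading, sex vectors)
.step_agents <- function(st, cfg, domain, day) {
  doy <- ((day - 1) %% 365) + 1
  n <- length(st$x)
  if (n == 0) return(st)

  draw_steps <- function(m, scale) rgamma(m, shape = cfg$step_shape,
                                          scale = scale / cfg$step_shape)
  taxis_update <- function(idx) {
    res <- resource_value(cbind(st$x[idx], st$y[idx]), doy, cfg, day, domain)
    g <- res$gradient
    gmag <- sqrt(g[, 1]^2 + g[, 2]^2)
    gscale <- exp(-0.5) / if (cfg$strategy == "resource_tracking") cfg$ridge_sd else cfg$patch_sd
    w <- cfg$taxis_strength * pmin(1, gmag / gscale)
    gdir <- atan2(g[, 2], g[, 1])
    gdir[gmag == 0] <- st$heading[idx][gmag == 0]
    mean_dir <- .blend_heading(st$heading[idx], gdir, w)
    h <- mean_dir + .rwcauchy(length(idx), cfg$turn_concentration)
    list(h = h, L = draw_steps(length(idx), cfg$step_scale))
  }
  goal_update <- function(idx, target, rho, scale) {
    gdir <- atan2(target[2] - st$y[idx], target[1] - st$x[idx])
    list(h = gdir + .rwcauchy(length(idx), rho),
         L = draw_steps(length(idx), scale))
  }
  residence_update <- function(idx, centre, home_radius) {
    d <- sqrt((st$x[idx] - centre[1])^2 + (st$y[idx] - centre[2])^2)
    far <- d > home_radius
    h <- numeric(length(idx))
    if (any(far)) {
      h[far] <- atan2(centre[2] - st$y[idx][far], centre[1] - st$x[idx][far]) +
        .rwcauchy(sum(far), cfg$turn_concentration)
    }
    if (any(!far)) {
      h[!far] <- st$heading[idx][!far] + .rwcauchy(sum(!far), 0.3)
    }
    list(h = h, L = draw_steps(length(idx),
                               cfg$step_scale * cfg$residence_step_frac))
  }
  migratory_update <- function(idx) {
    phase <- .tofro_phase(doy, cfg$migration_windows)
    target <- switch(phase,
                     mig_north = , res_north = domain$stations$north,
                     domain$stations$south)
    if (startsWith(phase, "mig")) {
      d <- sqrt((st$x[idx] - target[1])^2 + (st$y[idx] - target[2])^2)
      en_route <- d > domain$radius
      upd <- list(h = numeric(length(idx)), L = numeric(length(idx)))
      if (any(en_route)) {
        u <- goal_update(idx[en_route], target, cfg$migration_concentration,
                         cfg$step_scale)
        upd$h[en_route] <- u$h; upd$L[en_route] <- u$L
      }
      if (any(!en_route)) {
        u <- residence_update(idx[!en_route], target, cfg$home_radius)
        upd$h[!en_route] <- u$h; upd$L[!en_route] <- u$L
      }
      upd
    } else {
      residence_update(idx, target, cfg$home_radius)
    }
  }

  upd <- switch(cfg$strategy,
    resource_tracking = , nomadic = taxis_update(seq_len(n)),
    to_and_fro = migratory_update(seq_len(n)),
    partial = {
      male <- st$sex == "male"
      h <- numeric(n); L <- numeric(n)
      if (any(male)) {
        u <- migratory_update(which(male)); h[male] <- u$h; L[male] <- u$L
      }
      if (any(!male)) {
        u <- residence_update(which(!male), domain$stations$south, 150)
        h[!male] <- u$h; L[!male] <- u$L
      }
      list(h = h, L = L)
    },
    stop("unknown strategy: ", cfg$strategy))

  st$heading <- upd$h
  st$x <- .fold(st$x + upd$L * cos(upd$h), domain$x_max)
  st$y <- .fold(st$y + upd$L * sin(upd$h), domain$y_max)
  st
}

#' Advance a single agent by one day
#'
#' Single-agent wrapper around the vectorized daily update used by
#' [run_simulation()]; exposed for inspection and unit testing of the
#' decision rules.
#'
#' @param agent list with `x`, `y`, `heading` and (for the partial
#'   strategy) `sex` (`"female"` or `"male"`).
#' @param cfg a [strategy_config()].
#' @param day absolute simulation day (day of year = `((day-1) %% 365)+1`).
#' @param domain a [sim_domain()].
#' @return the updated agent list.
#' @export
step_agent <- function(agent, cfg, day = 1, domain = sim_domain()) {
  .assert(agent$x >= 0 && agent$x <= domain$x_max &&
            agent$y >= 0 && agent$y <= domain$y_max,
          "agent must start inside the domain")
  st <- list(x = agent$x, y = agent$y,
             heading = agent$heading %||% runif(1, -pi, pi),
             sex = agent$sex %||% "female")
  st <- .step_agents(st, cfg, domain, day)
  agent$x <- st$x; agent$y <- st$y; agent$heading <- st$heading
  agent
}

.init_agents <- function(cfg, domain, n_agents) {
  south <- domain$stations$south
  st <- list(heading = runif(n_agents, -pi, pi),
             sex = rep("female", n_agents))
  if (cfg$strategy == "resource_tracking") {
    peak <- .ridge_peak(1, cfg, domain$y_max / 2)
    st$x <- runif(n_agents, 0, domain$x_max)
    st$y <- .fold(peak + rnorm(n_agents, 0, 300), domain$y_max)
  } else if (cfg$strategy == "nomadic") {
    centres <- .current_patches(cfg, 1)
    pick <- sample.int(nrow(centres), n_agents, replace = TRUE)
    st$x <- .fold(centres[pick, 1] + rnorm(n_agents, 0, cfg$patch_sd), domain$x_max)
    st$y <- .fold(centres[pick, 2] + rnorm(n_agents, 0, cfg$patch_sd), domain$y_max)
  } else {
    # migratory strategies start in the winter (southern) residence
    st$x <- .fold(south[1] + rnorm(n_agents, 0, cfg$home_radius), domain$x_max)
    st$y <- .fold(south[2] + rnorm(n_agents, 0, cfg$home_radius), domain$y_max)
    if (cfg$strategy == "partial") {
      st$sex <- rep(c("female", "male"), length.out = n_agents)
    }
  }
  st
}

#' Run an individual-based movement simulation
#'
#' Moves `n_agents` daily for `n_years` simulated 365-day years under one
#' strategy's decision rules, recording for every day how many agents sit
#' inside each listening range. Fully reproducible under a fixed seed.
#'
#' @param cfg a [strategy_config()].
#' @param n_agents number of agents.
#' @param n_years simulated years; the first year is treated as burn-in
#'   by [monthly_detection()].
#' @param seed integer seed.
#' @param domain a [sim_domain()].
#' @return object of class `sim_result`: list with `daily` (data.frame:
#'   `day`, `year`, `doy`, `month`, `n_south`, `n_north`), `monthly`
#'   (12 x 2 percent table over years 2+), `cfg`, `domain`, `seed`.
#' @export
run_simulation <- function(cfg, n_agents = 100, n_years = 10, seed = NULL,
                           domain = sim_domain()) {
  .assert(inherits(cfg, "strategy_config"), "cfg must be a strategy_config")
  .assert(n_agents >= 0, "n_agents must be >= 0")
  .assert(n_years >= 1, "n_years must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (cfg$strategy == "nomadic" && is.null(cfg$patch_timeline)) {
    cfg$resource_seed <- cfg$resource_seed %||%
      (((seed %||% 0) + 1L) %% .Machine$integer.max)
    cfg$horizon_days <- max(cfg$horizon_days, 365 * n_years)
    cfg$patch_timeline <- .build_patch_timeline(cfg, domain)
    if (!is.null(seed)) set.seed(seed + 1e6)  # decouple movement RNG from layout
  }
  n_days <- 365L * n_years
  n_south <- integer(n_days); n_north <- integer(n_days)
  st <- .init_agents(cfg, domain, n_agents)
  r2 <- domain$radius^2
  s <- domain$stations$south; no <- domain$stations$north
  for (day in seq_len(n_days)) {
    st <- .step_agents(st, cfg, domain, day)
    n_south[day] <- sum((st$x - s[1])^2 + (st$y - s[2])^2 <= r2)
    n_north[day] <- sum((st$x - no[1])^2 + (st$y - no[2])^2 <= r2)
  }
  doy <- ((seq_len(n_days) - 1L) %% 365L) + 1L
  daily <- data.frame(day = seq_len(n_days),
                      year = ((seq_len(n_days) - 1L) %/% 365L) + 1L,
                      doy = doy, month = .month_of_doy(doy),
                      n_south = n_south, n_north = n_north)
  res <- structure(list(daily = daily, monthly = NULL, cfg = cfg,
                        domain = domain, seed = seed,
                        n_agents = n_agents, n_years = n_years),
                   class = "sim_result")
  res$monthly <- if (n_years >= 2) monthly_detection(res) else NULL
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("simulation: %s, %d agents x %d years (seed %s)\n",
              x$cfg$strategy, x$n_agents, x$n_years,
              if (is.null(x$seed)) "none" else x$seed))
  if (!is.null(x$monthly)) {
    cat(sprintf("  monthly detection: south %.1f-%.1f%%, north %.1f-%.1f%%\n",
                min(x$monthly$south), max(x$monthly$south),
                min(x$monthly$north), max(x$monthly$north)))
  }
  invisible(x)
}

#' Daily detections in long station format
#'
#' @param result a `sim_result`.
#' @return data.frame with `day`, `station_id`, `n_agents_in_range`,
#'   `present`.
#' @export
daily_detections <- function(result) {
  d <- result$daily
  data.frame(day = rep(d$day, 2),
             station_id = rep(c("south", "north"), each = nrow(d)),
             n_agents_in_range = c(d$n_south, d$n_north),
             present = c(d$n_south, d$n_north) >= 1L)
}

#' Monthly mean detection per station
#'
#' For each calendar month and station, the mean over analysis years of
#' the percent of days with at least one agent in range. Year 1 is
#' discarded as burn-in by default.
#'
#' @param result a `sim_result` (or its `daily` data.frame).
#' @param analysis_years years to average over (default all but year 1).
#' @return data.frame with `month`, `south`, `north` (percent of days).
#' @export
monthly_detection <- function(result, analysis_years = NULL) {
  d <- if (inherits(result, "sim_result")) result$daily else result
  analysis_years <- analysis_years %||% setdiff(unique(d$year), 1L)
  .assert(length(analysis_years) >= 1 && length(unique(d$year)) >= 2,
          "need at least 2 simulated years (year 1 is burn-in)")
  d <- d[d$year %in% analysis_years, , drop = FALSE]
  agg <- function(col) {
    per_ym <- aggregate(list(pct = 100 * (d[[col]] >= 1)),
                        by = list(year = d$year, month = d$month), FUN = mean)
    out <- aggregate(list(pct = per_ym$pct), by = list(month = per_ym$month),
                     FUN = mean)
    out$pct[order(out$month)]
  }
  data.frame(month = 1:12, south = agg("n_south"), north = agg("n_north"))
}

#' Root-mean-square deviation between monthly detection tables
#'
#' Deviation over the 24 cells (12 months x 2 stations) between a
#' simulated and a reference monthly table, in percentage points.
#'
#' @param sim_table,ref_table data.frames with columns `month`, `south`,
#'   `north` aligned on month.
#' @return non-negative scalar (percentage points).
#' @export
rmsd <- function(sim_table, ref_table) {
  .assert(all(c("month", "south", "north") %in% names(sim_table)) &&
            all(c("month", "south", "north") %in% names(ref_table)),
          "tables need columns month, south, north")
  .assert(nrow(sim_table) == nrow(ref_table) &&
            all(sim_table$month == ref_table$month),
          "tables must align on month")
  diffs <- c(sim_table$south - ref_table$south,
             sim_table$north - ref_table$north)
  sqrt(mean(diffs^2))
}

#' Compare movement strategies against a reference seasonal series
#'
#' Runs every strategy `n_reps` times (identical seeds across strategies
#' within a rep), scores each run by [rmsd()] against the reference
#' monthly table, and ranks strategies by their median RMSD.
#'
#' @param ref_table reference monthly table ([reference_table()] default).
#' @param n_reps replicate simulations per strategy.
#' @param seed master seed; per-rep seeds are drawn from it.
#' @param n_agents,n_years simulation size per run.
#' @param configs named list of [strategy_config()]s; defaults to the four
#'   standard strategies.
#' @param domain a [sim_domain()].
#' @return object of class `strategy_comparison`: list with `per_rep`
#'   (strategy, rep, seed, rmsd), `summary` (median/mean/sd RMSD and rank)
#'   and `ranking` (strategy names, best first).
#' @export
compare_strategies <- function(ref_table = reference_table(), n_reps = 10,
                               seed = 1, n_agents = 100, n_years = 10,
                               configs = NULL, domain = sim_domain()) {
  configs <- configs %||% {
    strategies <- c("resource_tracking", "nomadic", "to_and_fro", "partial")
    stats::setNames(lapply(strategies, strategy_config), strategies)
  }
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  per_rep <- do.call(rbind, lapply(seq_len(n_reps), function(i) {
    do.call(rbind, lapply(names(configs), function(sname) {
      res <- run_simulation(configs[[sname]], n_agents = n_agents,
                            n_years = n_years, seed = rep_seeds[i],
                            domain = domain)
      data.frame(strategy = sname, rep = i, seed = rep_seeds[i],
                 rmsd = rmsd(res$monthly, ref_table))
    }))
  }))
  med <- aggregate(list(median_rmsd = per_rep$rmsd),
                   by = list(strategy = per_rep$strategy), FUN = median)
  smry <- data.frame(strategy = med$strategy, median_rmsd = med$median_rmsd)
  smry$mean_rmsd <- vapply(smry$strategy, function(s)
    mean(per_rep$rmsd[per_rep$strategy == s]), numeric(1))
  smry$sd_rmsd <- vapply(smry$strategy, function(s)
    sd(per_rep$rmsd[per_rep$strategy == s]), numeric(1))
  smry <- smry[order(smry$median_rmsd), ]
  smry$rank <- seq_len(nrow(smry))
  rownames(smry) <- NULL
  structure(list(per_rep = per_rep, summary = smry,
                 ranking = smry$strategy, ref_table = ref_table),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("strategy comparison (RMSD vs reference, percentage points):\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %d. %-18s median %.1f (mean %.1f +/- %.1f)\n",
                s$rank, s$strategy, s$median_rmsd, s$mean_rmsd, s$sd_rmsd))
  }
  invisible(x)
}
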