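dom <- sim_domain()

test_that("resource field has the stated symmetry, periodicity and limits", {
  cfg <- strategy_config("resource_tracking")
  peak <- deepclick:::.ridge_peak(100, cfg, dom$y_max / 2)
  on_peak <- resource_value(c(500, peak), 100, cfg, domain = dom)
  expect_equal(on_peak$gradient[1, 2], 0)
  expect_equal(on_peak$value, 1)
  # annual periodicity
  a <- resource_value(c(500, 1000), 40, cfg, domain = dom)
  b <- resource_value(c(500, 1000), 40 + 365, cfg, domain = dom)
  expect_equal(a$value, b$value)
  # amplitude 0: time-invariant field
  flat <- strategy_config("resource_tracking", ridge_amplitude = 0)
  v1 <- resource_value(c(500, 1000), 10, flat, domain = dom)
  v2 <- resource_value(c(500, 1000), 200, flat, domain = dom)
  expect_equal(v1$value, v2$value)
  # gradient points up-ridge
  below <- resource_value(c(500, peak - 500), 100, cfg, domain = dom)
  expect_gt(below$gradient[1, 2], 0)
})

test_that("nomadic patch field relocates but is deterministic in its seed", {
  cfg <- strategy_config("nomadic", resource_seed = 5)
  cfg2 <- strategy_config("nomadic", resource_seed = 5)
  p1 <- resource_value(c(500, 1500), 1, cfg, day = 1, domain = dom)
  p2 <- resource_value(c(500, 1500), 1, cfg2, day = 1, domain = dom)
  expect_equal(p1$value, p2$value)
  # patch layout eventually changes
  vals <- vapply(seq(1, 3000, by = 50), function(d)
    resource_value(c(500, 1500), ((d - 1) %% 365) + 1, cfg, day = d,
                   domain = dom)$value, numeric(1))
  expect_gt(length(unique(round(vals, 10))), 5)
  expect_error(resource_value(c(0, 0), 1, strategy_config("to_and_fro"),
                              domain = dom), "taxis")
})

test_that("step lengths collapse to zero in the degenerate limit", {
  cfg <- strategy_config("resource_tracking", step_scale = 1e-9)
  a <- list(x = 400, y = 1500, heading = 0)
  moved <- step_agent(a, cfg, day = 1, domain = dom)
  expect_equal(moved$x, 400, tolerance = 1e-6)
  expect_equal(moved$y, 1500, tolerance = 1e-6)
})

test_that("migrating agents head toward the target range", {
  cfg <- strategy_config("to_and_fro")
  # day 120: mid northbound window; agent south of the northern station
  set.seed(4)
  disp <- replicate(3000, {
    a <- step_agent(list(x = 500, y = 900, heading = runif(1, -pi, pi)),
                    cfg, day = 120, domain = dom)
    c(a$x - 500, a$y - 900)
  })
  mean_dir <- atan2(mean(disp[2, ]), mean(disp[1, ]))
  target_dir <- atan2(2250 - 900, 0)
  expect_lt(abs(mean_dir - target_dir), 10 * pi / 180)
})

test_that("resource-tracking agents drift up the meridional gradient", {
  cfg <- strategy_config("resource_tracking")
  set.seed(5)
  peak <- deepclick:::.ridge_peak(1, cfg, dom$y_max / 2)
  dy <- replicate(3000, {
    a <- step_agent(list(x = 500, y = peak - 800, heading = runif(1, -pi, pi)),
                    cfg, day = 1, domain = dom)
    a$y - (peak - 800)
  })
  expect_gt(mean(dy), 0)
})

test_that("simulations respect boundaries, determinism and degenerate inputs", {
  cfg <- strategy_config("to_and_fro")
  r1 <- run_simulation(cfg, n_agents = 30, n_years = 2, seed = 9)
  r2 <- run_simulation(cfg, n_agents = 30, n_years = 2, seed = 9)
  expect_identical(r1$daily, r2$daily)

  # no agents: never detected
  r0 <- run_simulation(cfg, n_agents = 0, n_years = 2, seed = 1)
  expect_true(all(r0$monthly$south == 0) && all(r0$monthly$north == 0))

  # near-frozen migrants stay in the winter residence where they started:
  # southern station detected every day, northern never
  frozen <- strategy_config("to_and_fro", step_scale = 1e-9)
  rfz <- run_simulation(frozen, n_agents = 30, n_years = 2, seed = 2)
  expect_true(all(rfz$monthly$south == 100))
  expect_true(all(rfz$monthly$north == 0))

  expect_error(run_simulation(cfg, n_agents = -1), "n_agents")
})

test_that("agents never leave the domain under reflection", {
  # direct check of the folding primitive plus a stochastic end-state check
  p <- deepclick:::.fold(c(-50, 20, 1040, 2950, -3100), 1000)
  expect_true(all(p >= 0 & p <= 1000))
  expect_equal(deepclick:::.fold(1040, 1000), 960)
  set.seed(11)
  cfg <- strategy_config("nomadic", step_scale = 500, resource_seed = 2)
  st <- deepclick:::.init_agents(cfg, dom, 40)
  for (d in 1:50) {
    st <- deepclick:::.step_agents(st, cfg, dom, d)
    expect_true(all(st$x >= 0 & st$x <= dom$x_max &
                      st$y >= 0 & st$y <= dom$y_max))
  }
})

test_that("monthly detection tables are bounded and correctly averaged", {
  daily <- data.frame(day = 1:730, year = rep(1:2, each = 365),
                      doy = rep(1:365, 2),
                      month = deepclick:::.month_of_doy(rep(1:365, 2)),
                      n_south = 1L, n_north = 0L)
  m <- monthly_detection(daily, analysis_years = 2)
  expect_equal(m$south, rep(100, 12))
  expect_equal(m$north, rep(0, 12))
  # alternating-day presence is about 50 percent
  daily$n_south <- rep_len(c(1L, 0L), 730)
  m2 <- monthly_detection(daily, analysis_years = 2)
  expect_true(all(abs(m2$south - 50) <= 2))
  expect_true(all(m2$south >= 0 & m2$south <= 100))
})

test_that("rmsd matches hand arithmetic and validates alignment", {
  tab <- data.frame(month = 1:12, south = 50, north = 50)
  expect_equal(rmsd(tab, tab), 0)
  shifted <- transform(tab, south = south + 10, north = north + 10)
  expect_equal(rmsd(shifted, tab), 10)
  bad <- tab; bad$month <- c(2:12, 1)
  expect_error(rmsd(bad, tab), "align")
  # 2-cell toy: differences 10 and 20 -> sqrt(250)
  expect_equal(sqrt(mean(c(10, 20)^2)), sqrt(250))
})

test_that("a strategy ranks first against its own emergent output", {
  cfg <- strategy_config("to_and_fro")
  own <- run_simulation(cfg, n_agents = 40, n_years = 3, seed = 31)$monthly
  configs <- list(to_and_fro = cfg,
                  nomadic = strategy_config("nomadic"),
                  resource_tracking = strategy_config("resource_tracking"))
  cmp <- compare_strategies(ref_table = own, n_reps = 2, seed = 31,
                            n_agents = 40, n_years = 3, configs = configs)
  expect_equal(cmp$ranking[1], "to_and_fro")
})
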