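test_that("zero-jitter click trains are exactly evenly spaced", {
  spec <- click_train_spec(start_time = 10, n_clicks = 8, ici_mean = 1.0)
  expect_equal(gen_click_train(spec), 10 + 0:7)
  spec2 <- click_train_spec(0.5, 2, 0.5)
  times <- gen_click_train(spec2)
  expect_length(times, 2)
  expect_equal(diff(times), 0.5)
})

test_that("jittered intervals have the requested spread and constant rounding", {
  spec <- click_train_spec(0, 100, 1.0, ici_jitter_sd = 0.05)
  times <- gen_click_train(spec, rng_seed = 7)
  intervals <- diff(times)
  expect_gte(sd(intervals), 0.03)
  expect_lte(sd(intervals), 0.07)
  expect_true(all(round_quarter(intervals) == 1.0))
})

test_that("invalid train specs name the offending field", {
  expect_error(click_train_spec(0, 1, 1.0), "n_clicks")
  expect_error(click_train_spec(0, 5, -1), "ici_mean")
  expect_error(click_train_spec(0, 5, 11), "ici_mean")
  expect_error(click_train_spec(0, 5, 1, ici_jitter_sd = -0.1), "ici_jitter_sd")
  expect_error(click_train_spec(86000, 500, 2), "day")
})

test_that("pure-noise days are labeled absent and sized correctly", {
  day <- gen_audio_day(list(), day_length = 10, rng_seed = 1)
  expect_false(day$truth_present)
  expect_length(day$waveform, 10 * 16000)
})

test_that("corpus generation enforces prevalence and is seed-reproducible", {
  corpus <- gen_labeled_corpus(n_days = 20, prevalence = 0.5, rng_seed = 3,
                               day_length = 30)
  expect_length(corpus, 20)
  expect_equal(sum(vapply(corpus, `[[`, logical(1), "truth_present")), 10)
  all_absent <- gen_labeled_corpus(n_days = 6, prevalence = 0, rng_seed = 3,
                                   day_length = 30)
  expect_false(any(vapply(all_absent, `[[`, logical(1), "truth_present")))
  expect_error(gen_labeled_corpus(n_days = 0), "n_days")

  c1 <- gen_labeled_corpus(n_days = 5, prevalence = 0.4, rng_seed = 11,
                           day_length = 20, keep_waveform = TRUE)
  c2 <- gen_labeled_corpus(n_days = 5, prevalence = 0.4, rng_seed = 11,
                           day_length = 20, keep_waveform = TRUE)
  expect_identical(c1, c2)
  # lazy rendering reproduces the eagerly rendered waveform bit for bit
  c3 <- gen_labeled_corpus(n_days = 5, prevalence = 0.4, rng_seed = 11,
                           day_length = 20)
  expect_identical(materialize_day(c3[[2]])$waveform, c1[[2]]$waveform)
})

test_that("positive corpus days carry detectable train layouts", {
  corpus <- gen_labeled_corpus(n_days = 12, prevalence = 1, rng_seed = 5,
                               day_length = 300)
  for (day in corpus) {
    expect_gte(length(day$truth_trains), 1)
    for (tr in day$truth_trains) {
      expect_gte(tr$n_clicks, 7)
      expect_gte(tr$ici_mean, 0.5)
      expect_lte(tr$ici_mean, 2.0)
    }
  }
})

test_that("reference series hits its stated extrema and bounds", {
  south <- gen_reference_series(59.3, 31.1, "south", peak_month = 1)
  expect_equal(south$mean_percent_present[south$month == 1], 59.3)
  expect_equal(south$mean_percent_present[south$month == 7], 31.1)
  expect_true(all(south$mean_percent_present >= 31.1 - 1e-9 &
                    south$mean_percent_present <= 59.3 + 1e-9))
  flat <- gen_reference_series(40, 40, "north")
  expect_equal(flat$mean_percent_present, rep(40, 12))
  expect_error(gen_reference_series(120, 10, "south"), "<= 100")
  # default two-station fixture reproduces the anchors
  ref <- reference_table()
  expect_equal(ref$south[ref$month == 1], 59.3)
  expect_equal(ref$south[ref$month == 7], 31.1)
  expect_equal(ref$north[ref$month == 7], 59.3)
})

test_that("synthetic SST grids place the isotherm where asked", {
  g <- gen_sst_grid(iso18_lat = 40, meridional_gradient = -0.5, noise_sd = 0)
  expect_equal(g$sst[g$lats == 40, ], rep(18, length(g$lons)))
  expect_equal(g$sst[g$lats == 38, 1], 19.0)
  expect_error(gen_sst_grid(iso18_lat = 80), "outside")
  expect_error(gen_sst_grid(meridional_gradient = 0.5), "gradient")
})
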