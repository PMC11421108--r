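test_that("inter-detection intervals are plain successive differences", {
  expect_equal(compute_idi(c(0.0, 1.0, 2.1)), c(1.0, 1.1))
  expect_equal(compute_idi(5), numeric(0))
  expect_equal(compute_idi(c(0, 0.5, 1.0, 1.5)), rep(0.5, 3))
  expect_error(compute_idi(c(1, 1)), "strictly increasing")
  expect_error(compute_idi(c(2, 1)), "strictly increasing")
})

test_that("quarter-second rounding uses the half-up tie rule", {
  expect_equal(round_quarter(1.1), 1.0)
  expect_equal(round_quarter(0.51), 0.5)
  expect_equal(round_quarter(0.625), 0.75)
  expect_equal(round_quarter(c(0.375, 1.875)), c(0.5, 2.0))
  x <- runif(200, 0.01, 5)
  expect_true(all(abs(round_quarter(x) - x) <= 0.125 + 1e-12))
  expect_error(round_quarter(0), "positive")
})

test_that("run filtration honors all three criteria on constructed cases", {
  # 8 detections at exact 1.0 s spacing, r = 6: one sequence of 7 intervals
  seqs <- find_click_sequences(0:7, r = 6)
  expect_equal(nrow(seqs), 1)
  expect_equal(seqs$n_intervals, 7L)
  expect_equal(seqs$rounded_idi_s, 1.0)
  expect_equal(seqs$mean_ici_s, 1.0)
  # 6 detections (5 intervals) is one short of r = 6
  expect_equal(nrow(find_click_sequences(0:5, r = 6)), 0)
  # constant 2.25 s spacing rounds outside the inclusive [0.5, 2.0] window
  expect_equal(nrow(find_click_sequences(seq(0, by = 2.25, length.out = 10),
                                         r = 6)), 0)
  # 2.0 s exactly is inside the inclusive window
  expect_equal(nrow(find_click_sequences(seq(0, by = 2, length.out = 8),
                                         r = 6)), 1)
  # a change in rounded value splits the run
  times <- c(cumsum(c(0, rep(1, 7))), 7 + cumsum(rep(1.5, 7)))
  seqs2 <- find_click_sequences(times, r = 6)
  expect_equal(sort(seqs2$rounded_idi_s), c(1.0, 1.5))
  expect_equal(seqs2$n_intervals, c(7L, 7L))
})

test_that("run filtration matches the exhaustive-window oracle on random sets", {
  set.seed(202)
  for (case in 1:300) {
    times <- random_detection_set()
    r <- sample(2:7, 1)
    got <- find_click_sequences(times, r = r)
    want <- brute_force_sequences(times, r = r)
    expect_equal(nrow(got), nrow(want), info = paste("case", case))
    if (nrow(got) > 0) {
      got_start <- match(got$start_s, times)
      ord <- order(got_start)
      expect_equal(got_start[ord], want$start[order(want$start)],
                   info = paste("case", case))
      expect_equal(got$n_intervals[ord], want$len[order(want$start)],
                   info = paste("case", case))
      expect_equal(got$rounded_idi_s[ord], want$rounded[order(want$start)],
                   info = paste("case", case))
    }
  }
})

test_that("presence is monotone non-increasing in r", {
  set.seed(17)
  for (i in 1:50) {
    times <- random_detection_set()
    present <- vapply(1:9, function(r) nrow(find_click_sequences(times, r = r)) > 0,
                      logical(1))
    expect_true(all(diff(present) <= 0))  # once absent, stays absent
  }
})

test_that("filtration rejects sets with no constant rounded run", {
  set.seed(33)
  for (i in 1:30) {
    # strictly irregular intervals: no 6 consecutive equal rounded values
    idi <- sample(seq(0.5, 2.0, by = 0.25), 12, replace = TRUE) +
      runif(12, -0.05, 0.05)
    idi <- idi[c(TRUE, diff(round_quarter(idi)) != 0)]
    times <- cumsum(c(0, idi))
    expect_equal(nrow(find_click_sequences(times, r = 6)), 0)
  }
})

test_that("daily_call runs end to end on audio, tables, and confounders", {
  pos <- gen_audio_day(list(click_train_spec(5, 8, 1.0, snr_db = 20)),
                       day_length = 30, rng_seed = 21)
  expect_true(daily_call(pos)$present)

  neg <- gen_audio_day(list(click_train_spec(5, 8, 1.0, snr_db = -10)),
                       day_length = 30, rng_seed = 22)
  expect_false(daily_call(neg)$present)

  noise <- gen_audio_day(list(), day_length = 30, rng_seed = 23)
  expect_false(daily_call(noise)$present)

  # irregular-interval transients only: energy detector fires, filter rejects
  set.seed(24)
  trans <- data.frame(time = sort(runif(15, 1, 55)), snr_db = 20, duration = 0.01)
  trans <- trans[c(TRUE, diff(trans$time) > 0.3), ]
  conf <- gen_audio_day(list(), day_length = 60, rng_seed = 24, transients = trans)
  call <- daily_call(conf)
  expect_false(call$present)
  expect_gt(call$n_candidates, 0)

  # detection-table input path
  tab <- data.frame(time = seq(10, 17, by = 1))
  expect_true(daily_call(tab)$present)
  expect_error(daily_call(numeric(0)), "non-recording")
})

test_that("noise-free in-range trains with >= r+1 clicks are always recalled", {
  fs <- 16000
  set.seed(55)
  for (i in 1:8) {
    ici <- sample(seq(0.5, 2.0, by = 0.25), 1)
    n_clicks <- sample(7:10, 1)
    tr <- click_train_spec(5, n_clicks, ici, snr_db = runif(1, 15, 30))
    day <- gen_audio_day(list(tr), day_length = ceiling(10 + n_clicks * ici))
    expect_true(daily_call(day)$present, info = paste("ici", ici, "n", n_clicks))
  }
})
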