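#' Specify a synthetic echolocation click train
#'
#' A click train is a run of broadband impulses with a near-constant
#' inter-click interval (ICI), the acoustic signature of a foraging sperm
#' whale. The spec object carries the timing and level parameters used by
#' [gen_click_train()] and [gen_audio_day()].
#'
#' @param start_time onset of the first click, seconds from day start.
#' @param n_clicks number of clicks (>= 2).
#' @param ici_mean mean inter-click interval in seconds, in (0, 10].
#' @param ici_jitter_sd standard deviation of the interval jitter (s).
#' @param click_duration duration of each rendered click (s).
#' @param snr_db click level above the background in the 1.4--4 kHz band (dB).
#' @return object of class `click_train_spec`.
#' @export
click_train_spec <- function(start_time, n_clicks, ici_mean,
                             ici_jitter_sd = 0, click_duration = 0.010,
                             snr_db = 15) {
  .assert(is.numeric(start_time) && length(start_time) == 1 && start_time >= 0,
          "invalid click_train_spec: start_time must be a non-negative number")
  .assert(is.numeric(n_clicks) && length(n_clicks) == 1 && n_clicks >= 2 &&
            n_clicks == round(n_clicks),
          "invalid click_train_spec: n_clicks must be an integer >= 2")
  .assert(is.numeric(ici_mean) && length(ici_mean) == 1 && ici_mean > 0 &&
            ici_mean <= 10,
          "invalid click_train_spec: ici_mean must lie in (0, 10]")
  .assert(is.numeric(ici_jitter_sd) && length(ici_jitter_sd) == 1 &&
            ici_jitter_sd >= 0,
          "invalid click_train_spec: ici_jitter_sd must be >= 0")
  .assert(is.numeric(click_duration) && click_duration > 0,
          "invalid click_train_spec: click_duration must be > 0")
  .assert(start_time + n_clicks * ici_mean <= 86400,
          "invalid click_train_spec: start_time + n_clicks * ici_mean exceeds one day")
  structure(list(start_time = start_time, n_clicks = as.integer(n_clicks),
                 ici_mean = ici_mean, ici_jitter_sd = ici_jitter_sd,
                 click_duration = click_duration, snr_db = snr_db),
            class = "click_train_spec")
}

#' @export
print.click_train_spec <- function(x, ...) {
  cat(sprintf("click train: %d clicks from t=%.2f s, ICI %.3f s (jitter sd %.3f), SNR %.1f dB\n",
              x$n_clicks, x$start_time, x$ici_mean, x$ici_jitter_sd, x$snr_db))
  invisible(x)
}

#' Generate click onset times for a train
#'
#' Successive intervals are drawn as `ici_mean + N(0, ici_jitter_sd)` and
#' truncated to stay positive. When `ici_jitter_sd <= 0.1` s the jitter is
#' additionally confined to the quarter-second rounding cell of
#' `round_quarter(ici_mean)`, so every rounded interval of the train equals
#' the rounded mean ICI -- the regime the run-filtration detector is built
#' for ("largely regular but not exactly constant" clicking).
#'
#' @param spec a [click_train_spec()].
#' @param rng_seed optional integer seed for reproducibility.
#' @return numeric vector of `n_clicks` onset times (seconds).
#' @export
gen_click_train <- function(spec, rng_seed = NULL) {
  .assert(inherits(spec, "click_train_spec"), "spec must be a click_train_spec")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_int <- spec$n_clicks - 1L
  intervals <- spec$ici_mean + rnorm(n_int, 0, spec$ici_jitter_sd)
  if (spec$ici_jitter_sd <= 0.1) {
    # keep jitter inside the rounding cell so the rounded IDI stays constant
    centre <- 0.25 * floor(spec$ici_mean / 0.25 + 0.5)
    intervals <- pmin(pmax(intervals, centre - 0.1249), centre + 0.1249)
  }
  intervals <- pmax(intervals, 1e-3)
  spec$start_time + c(0, cumsum(intervals))
}

# band-limited Gabor impulse centred at 2.7 kHz; amplitude 1 envelope
.gabor_click <- function(duration, fs, f0 = 2700) {
  n <- max(8L, round(duration * fs))
  t <- (seq_len(n) - (n + 1) / 2) / fs
  sigma <- duration / 6
  exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * f0 * t)
}

# add one click at time t0 scaled so its mean-square over the detector
# window exceeds the in-band noise mean-square by snr_db
.add_click <- function(waveform, fs, t0, duration, snr_db, noise_band_ms,
                       window = 0.010) {
  g <- .gabor_click(duration, fs)
  ms_g <- sum(g^2) / (window * fs)  # energy smeared over one analysis window
  a <- sqrt(noise_band_ms * 10^(snr_db / 10) / ms_g)
  i0 <- round(t0 * fs) + 1L
  idx <- i0:(i0 + length(g) - 1L)
  keep <- idx >= 1L & idx <= length(waveform)
  waveform[idx[keep]] <- waveform[idx[keep]] + a * g[keep]
  waveform
}

#' Synthesize one labeled day of hydrophone audio
#'
#' Renders Gaussian background noise at a flat spectral level plus each
#' click train as a band-limited (2.7 kHz centred) Gabor impulse scaled to
#' the requested in-band SNR. Optional irregular transients emulate
#' non-whale impulsive sounds (which the energy detector flags but the
#' interval filter must reject).
#'
#' @param trains list of [click_train_spec()] objects (may be empty).
#' @param noise_spectrum_level background spectral density, dB re 1 unit^2/Hz.
#' @param fs sample rate (Hz).
#' @param day_length day duration in seconds. The default keeps synthetic
#'   days small; full 86400-s days are supported when memory allows.
#' @param day_id identifier (coerced to `Date` when possible).
#' @param r repetition threshold used to define day-level truth: a day is
#'   truly positive when some train has at least `r + 1` clicks and a
#'   rounded mean ICI inside `[0.5, 2]` s.
#' @param transients optional data.frame (`time`, `snr_db`, `duration`) of
#'   irregular impulses to embed.
#' @param rng_seed optional integer seed.
#' @return a `labeled_day` list: `day_id`, `fs`, `day_length`, `waveform`,
#'   `truth_present`, `truth_trains`, `click_times` (list per train),
#'   `noise_spectrum_level`.
#' @export
gen_audio_day <- function(trains = list(), noise_spectrum_level = -30,
                          fs = 16000, day_length = 600, day_id = as.Date("2016-01-01"),
                          r = 6, transients = NULL, rng_seed = NULL) {
  if (inherits(trains, "click_train_spec")) trains <- list(trains)
  .assert(is.list(trains), "trains must be a list of click_train_spec objects")
  for (tr in trains) {
    .assert(inherits(tr, "click_train_spec"), "trains must be click_train_spec objects")
    .assert(tr$start_time + tr$n_clicks * tr$ici_mean <= day_length,
            "train does not fit inside day_length")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)

  n <- round(day_length * fs)
  noise_sigma <- sqrt(10^(noise_spectrum_level / 10) * fs / 2)
  noise_band_ms <- 10^(noise_spectrum_level / 10) * (4000 - 1400)
  waveform <- rnorm(n, 0, noise_sigma)

  click_times <- vector("list", length(trains))
  for (i in seq_along(trains)) {
    tr <- trains[[i]]
    times <- gen_click_train(tr)
    times <- times[times + tr$click_duration < day_length]
    for (t0 in times) {
      waveform <- .add_click(waveform, fs, t0, tr$click_duration, tr$snr_db,
                             noise_band_ms)
    }
    click_times[[i]] <- times
  }
  if (!is.null(transients) && nrow(transients) > 0) {
    for (j in seq_len(nrow(transients))) {
      waveform <- .add_click(waveform, fs, transients$time[j],
                             transients$duration[j], transients$snr_db[j],
                             noise_band_ms)
    }
  }

  truth_present <- any(vapply(trains, function(tr) {
    rq <- 0.25 * floor(tr$ici_mean / 0.25 + 0.5)
    tr$n_clicks >= r + 1 && rq >= 0.5 && rq <= 2.0
  }, logical(1)))

  structure(list(day_id = day_id, fs = fs, day_length = day_length,
                 waveform = waveform, truth_present = truth_present,
                 truth_trains = trains, click_times = click_times,
                 transients = transients,
                 noise_spectrum_level = noise_spectrum_level),
            class = "labeled_day")
}

#' @export
print.labeled_day <- function(x, ...) {
  cat(sprintf("labeled day %s: %d s @ %d Hz, %d train(s), truth_present=%s\n",
              format(x$day_id), x$day_length, x$fs, length(x$truth_trains),
              x$truth_present))
  invisible(x)
}

# layout (trains + transients) for one corpus day; deterministic given the RNG state
.plan_corpus_day <- function(positive, day_length, snr_range, r) {
  trains <- list()
  transients <- NULL
  if (positive) {
    n_trains <- sample(1:5, 1)
    t_cursor <- runif(1, 2, 15)
    for (k in seq_len(n_trains)) {
      n_clicks <- sample(seq(r + 1L, r + 14L), 1)
      ici <- runif(1, 0.5, 2.0)
      span <- n_clicks * ici
      if (t_cursor + span + 2 > day_length) break
      trains[[length(trains) + 1L]] <- click_train_spec(
        start_time = t_cursor, n_clicks = n_clicks, ici_mean = ici,
        ici_jitter_sd = 0.03, snr_db = runif(1, snr_range[1], snr_range[2]))
      t_cursor <- t_cursor + span + runif(1, 5, 20)
    }
    if (length(trains) == 0) {  # day too short for the drawn layout: one minimal train
      trains[[1]] <- click_train_spec(2, r + 1L, 0.75, ici_jitter_sd = 0.03,
                                      snr_db = runif(1, snr_range[1], snr_range[2]))
    }
  } else if (runif(1) < 0.8) {
    # bursts of Poisson-timed impulses: the energy detector flags them all,
    # and their exponential gaps produce occasional short chance runs of
    # constant rounded intervals -- so the repetition threshold r, not the
    # energy stage, is what has to reject them
    n_bursts <- sample(1:3, 1)
    times <- unlist(lapply(seq_len(n_bursts), function(b) {
      t0 <- runif(1, 1, day_length * 0.8)
      t0 + cumsum(rexp(sample(15:40, 1), rate = 0.5))
    }))
    times <- sort(times[times < day_length - 1])
    times <- times[c(TRUE, diff(times) > 0.15)]
    if (length(times) > 0) {
      transients <- data.frame(
        time = times,
        snr_db = runif(length(times), snr_range[1], snr_range[2]),
        duration = runif(length(times), 0.002, 0.030))
    }
  }
  list(trains = trains, transients = transients)
}

#' Generate a labeled corpus of synthetic recording days
#'
#' Emulates a manually validated tuning set: a fixed fraction of days carry
#' 1--5 genuine click trains (ICI drawn over 0.5--2.0 s, at least `r + 1`
#' clicks, SNR drawn from `snr_range`), the remainder are noise-only or
#' carry irregular impulsive confounders. Waveforms are rendered lazily by
#' default ([materialize_day()]) so large corpora stay memory-light; every
#' day re-renders bit-identically from its stored seed.
#'
#' @param n_days number of days (>= 1).
#' @param prevalence fraction of truly positive days in `[0, 1]`; exactly
#'   `round(prevalence * n_days)` days are positive.
#' @param snr_range 2-vector, dB range for train/transient SNR.
#' @param rng_seed integer seed for the whole corpus.
#' @param day_length seconds of audio per day.
#' @param fs sample rate (Hz).
#' @param r repetition threshold defining day-level truth.
#' @param keep_waveform render and store waveforms now (small corpora only).
#' @return list of `labeled_day` objects (waveform `NULL` unless
#'   `keep_waveform`), each with a `day_seed` for lazy rendering.
#' @export
gen_labeled_corpus <- function(n_days = 50, prevalence = 0.5,
                               snr_range = c(10, 25), rng_seed = NULL,
                               day_length = 600, fs = 16000, r = 6,
                               keep_waveform = FALSE) {
  .assert(is.numeric(n_days) && n_days >= 1, "n_days must be >= 1")
  .assert(prevalence >= 0 && prevalence <= 1, "prevalence must lie in [0, 1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_days <- as.integer(n_days)
  n_pos <- round(prevalence * n_days)
  positive <- rep(FALSE, n_days)
  if (n_pos > 0) positive[sample.int(n_days, n_pos)] <- TRUE
  day_seeds <- sample.int(.Machine$integer.max - 1L, n_days)
  day_ids <- as.Date("2016-01-01") + seq_len(n_days) - 1L

  lapply(seq_len(n_days), function(i) {
    set.seed(day_seeds[i])
    plan <- .plan_corpus_day(positive[i], day_length, snr_range, r)
    day <- structure(list(
      day_id = day_ids[i], fs = fs, day_length = day_length, waveform = NULL,
      truth_present = positive[i], truth_trains = plan$trains,
      click_times = NULL, transients = plan$transients,
      noise_spectrum_level = -30, day_seed = day_seeds[i], r = r,
      snr_range = snr_range),
      class = "labeled_day")
    if (keep_waveform) day <- materialize_day(day)
    day
  })
}

#' Render (or re-render) the waveform of a corpus day
#'
#' Deterministic: the day's stored seed drives both layout and noise, so
#' repeated calls give bit-identical audio.
#'
#' @param day a `labeled_day` from [gen_labeled_corpus()].
#' @return the day with `waveform` and `click_times` filled in.
#' @export
materialize_day <- function(day) {
  .assert(inherits(day, "labeled_day"), "day must be a labeled_day")
  if (!is.null(day$waveform)) return(day)
  .assert(!is.null(day$day_seed), "day has no waveform and no day_seed to render from")
  set.seed(day$day_seed)
  # replay the layout draws so the noise stream starts at the same RNG state
  # that corpus generation left it in; the stored specs are authoritative
  .plan_corpus_day(day$truth_present, day$day_length,
                   day$snr_range %||% c(10, 25), day$r %||% 6)
  rendered <- gen_audio_day(trains = day$truth_trains,
                            noise_spectrum_level = day$noise_spectrum_level,
                            fs = day$fs, day_length = day$day_length,
                            day_id = day$day_id, r = day$r %||% 6,
                            transients = day$transients)
  day$waveform <- rendered$waveform
  day$click_times <- rendered$click_times
  day
}
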