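#' Inter-detection intervals
#'
#' Time differences between successive detections. Intervals between
#' automated detections (IDI) may mix true clicks and false positives;
#' the run filter downstream decides which runs look like one whale.
#'
#' @param times strictly increasing detection times (s).
#' @return numeric vector of length `length(times) - 1`.
#' @export
compute_idi <- function(times) {
  .assert(is.numeric(times), "times must be numeric")
  if (length(times) < 2) return(numeric(0))
  d <- diff(times)
  .assert(all(d > 0), "times must be strictly increasing with no duplicates")
  d
}

#' Round to the nearest quarter second
#'
#' Exact midpoints (values ending in .125 s offsets) round half-up, a
#' deterministic tie rule that behaves identically across platforms.
#'
#' @param x positive times (s); vectorized.
#' @return values on the 0.25-s grid, within 0.125 s of the input.
#' @export
round_quarter <- function(x) {
  .assert(is.numeric(x) && all(x > 0), "x must be positive")
  0.25 * floor(x / 0.25 + 0.5)
}

# integer index on the quarter-second grid (half-up), for exact equality tests
.quarter_index <- function(x) as.integer(floor(x / 0.25 + 0.5))

#' Filter detections for constant rounded-interval click sequences
#'
#' Implements the three-criterion filtration that turns permissive energy
#' detections into sperm whale click sequences: successive inter-detection
#' intervals, rounded to the nearest quarter second, must (1) lie between
#' `idi_lo` and `idi_hi` inclusive, (2) be constant, and (3) persist for at
#' least `r` consecutive intervals. Only maximal runs are returned -- one
#' sequence per physical click train -- and a change in rounded value
#' terminates a run.
#'
#' @param detections data.frame with a `time` column (from
#'   [detect_candidates()]) or a numeric vector of times, sorted ascending.
#' @param r minimum number of consecutive qualifying intervals; a sequence
#'   therefore spans at least `r + 1` detections.
#' @param idi_lo,idi_hi inclusive bounds (s) on the rounded interval.
#' @return data.frame with one row per sequence: `start_s`, `end_s`,
#'   `n_intervals`, `rounded_idi_s`, `mean_ici_s`, and a list column
#'   `detection_times`.
#' @export
find_click_sequences <- function(detections, r = 6, idi_lo = 0.5, idi_hi = 2.0) {
  .assert(r >= 1, "r must be >= 1")
  times <- if (is.data.frame(detections)) detections$time else detections
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_intervals = integer(0), rounded_idi_s = numeric(0),
                      mean_ici_s = numeric(0))
  empty$detection_times <- list()
  if (length(times) < r + 1) return(empty)
  idi <- compute_idi(times)
  q <- .quarter_index(idi)
  ok <- q >= .quarter_index(idi_lo) & q <= .quarter_index(idi_hi)
  # runs of identical rounded value; out-of-range intervals break any run
  code <- ifelse(ok, q, -seq_along(q))  # unique negative codes: no false runs
  runs <- rle(code)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values > 0 & runs$lengths >= r)
  if (length(keep) == 0) return(empty)
  out <- data.frame(
    start_s = times[starts[keep]],
    end_s = times[ends[keep] + 1L],
    n_intervals = runs$lengths[keep],
    rounded_idi_s = 0.25 * runs$values[keep],
    mean_ici_s = vapply(keep, function(j) mean(idi[starts[j]:ends[j]]), numeric(1)))
  out$detection_times <- lapply(keep, function(j) times[starts[j]:(ends[j] + 1L)])
  out
}

#' Daily presence call
#'
#' Chains energy detection and sequence filtration for one day of input
#' and calls the day present when at least one qualifying sequence is
#' found. Input may be raw audio or a pre-computed detection-time table.
#'
#' @param x one day of input: a numeric waveform, a `labeled_day`, or a
#'   data.frame of detection times with a `time` column (seconds from day
#'   start).
#' @param cfg a [detector_config()].
#' @param r repetition threshold for [find_click_sequences()].
#' @param fs sample rate (Hz), required when `x` is a bare waveform.
#' @param day_id identifier attached to the call.
#' @return object of class `daily_call`: list with `day_id`, `present`,
#'   `sequences` (data.frame), `n_candidates`, `detections`.
#' @export
daily_call <- function(x, cfg = detector_config(), r = 6, fs = 16000,
                       day_id = NULL) {
  if (inherits(x, "labeled_day")) {
    x <- materialize_day(x)
    day_id <- day_id %||% x$day_id
    fs <- x$fs
    x <- x$waveform
  }
  if (is.data.frame(x)) {
    .assert("time" %in% names(x), "detection table must have a 'time' column")
    detections <- x[order(x$time), , drop = FALSE]
  } else {
    .assert(is.numeric(x) && length(x) > 0, "no audio for this day (non-recording day)")
    env <- band_energy_envelope(x, fs, cfg)
    detections <- detect_candidates(env, cfg)
  }
  sequences <- find_click_sequences(detections, r = r)
  structure(list(day_id = day_id, present = nrow(sequences) > 0,
                 sequences = sequences, n_candidates = nrow(detections),
                 detections = detections),
            class = "daily_call")
}

#' @export
print.daily_call <- function(x, ...) {
  cat(sprintf("daily call %s: present=%s (%d candidate(s), %d sequence(s))\n",
              if (is.null(x$day_id)) "<unnamed>" else format(x$day_id),
              x$present, x$n_candidates, nrow(x$sequences)))
  invisible(x)
}
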