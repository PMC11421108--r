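#' Band-limited energy detector configuration
#'
#' Parameters of the first stage of the detection workflow: band-limited
#' energy detection (BLED) of candidate clicks in the 1.4--4 kHz band,
#' where the low-frequency component of sperm whale clicks concentrates.
#' The candidate stage is deliberately permissive -- false positives are
#' removed downstream by the constant rounded-interval filter
#' ([find_click_sequences()]).
#'
#' @param band_lo,band_hi detection band edges (Hz).
#' @param snr_threshold dB above the running background required for a
#'   candidate.
#' @param window analysis window length (s).
#' @param hop hop between successive windows (s).
#' @param min_dur,max_dur admissible candidate duration bounds (s); sperm
#'   whale clicks are roughly 10--25 ms broadband impulses.
#' @param background_window length of the running background estimate (s).
#' @param background_percentile percentile used for the background (0.5 =
#'   running median, robust to click energy leakage).
#' @return object of class `detector_config`.
#' @export
detector_config <- function(band_lo = 1400, band_hi = 4000, snr_threshold = 5.0,
                            window = 0.010, hop = 0.005, min_dur = 0.002,
                            max_dur = 0.050, background_window = 60,
                            background_percentile = 0.5) {
  .assert(band_lo > 0 && band_lo < band_hi, "require 0 < band_lo < band_hi")
  .assert(min_dur < max_dur, "require min_dur < max_dur")
  .assert(snr_threshold > 0, "snr_threshold must be > 0")
  .assert(hop > 0 && window >= hop, "require 0 < hop <= window")
  .assert(background_percentile > 0 && background_percentile < 1,
          "background_percentile must lie in (0, 1)")
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 snr_threshold = snr_threshold, window = window, hop = hop,
                 min_dur = min_dur, max_dur = max_dur,
                 background_window = background_window,
                 background_percentile = background_percentile),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf("BLED config: %g-%g Hz, +%g dB over %g-s running background (p%g), %g/%g ms window/hop, duration %g-%g ms\n",
              x$band_lo, x$band_hi, x$snr_threshold, x$background_window,
              100 * x$background_percentile, 1000 * x$window, 1000 * x$hop,
              1000 * x$min_dur, 1000 * x$max_dur))
  invisible(x)
}

# brick-wall zero-phase bandpass of one zero-padded segment
.fft_bp_segment <- function(x, fs, lo, hi) {
  n <- length(x)
  m <- stats::nextn(n, 2L)
  X <- stats::fft(c(x, numeric(m - n)))
  f <- (seq_len(m) - 1) / m * fs
  f <- pmin(f, fs - f)  # fold to two-sided spectrum
  X[f < lo | f > hi] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE) / m)[seq_len(n)]
}

# zero-phase bandpass: FFT brick-wall, processed in overlapping blocks so a
# full day of audio stays in the fft size range where R is fastest; block
# seams are discarded well beyond the filter ringing scale
.bandpass <- function(waveform, fs, lo, hi) {
  .assert(fs >= 2 * hi, "sample rate must be at least twice the upper band edge")
  n <- length(waveform)
  block <- 2^19
  if (n <= block) return(.fft_bp_segment(waveform, fs, lo, hi))
  overlap <- 2^12
  core <- block - 2L * overlap
  out <- numeric(n)
  s <- 1L
  while (s <= n) {
    seg_lo <- max(1L, s - overlap)
    seg_hi <- min(n, s + core + overlap - 1L)
    y <- .fft_bp_segment(waveform[seg_lo:seg_hi], fs, lo, hi)
    keep_lo <- s - seg_lo + 1L
    keep_hi <- min(seg_hi, s + core - 1L) - seg_lo + 1L
    out[s:(s + keep_hi - keep_lo)] <- y[keep_lo:keep_hi]
    s <- s + core
  }
  out
}

#' In-band short-time energy envelope
#'
#' Zero-phase bandpass to the detector band, then mean-square energy over
#' sliding windows, in dB re 1 unit^2 (arbitrary pressure units). Silent
#' windows are floored at -200 dB rather than -Inf.
#'
#' @param waveform numeric samples.
#' @param fs sample rate (Hz).
#' @param cfg a [detector_config()].
#' @return object of class `bled_envelope`: list with `db` (one value per
#'   hop), `time` (window onset, s), and the config.
#' @export
band_energy_envelope <- function(waveform, fs, cfg = detector_config()) {
  wlen <- round(cfg$window * fs)
  .assert(length(waveform) >= wlen, "waveform shorter than one analysis window")
  bp <- .bandpass(waveform, fs, cfg$band_lo, cfg$band_hi)
  hlen <- max(1L, round(cfg$hop * fs))
  csum <- c(0, cumsum(bp^2))
  starts <- seq.int(1L, length(bp) - wlen + 1L, by = hlen)
  ms <- (csum[starts + wlen] - csum[starts]) / wlen
  structure(list(db = 10 * log10(pmax(ms, 1e-20)),
                 time = (starts - 1) / fs, fs = fs, cfg = cfg),
            class = "bled_envelope")
}

# running percentile of a series: sliding-window quantiles evaluated on a
# stride of anchor frames and linearly interpolated between them -- the
# background varies on the scale of the window, far slower than the hop
.running_percentile <- function(x, k, p) {
  n <- length(x)
  k <- min(k, n)
  if (k < 3L) return(rep(quantile(x, p, names = FALSE), n))
  half <- k %/% 2L
  stride <- max(1L, half %/% 5L)
  anchors <- unique(c(seq.int(1L, n, by = stride), n))
  vals <- vapply(anchors, function(i) {
    quantile(x[max(1L, i - half):min(n, i + half)], p, names = FALSE)
  }, numeric(1))
  if (length(anchors) == 1L) return(rep(vals, n))
  approx(anchors, vals, xout = seq_len(n))$y
}

#' Detect candidate clicks from an energy envelope
#'
#' A candidate is a maximal contiguous run of envelope values at least
#' `snr_threshold` dB above the running background whose total duration
#' falls inside `[min_dur, max_dur]`. The event time is the run onset,
#' which is stable under SNR changes.
#'
#' @param envelope a `bled_envelope` from [band_energy_envelope()].
#' @param cfg a [detector_config()]; defaults to the envelope's own.
#' @return data.frame with `time` (s) and `peak_excess` (dB) per candidate.
#' @export
detect_candidates <- function(envelope, cfg = envelope$cfg) {
  .assert(inherits(envelope, "bled_envelope"), "envelope must come from band_energy_envelope()")
  db <- envelope$db
  k <- round(cfg$background_window / cfg$hop)
  bg <- .running_percentile(db, k, cfg$background_percentile)
  above <- db >= bg + cfg$snr_threshold
  if (!any(above)) {
    return(data.frame(time = numeric(0), peak_excess = numeric(0)))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- lapply(keep, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- (i1 - i0) * cfg$hop + cfg$window
    if (dur < cfg$min_dur || dur > cfg$max_dur) return(NULL)
    data.frame(time = envelope$time[i0],
               peak_excess = max(db[i0:i1] - bg[i0:i1]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(time = numeric(0), peak_excess = numeric(0)) else out
}

#' Daily in-band noise level
#'
#' Mean-square sound pressure spectral density averaged over the detector
#' band and the whole day, in dB re 1 unit^2/Hz. Consistent across days,
#' so differences between days are meaningful even though the absolute
#' reference is arbitrary.
#'
#' @param waveform numeric samples (at least 1 s).
#' @param fs sample rate (Hz).
#' @param band 2-vector of band edges (Hz).
#' @return single dB value.
#' @export
daily_noise_level <- function(waveform, fs, band = c(1400, 4000)) {
  .assert(length(waveform) >= fs, "need at least 1 s of audio")
  bp <- .bandpass(waveform, fs, band[1], band[2])
  10 * log10(max(mean(bp^2) / (band[2] - band[1]), 1e-20))
}
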