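# Independent oracles used across the test files. Each one takes the
# slow-but-obviously-correct route so it can arbitrate the package's
# optimized implementations.

# exhaustive-window oracle for the constant rounded-interval run filter:
# enumerate every contiguous detection window, check all three criteria
# directly, and keep only maximal qualifying windows
brute_force_sequences <- function(times, r, idi_lo = 0.5, idi_hi = 2.0) {
  n <- length(times)
  if (n < r + 1) return(data.frame(start = integer(0), len = integer(0),
                                   rounded = numeric(0)))
  rq <- function(x) 0.25 * floor(x / 0.25 + 0.5)
  qualifies <- function(i, j) {
    idi <- diff(times[i:j])
    rid <- rq(idi)
    length(idi) >= r && all(rid >= idi_lo - 1e-12) && all(rid <= idi_hi + 1e-12) &&
      all(abs(rid - rid[1]) < 1e-12)
  }
  hits <- list()
  for (i in seq_len(n - r)) {
    for (j in (i + r):n) {
      if (qualifies(i, j)) {
        extendable <- (i > 1 && qualifies(i - 1, j)) || (j < n && qualifies(i, j + 1))
        if (!extendable) {
          hits[[length(hits) + 1]] <- data.frame(
            start = i, len = j - i, rounded = rq(times[i + 1] - times[i]))
        }
      }
    }
  }
  if (length(hits) == 0) return(data.frame(start = integer(0), len = integer(0),
                                           rounded = numeric(0)))
  unique(do.call(rbind, hits))
}

# random detection-time sets mixing regular trains with irregular clutter
random_detection_set <- function() {
  times <- numeric(0)
  if (runif(1) < 0.7) {  # maybe a regular train
    n <- sample(3:15, 1)
    ici <- sample(seq(0.25, 2.5, by = 0.25), 1) + runif(1, -0.1, 0.1)
    times <- c(times, runif(1, 0, 50) + cumsum(c(0, rep(ici, n - 1))))
  }
  n_noise <- sample(0:12, 1)
  times <- sort(c(times, runif(n_noise, 0, 80)))
  times[c(TRUE, diff(times) > 1e-3)]  # drop coincidences
}

# eigen-decomposition oracle for ranged major axis regression: standardize
# by ranges, take the leading eigenvector of the covariance matrix
rma_eigen_oracle <- function(x, y) {
  rx <- diff(range(x)); ry <- diff(range(y))
  S <- stats::cov(cbind(x / rx, y / ry))
  v <- eigen(S)$vectors[, 1]
  slope_std <- v[2] / v[1]
  if (stats::cor(x, y) < 0 && slope_std > 0) slope_std <- -slope_std
  slope <- slope_std * ry / rx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# small separable tuning corpus: positives carry one clean 8-click train,
# negatives carry exactly 6 aligned impulses (5 constant intervals), so
# some r in the grid separates them perfectly
separable_corpus <- function(n_pos = 4, n_neg = 4, day_length = 60) {
  days <- list()
  for (i in seq_len(n_pos)) {
    tr <- click_train_spec(5, 8, 1.0, snr_db = 20)
    d <- gen_audio_day(list(tr), day_length = day_length, rng_seed = 100 + i,
                       day_id = as.Date("2016-01-01") + i)
    days[[length(days) + 1]] <- d
  }
  for (i in seq_len(n_neg)) {
    impostor <- data.frame(time = 5 + (0:5) * 1.0, snr_db = 20, duration = 0.01)
    d <- gen_audio_day(list(), day_length = day_length, rng_seed = 200 + i,
                       transients = impostor,
                       day_id = as.Date("2016-02-01") + i)
    days[[length(days) + 1]] <- d
  }
  days
}
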