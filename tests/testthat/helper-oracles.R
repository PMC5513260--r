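# Independent brute-force oracles used to pin the vectorized implementations.

# Linear-interpolation empirical quantile computed from first principles
# (equivalent to stats::quantile type 7, written out so the oracle does not
# share code with the implementation).
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# Threshold at the top fraction, scan supra-threshold runs with an explicit
# loop, emit argmax of each run (earliest on ties) plus run metadata.
oracle_top_peaks <- function(values, top_fraction, times = seq_along(values) - 1) {
  thr <- oracle_quantile(values, 1 - top_fraction)
  above <- values > thr
  peaks <- list()
  i <- 1
  while (i <= length(values)) {
    if (above[i]) {
      j <- i
      while (j < length(values) && above[j + 1]) j <- j + 1
      seg <- values[i:j]
      k <- i + which(seg == max(seg))[1] - 1
      peaks[[length(peaks) + 1]] <- c(time = times[k], value = values[k], run_len = j - i + 1)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(peaks) == 0) {
    return(data.frame(time = numeric(0), value = numeric(0), run_len = numeric(0)))
  }
  as.data.frame(do.call(rbind, peaks))
}

# First bin of each sub-threshold run at the bottom fraction.
oracle_jerk_drops <- function(values, bottom_fraction, times = seq_along(values) - 1) {
  thr <- oracle_quantile(values, bottom_fraction)
  below <- values < thr
  out <- numeric(0)
  for (i in seq_along(values)) {
    if (below[i] && (i == 1 || !below[i - 1])) out <- c(out, times[i])
  }
  out
}

# Exhaustive one-to-one assignment: maximum number of detection/truth pairs
# with |dt| <= tol. Recursion over detections; feasible for <= 5 x 5 sets.
oracle_max_matching <- function(det, truth, tol) {
  rec <- function(i, used) {
    if (i > length(det)) return(0)
    best <- rec(i + 1, used) # leave detection i unmatched
    for (j in seq_along(truth)) {
      if (!used[j] && abs(det[i] - truth[j]) <= tol) {
        used2 <- used
        used2[j] <- TRUE
        best <- max(best, 1 + rec(i + 1, used2))
      }
    }
    best
  }
  rec(1, rep(FALSE, length(truth)))
}

# Per-window band RMS via the discrete Fourier transform (Parseval over the
# brick-wall band), in dB.
oracle_fft_band_db <- function(x, fs, band, out_rate) {
  win <- round(fs / out_rate)
  n_win <- floor(length(x) / win)
  sapply(seq_len(n_win), function(i) {
    w <- x[((i - 1) * win + 1):(i * win)]
    X <- fft(w)
    f <- (seq_along(w) - 1) * fs / length(w)
    keep <- f >= band[1] & f <= band[2]
    20 * log10(sqrt(2 * sum(Mod(X[keep])^2) / length(w)^2))
  })
}

# Canonical test records -------------------------------------------------

quiet_spec <- function(seed = 1, ...) {
  synthetic_spec(n_lunges = 0, duration_s = 180, surfacings = FALSE, seed = seed, ...)
}

canonical_run <- function(seed, spec = synthetic_spec(seed = seed), config = default_config()) {
  out <- generate_record(spec, seed = seed)
  det <- detect_lunges(out$record, config)
  list(record = out$record, truth = out$truth, detections = det,
       eval = evaluate_detections(det, out$truth, tolerance_s = config$match_tolerance_s))
}
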