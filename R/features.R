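#' Band-limited flow-noise level from hydrophone audio
#'
#' Flow noise — low-frequency hydrophone noise generated by water flowing over
#' the tag — scales with swim speed and is used here as a relative speed
#' proxy. The level is the root-mean-square sound pressure in a low-frequency
#' band (66-94 Hz by default), measured over consecutive non-overlapping
#' windows (5 per second by default) and expressed in dB re an arbitrary unit
#' reference: only quantiles and relative drops of the series are ever used
#' downstream, never absolute level.
#'
#' The band is isolated with a 4th-order Butterworth band-pass applied
#' forward-backward (zero phase); windows whose RMS falls below the floor are
#' clipped to `floor_db` so silent records stay finite.
#'
#' @param audio Numeric mono waveform.
#' @param fs_audio Audio sampling rate, Hz; must exceed twice the band's upper
#'   edge.
#' @param band Two-element band `c(lo, hi)` in Hz. Default `c(66, 94)`.
#' @param out_rate Output rate, Hz (windows of `1/out_rate` s). Default 5.
#' @param floor_db Lower clip for the level, dB. Default -120.
#' @return A tibble with columns `t_s` (window start) and `flow_db`.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 80 * seq(0, 2, by = 1 / fs))
#' head(compute_flow_noise(x, fs))
#' @export
compute_flow_noise <- function(audio, fs_audio, band = c(66, 94), out_rate = 5,
                               floor_db = -120) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    abort("`band` must be c(lo, hi) with 0 < lo < hi.")
  }
  if (band[2] >= fs_audio / 2) {
    abort(sprintf(
      "Band upper edge (%g Hz) must be below the Nyquist frequency (%g Hz).",
      band[2], fs_audio / 2
    ))
  }
  win <- round(fs_audio / out_rate)
  if (length(audio) < win) abort("Audio shorter than one output window.")
  bf <- signal::butter(4, band / (fs_audio / 2), type = "pass")
  filtered <- signal::filtfilt(bf, as.numeric(audio))
  n_win <- floor(length(filtered) / win)
  idx <- matrix(filtered[seq_len(n_win * win)], nrow = win)
  rms <- sqrt(colMeans(idx^2))
  level <- ifelse(rms > 0, 20 * log10(rms), -Inf)
  level <- pmax(level, floor_db)
  tibble(t_s = (seq_len(n_win) - 1) / out_rate, flow_db = level)
}

#' Triaxial jerk magnitude
#'
#' Jerk — the rate of change of acceleration — is computed as the Euclidean
#' norm of the difference of successive triaxial accelerometer samples,
#' scaled by the sampling rate so the result is in m/s³ and thresholds are
#' comparable across 50-500 Hz tags. Jerk highlights the rapid
#' acceleration/deceleration of a lunge while cancelling the slowly varying
#' gravity component of the accelerometer signal.
#'
#' @param accel Numeric matrix/data frame with three columns (m/s²), or a
#'   [tag_record()] whose motion table is used.
#' @param fs_accel Sampling rate, Hz (ignored when `accel` is a record).
#' @return A tibble with columns `t_s` (time of the leading sample of each
#'   difference) and `jerk` (m/s³, non-negative); one row fewer than the
#'   acceleration series.
#' @examples
#' a <- matrix(rnorm(300), ncol = 3)
#' j <- compute_jerk(a, fs_accel = 50)
#' nrow(j) # 99
#' @export
compute_jerk <- function(accel, fs_accel = NULL) {
  if (inherits(accel, "tag_record")) {
    fs_accel <- accel$fs_accel
    accel <- as.matrix(accel$motion[, c("ax", "ay", "az")])
  }
  accel <- as.matrix(accel)
  if (is.null(fs_accel)) abort("`fs_accel` is required when `accel` is a matrix.")
  if (nrow(accel) < 2L) abort("Jerk needs at least 2 accelerometer samples.")
  d <- diff(accel)
  jerk <- fs_accel * sqrt(rowSums(d^2))
  tibble(t_s = (seq_len(nrow(d)) - 1) / fs_accel, jerk = jerk)
}

#' Mode of a quantized continuous series
#'
#' Continuous sensor values have no repeated values to vote on, so the mode
#' is taken after rounding to a fixed quantization step; ties break to the
#' smallest value, the convention of common statistical mode implementations.
#'
#' @param x Numeric vector.
#' @param step Quantization step (same units as `x`).
#' @return The modal quantized value.
#' @export
quantized_mode <- function(x, step) {
  if (length(x) == 0L) return(NA_real_)
  if (!is.finite(step) || step <= 0) step <- 1e-9
  q <- round(x / step)
  tab <- table(q)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  min(winners) * step
}

#' One-second binned detection features
#'
#' Reduces a record's derived series to the per-bin statistics the decision
#' tree operates on: the quantized modes of jerk, flow noise and roll, the
#' sample standard deviation of (un-quantized) roll, and a representative
#' depth (mean of the bin's depth samples). Bins are `bin_width_s` wide,
#' `floor(duration / bin_width_s)` of them, and sample `t` falls in bin
#' `floor(t / bin_width_s)`.
#'
#' Quantization steps come from the config: 0.5 dB for flow, 1° for roll, and
#' for jerk a fraction (`quant_jerk_frac`) of the record's 99th-percentile
#' jerk, which adapts the step to the tag's sampling rate (higher-rate tags
#' resolve much larger absolute jerk).
#'
#' @param record A [tag_record()] (must carry flow noise, or audio to derive
#'   it from).
#' @param config A `lunge_config`; see [default_config()].
#' @return A `binned_features` tibble: `bin_start_s`, `jerk_mode`,
#'   `flow_mode`, `roll_mode`, `roll_sd`, `depth_m`.
#' @export
bin_features <- function(record, config = default_config()) {
  stopifnot(inherits(record, "tag_record"))
  validate_config(config)
  bw <- config$bin_width_s
  n_bins <- floor(record$duration_s / bw)
  if (n_bins < 1L) abort("Record shorter than one bin.")

  flow <- record$flow
  if (is.null(flow)) {
    if (is.null(record$audio)) {
      abort("Record has neither a flow-noise series nor audio to derive one from.")
    }
    flow <- compute_flow_noise(
      record$audio$samples, record$audio$fs,
      band = config$flow_band_hz, out_rate = config$flow_rate_hz,
      floor_db = config$flow_floor_db
    )
  }

  jerk <- compute_jerk(record)
  jerk_step <- if (is.finite(config$quant_jerk_step)) {
    config$quant_jerk_step
  } else {
    config$quant_jerk_frac * quantile(jerk$jerk, 0.99, names = FALSE, type = 7)
  }

  bin_of <- function(t) floor(t / bw + 1e-9)
  bins <- seq_len(n_bins) - 1

  agg <- function(t, v, f) {
    b <- bin_of(t)
    keep <- b >= 0 & b < n_bins
    split_v <- split(v[keep], factor(b[keep], levels = bins))
    unname(vapply(split_v, f, numeric(1)))
  }
  counts <- function(t) {
    b <- bin_of(t)
    tabulate(b[b >= 0 & b < n_bins] + 1L, nbins = n_bins)
  }
  for (nm in list(
    list("jerk", counts(jerk$t_s)),
    list("flow noise", counts(flow$t_s)),
    list("roll", counts(record$motion$t_s)),
    list("depth", counts(record$depth$t_s))
  )) {
    empty <- which(nm[[2]] == 0L)
    if (length(empty) > 0L) {
      abort(sprintf(
        "Series gap: %s has no samples in bin %d (start %g s).",
        nm[[1]], empty[1] - 1L, (empty[1] - 1L) * bw
      ))
    }
  }

  out <- tibble(
    bin_start_s = bins * bw,
    jerk_mode = agg(jerk$t_s, jerk$jerk, function(v) quantized_mode(v, jerk_step)),
    flow_mode = agg(flow$t_s, flow$flow_db, function(v) quantized_mode(v, config$quant_flow_db)),
    roll_mode = agg(
      record$motion$t_s, record$motion$roll_deg,
      function(v) quantized_mode(v, config$quant_roll_deg)
    ),
    roll_sd = agg(
      record$motion$t_s, record$motion$roll_deg,
      function(v) if (length(v) > 1L) sd(v) else 0
    ),
    depth_m = agg(record$depth$t_s, record$depth$depth_m, mean)
  )
  class(out) <- c("binned_features", class(out))
  out
}
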