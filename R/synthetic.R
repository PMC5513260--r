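#' Specification for a synthetic tag record
#'
#' Collects every knob of the synthetic deployment generator: how many lunges
#' to inject and where, the lunge signature shape, and the background
#' processes (sensor noise, fluking, dive profile, surfacing artifacts). The
#' defaults encode a canonical feeding bout: interlunge intervals drawn from
#' the 44.5 ± 19.1 s distribution observed between speed maxima in feeding
#' fin whales (truncated at 30 s so consecutive signatures never overlap and
#' duplicates never merge), a flow-noise rise to ~18 dB above background with
#' a 20 dB collapse reached 8 s after the peak, a triaxial jerk burst
#' followed by a low-jerk processing interval, and a >20° roll excursion for
#' shallow lunges.
#'
#' @param n_lunges Number of lunges to inject. Default 10.
#' @param lunge_times_s Optional explicit lunge times (overrides the
#'   interlunge sampler).
#' @param lunge_depths_m Optional lunge depths; by default drawn uniformly
#'   from 12-20 m (shallow) or 45-75 m (deep) with equal probability.
#' @param duration_s Record length; default places the last lunge 40 s before
#'   the end.
#' @param fs_accel Accelerometer (and roll) rate, Hz. Default 50.
#' @param fs_depth Depth rate, Hz. Default `fs_accel`.
#' @param first_lunge_s Time of the first lunge. Default 45.
#' @param interlunge_mean_s,interlunge_sd_s,interlunge_min_s Interlunge
#'   interval distribution (s). Defaults 44.5, 19.1, 30.
#' @param flow_rise_s Flow-noise ramp-up before the peak, s. Default 10.
#' @param flow_peak_db Flow-noise peak above background, dB. Default 18.
#' @param flow_drop_db Signature drop below the peak, dB. Default 20.
#' @param drop_delay_s Time after the peak at which the full drop is reached,
#'   s (the drop then holds through +12 s). Default 8.
#' @param jerk_burst_s Duration of the acceleration burst, s. Default 2.5.
#' @param jerk_burst_accel_sd Per-sample extra acceleration noise during the
#'   burst, m/s² (sets the jerk spike height via the sampling rate).
#'   Default 2.
#' @param jerk_quiet_delay_s,jerk_quiet_end_s Low-jerk processing interval
#'   after the burst, s after the lunge. Defaults 7 and 14.
#' @param jerk_quiet_factor Shrink factor for accelerometer deviations in the
#'   quiet interval. Default 0.15.
#' @param roll_excursion_deg Roll excursion amplitude for shallow lunges,
#'   degrees (> 20 so the roll criterion can fire). Default 45.
#' @param roll_hold_s,roll_ramp_s Hold and ramp durations of the excursion,
#'   s. Defaults 4 and 2 (so roll exceeds 20° for well over 3 s).
#' @param accel_noise_sd Background accelerometer noise SD, m/s² (AR(1),
#'   `accel_noise_rho`). Default 0.05.
#' @param accel_noise_rho AR(1) coefficient of the accelerometer noise.
#'   Default 0.6.
#' @param fluking_hz,fluking_amp Fluking oscillation on the longitudinal
#'   axis: frequency (Hz) and amplitude (m/s²). Defaults 0.25 and 0.3.
#' @param flow_background_db,flow_noise_sd Background flow-noise level and
#'   its per-sample noise SD, dB. Defaults 90 and 2.5 (half the 5 dB margin
#'   between the 20 dB signature drop and the 15 dB deep criterion).
#' @param roll_noise_sd Background roll noise SD, degrees. Default 2.
#' @param depth_noise_sd Depth sensor noise SD, m. Default 0.3.
#' @param surfacings If `TRUE` (default), inject tag-surfacing artifacts
#'   (accelerometer spike + brief flow bump + short quiet interval) at each
#'   surface interval of the dive profile.
#' @param surf_accel_sd,surf_flow_db Artifact amplitudes: extra accel noise
#'   SD (m/s²) and flow bump (dB). Defaults 4 and 8.
#' @param seed Integer seed; a fixed seed makes [generate_record()] fully
#'   reproducible. Default 1.
#' @return A `synthetic_spec` object (named list).
#' @export
synthetic_spec <- function(n_lunges = 10, lunge_times_s = NULL, lunge_depths_m = NULL,
                           duration_s = NULL, fs_accel = 50, fs_depth = fs_accel,
                           first_lunge_s = 45,
                           interlunge_mean_s = 44.5, interlunge_sd_s = 19.1,
                           interlunge_min_s = 30,
                           flow_rise_s = 10, flow_peak_db = 18, flow_drop_db = 20,
                           drop_delay_s = 8,
                           jerk_burst_s = 2.5, jerk_burst_accel_sd = 2,
                           jerk_quiet_delay_s = 7, jerk_quiet_end_s = 14,
                           jerk_quiet_factor = 0.15,
                           roll_excursion_deg = 45, roll_hold_s = 4, roll_ramp_s = 2,
                           accel_noise_sd = 0.05, accel_noise_rho = 0.6,
                           fluking_hz = 0.25, fluking_amp = 0.3,
                           flow_background_db = 90, flow_noise_sd = 2.5,
                           roll_noise_sd = 2, depth_noise_sd = 0.3,
                           surfacings = TRUE, surf_accel_sd = 4, surf_flow_db = 8,
                           seed = 1) {
  spec <- as.list(environment())
  if (spec$drop_delay_s < 8 || spec$drop_delay_s > 12) {
    abort("`drop_delay_s` must lie in [8, 12] (the drop-window of the signature).")
  }
  if (!is.null(spec$lunge_times_s) && is.unsorted(spec$lunge_times_s, strictly = TRUE)) {
    abort("`lunge_times_s` must be strictly increasing.")
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d lunges, fs %g Hz, interlunge %g +/- %g s (min %g), seed %s\n",
    x$n_lunges, x$fs_accel, x$interlunge_mean_s, x$interlunge_sd_s,
    x$interlunge_min_s, format(x$seed)
  ))
  invisible(x)
}

#' Draw interlunge intervals
#'
#' Samples intervals from a normal distribution (default mean 44.5 s, SD
#' 19.1 s, the interval between speed maxima observed in feeding fin whales)
#' by rejection below `min_gap_s`; the default floor of 0 leaves the mean
#' essentially untouched, while canonical detector test records use a 30 s
#' floor so no two signatures overlap.
#'
#' @param n Number of intervals.
#' @param mean_s,sd_s Distribution parameters, seconds.
#' @param min_gap_s Smallest admissible interval, seconds. Default 0.
#' @return Numeric vector of `n` intervals.
#' @export
draw_interlunge_gaps <- function(n, mean_s = 44.5, sd_s = 19.1, min_gap_s = 0) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mean_s, sd_s)
    out <- c(out, draw[draw >= min_gap_s])
  }
  out[seq_len(n)]
}

ease <- function(u) 0.5 - 0.5 * cos(pi * pmin(pmax(u, 0), 1))

flow_signature <- function(rel, peak_db, drop_db, rise_s, fall_s) {
  # rel: time since the flow peak; returns dB offset over background
  up <- rel >= -rise_s & rel <= 0
  fall <- rel > 0 & rel <= fall_s
  hold <- rel > fall_s & rel <= 12
  rec <- rel > 12 & rel <= 18
  out <- numeric(length(rel))
  out[up] <- peak_db * ease((rel[up] + rise_s) / rise_s)
  out[fall] <- peak_db - drop_db * (rel[fall] / fall_s)
  out[hold] <- peak_db - drop_db
  out[rec] <- (peak_db - drop_db) * (1 - (rel[rec] - 12) / 6)
  out
}

shrink_window <- function(x, idx, factor) {
  if (length(idx) == 0L) return(x)
  mu <- mean(x[idx])
  x[idx] <- mu + (x[idx] - mu) * factor
  x
}

#' Superimpose one lunge signature on a tag record
#'
#' Adds the canonical sensor signature of a single lunge at `time_s`: a
#' flow-noise ramp peaking at the lunge time then collapsing by
#' `flow_drop_db` within `drop_delay_s` seconds, an acceleration burst (the
#' jerk spike) followed by a shrunk-deviation low-jerk interval (the
#' engulfed-water processing pause), and — when `depth_m` is above the 30 m
#' split, i.e. a shallow lunge — a sustained roll excursion. The depth series
#' is not modified; the record's dive profile is expected to pass through
#' `depth_m` at `time_s` (as [generate_record()] arranges).
#'
#' @param record A [tag_record()] with a flow-noise series.
#' @param time_s Lunge time, seconds from record start.
#' @param depth_m Depth of the lunge, m (decides whether the roll excursion
#'   is applied).
#' @param spec A [synthetic_spec()] providing the signature parameters.
#' @param depth_split_m Shallow/deep boundary, m. Default 30.
#' @return The modified `tag_record`. Signatures may not overlap a previous
#'   injection; injections must fit within the record.
#' @export
inject_lunge <- function(record, time_s, depth_m, spec = synthetic_spec(),
                         depth_split_m = 30) {
  stopifnot(inherits(record, "tag_record"))
  span <- c(time_s - spec$flow_rise_s, time_s + 18)
  if (span[1] < 0 || span[2] > record$duration_s) {
    abort(sprintf("Lunge at %g s does not fit within the record.", time_s))
  }
  prev <- attr(record, "injected_lunges") %||% numeric(0)
  if (any(abs(prev - time_s) < spec$flow_rise_s + 18)) {
    abort(sprintf("Lunge at %g s overlaps a previously injected signature.", time_s))
  }

  # flow noise
  relf <- record$flow$t_s - time_s
  record$flow$flow_db <- record$flow$flow_db +
    flow_signature(relf, spec$flow_peak_db, spec$flow_drop_db, spec$flow_rise_s, spec$drop_delay_s)

  # jerk burst: extra accel noise over [0, burst], decaying to 0 by burst + 2.5
  tm <- record$motion$t_s
  rel <- tm - time_s
  burst <- which(rel >= 0 & rel <= spec$jerk_burst_s)
  decay <- which(rel > spec$jerk_burst_s & rel <= spec$jerk_burst_s + 2.5)
  for (ax in c("ax", "ay", "az")) {
    v <- record$motion[[ax]]
    v[burst] <- v[burst] + rnorm(length(burst), sd = spec$jerk_burst_accel_sd)
    if (length(decay) > 0L) {
      w <- 1 - (rel[decay] - spec$jerk_burst_s) / 2.5
      v[decay] <- v[decay] + rnorm(length(decay), sd = spec$jerk_burst_accel_sd * 0.3) * w
    }
    # processing pause: deviations shrunk toward the local mean
    quiet <- which(rel > spec$jerk_quiet_delay_s & rel <= spec$jerk_quiet_end_s)
    record$motion[[ax]] <- shrink_window(v, quiet, spec$jerk_quiet_factor)
  }

  # roll excursion (shallow lunges only)
  if (depth_m < depth_split_m) {
    a <- spec$roll_excursion_deg
    ramp <- spec$roll_ramp_s
    hold <- spec$roll_hold_s
    r0 <- -(ramp + hold / 2)  # excursion centered slightly before/around the peak
    up <- rel >= r0 & rel < r0 + ramp
    hd <- rel >= r0 + ramp & rel <= r0 + ramp + hold
    dn <- rel > r0 + ramp + hold & rel <= r0 + 2 * ramp + hold
    bump <- numeric(length(rel))
    bump[up] <- a * ease((rel[up] - r0) / ramp)
    bump[hd] <- a
    bump[dn] <- a * (1 - ease((rel[dn] - (r0 + ramp + hold)) / ramp))
    record$motion$roll_deg <- pmin(pmax(record$motion$roll_deg + bump, -180), 180)
  }

  attr(record, "injected_lunges") <- c(prev, time_s)
  record
}

inject_surfacing <- function(record, time_s, spec) {
  tm <- record$motion$t_s
  rel <- tm - time_s
  spike <- which(rel >= 0 & rel <= 0.5)
  for (ax in c("ax", "ay", "az")) {
    v <- record$motion[[ax]]
    v[spike] <- v[spike] + rnorm(length(spike), sd = spec$surf_accel_sd)
    quiet <- which(rel > 0.7 & rel <= 2.5)
    record$motion[[ax]] <- shrink_window(v, quiet, 0.3)
  }
  relf <- record$flow$t_s - time_s
  bump <- which(relf >= -0.4 & relf <= 0.4)
  record$flow$flow_db[bump] <- record$flow$flow_db[bump] +
    spec$surf_flow_db * (1 - abs(relf[bump]) / 0.4)
  jig <- which(rel >= 0 & rel <= 1)
  record$motion$roll_deg[jig] <- pmin(pmax(
    record$motion$roll_deg[jig] + rnorm(length(jig), sd = 5), -180
  ), 180)
  record
}

ar1_noise <- function(n, sd, rho) {
  innov_sd <- sd * sqrt(1 - rho^2)
  as.numeric(stats::filter(rnorm(n, sd = innov_sd), rho, method = "recursive"))
}

#' Generate a seeded synthetic tag record with known lunges
#'
#' Builds a full multisensor deployment from a [synthetic_spec()]: a dive
#' profile interpolated monotonically through the lunge depths with surface
#' intervals at the record ends, AR(1) accelerometer noise plus a fluking
#' oscillation on the longitudinal axis, background flow noise at 5 Hz, roll
#' noise, surfacing artifacts, and one injected lunge signature per truth
#' time. The generator is fully reproducible for a fixed spec and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A list with elements `record` (a [tag_record()]) and `truth` (a
#'   tibble `time_s`, `depth_m`, `category`).
#' @examples
#' out <- generate_record(synthetic_spec(n_lunges = 3, seed = 7))
#' out$truth
#' @export
generate_record <- function(spec = synthetic_spec(), seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)

  # lunge times and depths
  if (is.null(spec$lunge_times_s)) {
    gaps <- draw_interlunge_gaps(
      max(spec$n_lunges - 1, 0),
      spec$interlunge_mean_s, spec$interlunge_sd_s, spec$interlunge_min_s
    )
    times <- if (spec$n_lunges > 0) spec$first_lunge_s + c(0, cumsum(gaps)) else numeric(0)
  } else {
    times <- spec$lunge_times_s
  }
  n <- length(times)
  if (is.null(spec$lunge_depths_m)) {
    shallow <- if (n > 0) sample(c(TRUE, FALSE), n, replace = TRUE) else logical(0)
    depths <- ifelse(shallow, stats::runif(n, 12, 20), stats::runif(n, 45, 75))
  } else {
    depths <- spec$lunge_depths_m
    if (length(depths) != n) abort("`lunge_depths_m` must match the number of lunges.")
  }
  duration <- spec$duration_s %||% (if (n > 0) max(times) + 40 else 300)
  if (n > 0 && (min(times) < spec$flow_rise_s + 5 || max(times) > duration - 20)) {
    abort("Lunge times must leave room for the signature within the record.")
  }

  fs <- spec$fs_accel
  n_acc <- round(duration * fs)
  tm <- (seq_len(n_acc) - 1) / fs

  # dive profile through surface intervals and lunge depths
  way_t <- c(0, 4)
  way_d <- c(0, 0)
  if (n > 0) {
    way_t <- c(way_t, times)
    way_d <- c(way_d, depths)
  }
  way_t <- c(way_t, duration - 6, duration)
  way_d <- c(way_d, 0, 0)
  prof <- stats::splinefun(way_t, way_d, method = "monoH.FC")
  n_dep <- round(duration * spec$fs_depth)
  td <- (seq_len(n_dep) - 1) / spec$fs_depth
  depth <- pmax(prof(td) + rnorm(n_dep, sd = spec$depth_noise_sd), 0)

  accel <- cbind(
    ar1_noise(n_acc, spec$accel_noise_sd, spec$accel_noise_rho) +
      spec$fluking_amp * sin(2 * pi * spec$fluking_hz * tm),
    ar1_noise(n_acc, spec$accel_noise_sd, spec$accel_noise_rho),
    9.80665 + ar1_noise(n_acc, spec$accel_noise_sd, spec$accel_noise_rho)
  )
  roll <- rnorm(n_acc, sd = spec$roll_noise_sd)
  n_flow <- round(duration * 5)
  flow <- spec$flow_background_db + rnorm(n_flow, sd = spec$flow_noise_sd)

  record <- tag_record(
    whale_id = sprintf("synthetic-%s", format(seed %||% "unseeded")),
    accel = accel, fs_accel = fs,
    depth = depth, fs_depth = spec$fs_depth,
    roll = roll, flow_db = flow, flow_rate_hz = 5
  )

  for (i in seq_len(n)) {
    record <- inject_lunge(record, times[i], depths[i], spec)
  }
  if (isTRUE(spec$surfacings)) {
    surf_times <- c(2, duration - 4)
    for (s in surf_times) record <- inject_surfacing(record, s, spec)
  }

  truth <- tibble(
    time_s = times,
    depth_m = depths,
    category = ifelse(depths < 30, "shallow", "deep")
  )
  list(record = record, truth = truth)
}
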