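#' Apply the pairing and exclusion rules to one branch's peaks
#'
#' The heart of the decision tree. A flow-noise peak at time `t` survives as
#' a lunge candidate iff, in order:
#'
#' 1. a jerk peak lies within `pair_window_flow_jerk_s` (5 s) of `t` — the
#'    acceleration burst and the speed maximum of a lunge coincide;
#' 2. (shallow branch only) a surviving roll-SD peak lies within
#'    `pair_window_roll_s` (10 s) — roll tends to be more offset from the
#'    acceleration peak;
#' 3. the minimum of the binned flow mode over `t + drop_window_s`
#'    (+8 to +12 s) is at least `flow_drop_db` below the flow mode at `t` —
#'    the mouth opening stalls the whale;
#' 4. a jerk-drop time falls in `(t_j, t_j + jerk_min_window_s]` after some
#'    jerk peak `t_j` paired in step 1, where jerk drops that have *any* jerk
#'    peak within ±`surfacing_exclusion_s` (4 s) are first discarded — such
#'    spike-then-silence patterns are surfacing impacts, not feeding.
#'
#' Flow peaks whose drop window runs past the end of the record cannot be
#' evaluated and are discarded.
#'
#' @param flow_peaks,jerk_peaks,roll_sd_peaks `peak_set` tibbles from
#'   [find_top_peaks()] (after any short-run / roll-criterion filtering).
#' @param jerk_drops Numeric vector of jerk-drop times from
#'   [find_jerk_drops()].
#' @param flow_mode Binned flow-mode values.
#' @param branch `"shallow"` or `"deep"`; the roll pairing (step 2) applies
#'   only to the shallow branch.
#' @param config A `lunge_config`.
#' @param times Bin-start times for `flow_mode`; defaults to `0:(n-1)`.
#' @param debug If `TRUE`, return a tibble of all flow peaks with a logical
#'   column per rule instead of the surviving times.
#' @return Numeric vector of candidate lunge times (flow-peak bin times), or
#'   the per-rule audit tibble when `debug = TRUE`.
#' @export
pair_and_filter <- function(flow_peaks, jerk_peaks, roll_sd_peaks, jerk_drops,
                            flow_mode, branch = c("shallow", "deep"),
                            config = default_config(),
                            times = seq_along(flow_mode) - 1,
                            debug = FALSE) {
  branch <- match.arg(branch)
  drop_db <- config[[branch]]$flow_drop_db
  dw <- config$drop_window_s

  # surfacing exclusion: drop times with any jerk peak within +/- 4 s (closed)
  drops_ok <- jerk_drops
  if (length(jerk_drops) > 0L && nrow(jerk_peaks) > 0L) {
    near_peak <- vapply(
      jerk_drops,
      function(td) any(abs(jerk_peaks$time_s - td) <= config$surfacing_exclusion_s),
      logical(1)
    )
    drops_ok <- jerk_drops[!near_peak]
  }

  t_end <- max(times)
  eval_peak <- function(t, v) {
    in_record <- (t + dw[2]) <= t_end
    jp <- jerk_peaks$time_s[abs(jerk_peaks$time_s - t) <= config$pair_window_flow_jerk_s]
    has_jerk <- length(jp) > 0L
    has_roll <- branch != "shallow" ||
      any(abs(roll_sd_peaks$time_s - t) <= config$pair_window_roll_s)
    win <- flow_mode[times >= t + dw[1] & times <= t + dw[2]]
    has_drop <- in_record && length(win) > 0L && min(win) <= v - drop_db
    has_jerk_min <- has_jerk && length(drops_ok) > 0L &&
      any(vapply(
        jp,
        function(tj) any(drops_ok > tj & drops_ok <= tj + config$jerk_min_window_s),
        logical(1)
      ))
    c(
      in_record = in_record, has_jerk = has_jerk, has_roll = has_roll,
      has_drop = has_drop, has_jerk_min = has_jerk_min
    )
  }

  if (nrow(flow_peaks) == 0L) {
    if (debug) {
      return(tibble(
        time_s = numeric(0), in_record = logical(0), has_jerk = logical(0),
        has_roll = logical(0), has_drop = logical(0), has_jerk_min = logical(0),
        kept = logical(0)
      ))
    }
    return(numeric(0))
  }

  rules <- t(mapply(eval_peak, flow_peaks$time_s, flow_peaks$value))
  kept <- rowSums(rules) == ncol(rules)
  if (debug) {
    out <- as_tibble(as.data.frame(rules))
    out$time_s <- flow_peaks$time_s
    out$kept <- kept
    return(out[, c("time_s", "in_record", "has_jerk", "has_roll", "has_drop", "has_jerk_min", "kept")])
  }
  flow_peaks$time_s[kept]
}

run_branch <- function(features, branch, config, debug = FALSE) {
  b <- config[[branch]]
  flow_peaks <- find_top_peaks(features$flow_mode, b$peak_top_fraction, features$bin_start_s)
  jerk_peaks <- find_top_peaks(features$jerk_mode, b$peak_top_fraction, features$bin_start_s)
  roll_sd_peaks <- find_top_peaks(features$roll_sd, b$peak_top_fraction, features$bin_start_s)
  if (branch == "shallow") {
    flow_peaks <- filter_short_runs(flow_peaks, b$min_peak_run_bins)
    jerk_peaks <- filter_short_runs(jerk_peaks, b$min_peak_run_bins)
    roll_sd_peaks <- roll_criterion_filter(
      roll_sd_peaks, features$roll_mode,
      threshold_deg = config$roll_mode_threshold_deg,
      n_consecutive = config$roll_consecutive_bins,
      window_s = config$roll_check_window_s,
      times = features$bin_start_s,
      bin_width_s = config$bin_width_s
    )
  }
  jerk_drops <- find_jerk_drops(features$jerk_mode, b$jerk_bottom_fraction, features$bin_start_s)
  pair_and_filter(
    flow_peaks, jerk_peaks, roll_sd_peaks, jerk_drops,
    features$flow_mode,
    branch = branch, config = config, times = features$bin_start_s,
    debug = debug
  )
}

#' Detect lunge-feeding events in a tag record
#'
#' Runs the decision-tree detector: bins the derived series
#' ([bin_features()]), applies the shallow and the deep rule branch each over
#' the *whole* record (segmenting first would truncate signatures straddling
#' the depth split), keeps a shallow candidate only where the depth at its
#' time is below `depth_split_m` (30 m) and a deep candidate only at or
#' below it, merges the branches, and collapses duplicates within
#' `dedup_window_s` keeping the last of each cluster. The time of the flow-
#' noise peak is taken as the lunge time. Deterministic for a fixed
#' `(record, config)`.
#'
#' @param record A [tag_record()] carrying flow noise (or audio).
#' @param config A `lunge_config`; see [default_config()].
#' @param features Optional precomputed [bin_features()] output (skips
#'   recomputation).
#' @return A `lunge_detections` tibble: `time_s`, `depth_m` (interpolated at
#'   the detection time), `category` (`"shallow"` iff `depth_m <
#'   depth_split_m`).
#' @export
detect_lunges <- function(record, config = default_config(), features = NULL) {
  validate_config(config)
  if (is.null(features)) features <- bin_features(record, config)

  cands <- lapply(c("shallow", "deep"), function(br) {
    ts <- run_branch(features, br, config)
    if (length(ts) == 0L) return(numeric(0))
    d <- depth_at(record, ts)
    if (br == "shallow") ts[d < config$depth_split_m] else ts[d >= config$depth_split_m]
  })
  all_times <- sort(unique(c(cands[[1]], cands[[2]])))
  final <- dedup_detections(all_times, config$dedup_window_s)
  d <- depth_at(record, final)
  out <- tibble(
    time_s = final,
    depth_m = d,
    category = ifelse(d < config$depth_split_m, "shallow", "deep")
  )
  class(out) <- c("lunge_detections", class(out))
  out
}

#' Per-rule audit of detector candidates
#'
#' Runs one branch of the detector and reports every flow-noise peak with the
#' outcome of each pairing/exclusion rule, for inspection of why a candidate
#' survived or died.
#'
#' @inheritParams detect_lunges
#' @param branch `"shallow"` or `"deep"`.
#' @return A tibble with one row per flow peak and logical columns
#'   `in_record`, `has_jerk`, `has_roll`, `has_drop`, `has_jerk_min`, `kept`.
#' @export
detector_audit <- function(record, branch = c("shallow", "deep"),
                           config = default_config(), features = NULL) {
  branch <- match.arg(branch)
  validate_config(config)
  if (is.null(features)) features <- bin_features(record, config)
  run_branch(features, branch, config, debug = TRUE)
}
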