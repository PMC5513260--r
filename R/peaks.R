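# Run-length helpers over logical masks ---------------------------------

mask_runs <- function(mask) {
  if (length(mask) == 0L || !any(mask)) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

#' Top-fraction peak finder
#'
#' Tag placement varies between deployments, so absolute signal levels are
#' not comparable across whales; peaks are instead defined relative to each
#' record's own distribution. The threshold is the empirical
#' `1 - top_fraction` quantile (linear interpolation) of the binned series;
#' bins strictly above it are grouped into maximal consecutive runs and each
#' run contributes a single peak at its maximum bin (earliest bin on value
#' ties).
#'
#' @param values Numeric vector of binned values (one per bin).
#' @param top_fraction Fraction of the data treated as "high", in (0, 1)
#'   (0.16 for the shallow branch, 0.22 for the deep branch).
#' @param times Bin-start times, seconds; defaults to `0:(n-1)`.
#' @return A `peak_set` tibble: `time_s`, `value`, `run_start_s`,
#'   `run_length_bins`. A constant series yields no peaks (the strict
#'   inequality never fires).
#' @examples
#' find_top_peaks(c(0, 0, 5, 6, 5, 0, 0, 7, 0), 0.25)
#' @export
find_top_peaks <- function(values, top_fraction, times = seq_along(values) - 1) {
  if (length(values) == 0L) abort("`values` must be non-empty.")
  if (top_fraction <= 0 || top_fraction >= 1) abort("`top_fraction` must be in (0, 1).")
  thr <- quantile(values, 1 - top_fraction, names = FALSE, type = 7)
  runs <- mask_runs(values > thr)
  if (nrow(runs) == 0L) {
    return(peak_set(numeric(0), numeric(0), numeric(0), integer(0)))
  }
  peak_idx <- mapply(function(s, e) s + which.max(values[s:e]) - 1L, runs$start, runs$end)
  peak_set(
    time_s = times[peak_idx],
    value = values[peak_idx],
    run_start_s = times[runs$start],
    run_length_bins = runs$end - runs$start + 1L
  )
}

peak_set <- function(time_s, value, run_start_s, run_length_bins) {
  out <- tibble(
    time_s = as.numeric(time_s), value = as.numeric(value),
    run_start_s = as.numeric(run_start_s),
    run_length_bins = as.integer(run_length_bins)
  )
  class(out) <- c("peak_set", class(out))
  out
}

#' Jerk-drop finder (bottom-fraction runs)
#'
#' A lunge ends with the whale stalling as the engulfed water is processed,
#' visible as an interval of unusually low jerk. The threshold is the
#' empirical `bottom_fraction` quantile of the binned jerk mode; bins
#' strictly below it form maximal runs, and the first bin of each run marks
#' the time the jerk dropped.
#'
#' @param values Binned jerk-mode values.
#' @param bottom_fraction Fraction treated as "low", in (0, 1) (0.32 shallow,
#'   0.66 deep).
#' @param times Bin-start times, seconds; defaults to `0:(n-1)`.
#' @return Numeric vector of drop times (first bin of each sub-threshold
#'   run). An all-equal series yields none.
#' @export
find_jerk_drops <- function(values, bottom_fraction, times = seq_along(values) - 1) {
  if (length(values) == 0L) abort("`values` must be non-empty.")
  if (bottom_fraction <= 0 || bottom_fraction >= 1) abort("`bottom_fraction` must be in (0, 1).")
  thr <- quantile(values, bottom_fraction, names = FALSE, type = 7)
  runs <- mask_runs(values < thr)
  times[runs$start]
}

#' Remove peaks from short supra-threshold runs
#'
#' Shallow-branch rule: genuine lunge signatures stay elevated for a couple
#' of seconds, whereas surfacing impacts spike for a single bin, so jerk and
#' flow-noise peaks whose originating run spans fewer than `min_run_bins`
#' bins are discarded.
#'
#' @param peaks A `peak_set` from [find_top_peaks()].
#' @param min_run_bins Minimum run length (bins) for a peak to survive;
#'   default 2 (runs shorter than 2 s removed).
#' @return The filtered `peak_set`.
#' @export
filter_short_runs <- function(peaks, min_run_bins = 2) {
  stopifnot(is.data.frame(peaks), "run_length_bins" %in% names(peaks))
  peaks[peaks$run_length_bins >= min_run_bins, , drop = FALSE]
}

#' Roll-excursion criterion for roll-SD peaks
#'
#' Shallow lunges typically involve a sustained body roll. A roll-SD peak is
#' kept only if some run of at least `n_consecutive` consecutive bins with
#' `|roll mode| > threshold_deg` lies wholly within `window_s` seconds of the
#' peak (default: three 1 s bins over 20° within ±3 s).
#'
#' @param roll_sd_peaks A `peak_set` of roll-SD peaks.
#' @param roll_mode Binned roll-mode values, degrees.
#' @param threshold_deg Roll magnitude threshold, degrees. Default 20.
#' @param n_consecutive Required consecutive qualifying bins. Default 3.
#' @param window_s Half-width of the check window around each peak, seconds.
#'   Default 3.
#' @param times Bin-start times for `roll_mode`; defaults to `0:(n-1)`.
#' @param bin_width_s Bin width, seconds. Default 1.
#' @return The filtered `peak_set`.
#' @export
roll_criterion_filter <- function(roll_sd_peaks, roll_mode, threshold_deg = 20,
                                  n_consecutive = 3, window_s = 3,
                                  times = seq_along(roll_mode) - 1,
                                  bin_width_s = 1) {
  if (window_s < (n_consecutive - 1) * bin_width_s) {
    abort("`window_s` is too short to contain `n_consecutive` bins on one side.")
  }
  if (nrow(roll_sd_peaks) == 0L) return(roll_sd_peaks)
  qual <- abs(roll_mode) > threshold_deg
  keep <- vapply(roll_sd_peaks$time_s, function(p) {
    inside <- which(qual & times >= p - window_s & times <= p + window_s)
    if (length(inside) < n_consecutive) return(FALSE)
    # consecutive bin indices within the window
    r <- rle(diff(inside) == 1L)
    any(r$values & r$lengths >= n_consecutive - 1L)
  }, logical(1))
  roll_sd_peaks[keep, , drop = FALSE]
}

#' Collapse duplicate detections
#'
#' Lunges are separated by a physiological minimum interval (the engulfed
#' water must be filtered before the next lunge), so detections closer than
#' `window_s` are duplicates of one event. Clustering is transitive — while
#' successive gaps stay below `window_s` the cluster grows — and the final
#' time of each cluster is kept.
#'
#' @param times Sorted numeric vector of detection times, seconds.
#' @param window_s Duplicate window, seconds. Default 15.
#' @return Numeric vector of deduplicated times; all successive gaps are
#'   `>= window_s`.
#' @examples
#' dedup_detections(c(0, 10, 20, 30, 100), 15)
#' @export
dedup_detections <- function(times, window_s = 15) {
  if (length(times) <= 1L) return(times)
  if (is.unsorted(times)) abort("`times` must be sorted ascending.")
  new_cluster <- c(TRUE, diff(times) >= window_s)
  cluster_id <- cumsum(new_cluster)
  as.numeric(tapply(times, cluster_id, max))
}
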