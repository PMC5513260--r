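#' Default detector configuration
#'
#' Returns the full threshold set of the decision-tree lunge detector, one
#' sub-list per depth branch plus the shared windows and rules. The defaults
#' are the operating point tuned on the 19 fin whale deployments the detector
#' was developed on:
#'
#' * per branch: `peak_top_fraction` (fraction of bins counted as "high" for
#'   the flow/jerk/roll-SD peak finders; 0.16 shallow, 0.22 deep),
#'   `jerk_bottom_fraction` (fraction counted as "low" for the jerk-drop
#'   finder; 0.32 shallow, 0.66 deep), `flow_drop_db` (required flow-noise
#'   drop after the peak; 10 dB shallow, 15 dB deep), and
#'   `min_peak_run_bins` (supra-threshold runs shorter than this are
#'   discarded; 2 for shallow — the <2 s rule — and 1, i.e. no filtering,
#'   for deep).
#' * shared: `pair_window_flow_jerk_s` (5), `pair_window_roll_s` (10),
#'   `drop_window_s` (`c(8, 12)`), `jerk_min_window_s` (15),
#'   `surfacing_exclusion_s` (4), `roll_mode_threshold_deg` (20),
#'   `roll_consecutive_bins` (3), `roll_check_window_s` (3),
#'   `dedup_window_s` (15), `depth_split_m` (30), `match_tolerance_s` (10),
#'   `bin_width_s` (1), `flow_band_hz` (`c(66, 94)`), `flow_rate_hz` (5),
#'   `flow_floor_db` (-120), and the mode quantization steps
#'   `quant_flow_db` (0.5), `quant_roll_deg` (1), `quant_jerk_frac` (0.01,
#'   as a fraction of the record's 99th-percentile jerk) and
#'   `quant_jerk_step` (`NA`: an absolute jerk step in m/s³ that overrides
#'   the relative one, for records whose background jerk the relative step
#'   would not resolve).
#'
#' @return A `lunge_config` object (named list).
#' @examples
#' cfg <- default_config()
#' cfg$deep$flow_drop_db
#' @export
default_config <- function() {
  structure(
    list(
      shallow = list(
        peak_top_fraction = 0.16,
        jerk_bottom_fraction = 0.32,
        flow_drop_db = 10,
        min_peak_run_bins = 2
      ),
      deep = list(
        peak_top_fraction = 0.22,
        jerk_bottom_fraction = 0.66,
        flow_drop_db = 15,
        min_peak_run_bins = 1
      ),
      pair_window_flow_jerk_s = 5,
      pair_window_roll_s = 10,
      drop_window_s = c(8, 12),
      jerk_min_window_s = 15,
      surfacing_exclusion_s = 4,
      roll_mode_threshold_deg = 20,
      roll_consecutive_bins = 3,
      roll_check_window_s = 3,
      dedup_window_s = 15,
      depth_split_m = 30,
      match_tolerance_s = 10,
      bin_width_s = 1,
      flow_band_hz = c(66, 94),
      flow_rate_hz = 5,
      flow_floor_db = -120,
      quant_flow_db = 0.5,
      quant_roll_deg = 1,
      quant_jerk_frac = 0.01,
      quant_jerk_step = NA_real_
    ),
    class = "lunge_config"
  )
}

#' @export
print.lunge_config <- function(x, ...) {
  cat("<lunge_config>\n")
  for (br in c("shallow", "deep")) {
    cat(sprintf(
      "  %s: top %.0f%% peaks, bottom %.0f%% jerk drops, %g dB flow drop, min run %d bin(s)\n",
      br, 100 * x[[br]]$peak_top_fraction, 100 * x[[br]]$jerk_bottom_fraction,
      x[[br]]$flow_drop_db, x[[br]]$min_peak_run_bins
    ))
  }
  cat(sprintf(
    "  pairing %g s (jerk) / %g s (roll); drop window +%g..+%g s; dedup %g s; split %g m\n",
    x$pair_window_flow_jerk_s, x$pair_window_roll_s,
    x$drop_window_s[1], x$drop_window_s[2], x$dedup_window_s, x$depth_split_m
  ))
  invisible(x)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid config field '%s': %s", field, msg))
  }
  for (br in c("shallow", "deep")) {
    b <- cfg[[br]]
    chk(
      is.numeric(b$peak_top_fraction) && b$peak_top_fraction > 0 && b$peak_top_fraction < 1,
      paste0(br, ".peak_top_fraction"), "must be in (0, 1)"
    )
    chk(
      is.numeric(b$jerk_bottom_fraction) && b$jerk_bottom_fraction > 0 && b$jerk_bottom_fraction < 1,
      paste0(br, ".jerk_bottom_fraction"), "must be in (0, 1)"
    )
    chk(is.numeric(b$flow_drop_db) && b$flow_drop_db > 0, paste0(br, ".flow_drop_db"), "must be > 0")
    chk(
      is.numeric(b$min_peak_run_bins) && b$min_peak_run_bins >= 1,
      paste0(br, ".min_peak_run_bins"), "must be >= 1"
    )
  }
  for (f in c(
    "pair_window_flow_jerk_s", "pair_window_roll_s", "jerk_min_window_s",
    "surfacing_exclusion_s", "roll_mode_threshold_deg", "dedup_window_s",
    "depth_split_m", "match_tolerance_s", "bin_width_s", "flow_rate_hz",
    "quant_flow_db", "quant_roll_deg", "quant_jerk_frac", "roll_check_window_s"
  )) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && cfg[[f]] > 0, f, "must be a single positive number")
  }
  chk(
    is.numeric(cfg$drop_window_s) && length(cfg$drop_window_s) == 2L &&
      cfg$drop_window_s[1] > 0 && cfg$drop_window_s[1] < cfg$drop_window_s[2],
    "drop_window_s", "must be c(lo, hi) with 0 < lo < hi"
  )
  chk(
    is.numeric(cfg$flow_band_hz) && length(cfg$flow_band_hz) == 2L &&
      cfg$flow_band_hz[1] > 0 && cfg$flow_band_hz[1] < cfg$flow_band_hz[2],
    "flow_band_hz", "must be c(lo, hi) with 0 < lo < hi"
  )
  chk(
    is.numeric(cfg$roll_consecutive_bins) && cfg$roll_consecutive_bins >= 1,
    "roll_consecutive_bins", "must be >= 1"
  )
  chk(
    cfg$roll_check_window_s >= cfg$roll_consecutive_bins * cfg$bin_width_s - cfg$bin_width_s,
    "roll_check_window_s", "too short to hold roll_consecutive_bins bins on one side"
  )
  chk(is.numeric(cfg$flow_floor_db) && length(cfg$flow_floor_db) == 1L, "flow_floor_db", "must be a number")
  chk(
    is.numeric(cfg$quant_jerk_step) && length(cfg$quant_jerk_step) == 1L &&
      (is.na(cfg$quant_jerk_step) || cfg$quant_jerk_step > 0),
    "quant_jerk_step", "must be NA (relative quantization) or a positive number"
  )
  invisible(cfg)
}

#' Load a detector configuration from JSON
#'
#' Reads a (possibly partial) JSON object of overrides and merges it over
#' [default_config()]. Unknown keys are rejected so typos cannot silently
#' leave a threshold at its default; out-of-range values raise a validation
#' error naming the field. An empty JSON object yields the default
#' configuration.
#'
#' @param path Path to a JSON file, e.g. `{"deep": {"flow_drop_db": 12}}`.
#' @return A `lunge_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_lunge_config(ov)
}

#' Coerce a list of overrides to a detector configuration
#'
#' @param overrides Named list of overrides over [default_config()]; branch
#'   fields nest under `shallow` / `deep`.
#' @return A `lunge_config` object.
#' @export
as_lunge_config <- function(overrides = list()) {
  cfg <- default_config()
  if (length(overrides) == 0L) return(cfg)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    abort("Config overrides must be a named list / JSON object.")
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in names(overrides)) {
    if (key %in% c("shallow", "deep")) {
      sub <- overrides[[key]]
      unknown <- setdiff(names(sub), names(cfg[[key]]))
      if (length(unknown) > 0L) {
        abort(sprintf("Unknown config key(s) under '%s': %s", key, paste(unknown, collapse = ", ")))
      }
      for (sk in names(sub)) {
        if (!is.null(sub[[sk]])) cfg[[key]][[sk]] <- as.numeric(sub[[sk]])
      }
    } else if (!is.null(overrides[[key]])) {
      cfg[[key]] <- as.numeric(overrides[[key]])
    }
  }
  validate_config(cfg)
  cfg
}

#' Write a detector configuration to JSON
#'
#' @param config A `lunge_config` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
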