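#' Build a multisensor tag record
#'
#' A `tag_record` holds the synchronized sensor streams of one deployment:
#' triaxial acceleration and roll at the accelerometer rate, depth at its own
#' rate, and (optionally) a 5 Hz band-limited flow-noise level or the raw
#' hydrophone waveform it can be derived from. All series start at time 0 and
#' span the same interval; sample `i` (0-based) of a series at rate `fs` sits
#' at `i / fs` seconds.
#'
#' @param whale_id Character label for the deployment.
#' @param accel Numeric matrix or data frame with three columns (`ax`, `ay`,
#'   `az`), acceleration in m/s² (use `accel_units = "g"` to convert on
#'   construction).
#' @param fs_accel Accelerometer sampling rate, Hz (tags in the source study
#'   used 50, 200, 250 or 500 Hz; any positive rate is accepted).
#' @param depth Numeric vector, depth in meters (positive down).
#' @param fs_depth Depth sampling rate, Hz. Defaults to `fs_accel`.
#' @param roll Numeric vector, roll in degrees in \[-180, 180\], sampled at
#'   `fs_accel` (same length as `accel` rows).
#' @param flow_db Optional numeric vector, flow-noise level in dB (arbitrary
#'   reference) at `flow_rate_hz`.
#' @param flow_rate_hz Rate of the flow-noise series, Hz. Default 5.
#' @param audio Optional mono waveform (numeric vector) the flow-noise series
#'   can be computed from; requires `fs_audio`.
#' @param fs_audio Audio sampling rate, Hz.
#' @param accel_units Either `"m/s2"` (default) or `"g"`; in the latter case
#'   acceleration is multiplied by 9.80665 so jerk comes out in m/s³.
#'
#' @return An object of class `tag_record`: a list with tibbles `motion`
#'   (`t_s`, `ax`, `ay`, `az`, `roll_deg`), `depth` (`t_s`, `depth_m`), `flow`
#'   (`t_s`, `flow_db`, or `NULL`), optional `audio`, and scalars `whale_id`,
#'   `fs_accel`, `fs_depth`, `flow_rate_hz`, `duration_s`.
#' @examples
#' fs <- 50
#' n <- 60 * fs
#' rec <- tag_record(
#'   whale_id = "demo",
#'   accel = cbind(rnorm(n, sd = 0.05), rnorm(n, sd = 0.05), 9.81 + rnorm(n, sd = 0.05)),
#'   fs_accel = fs,
#'   depth = rep(12, n),
#'   roll = rnorm(n, sd = 2)
#' )
#' rec$duration_s
#' @export
tag_record <- function(whale_id, accel, fs_accel, depth, fs_depth = fs_accel,
                       roll, flow_db = NULL, flow_rate_hz = 5,
                       audio = NULL, fs_audio = NULL,
                       accel_units = c("m/s2", "g")) {
  accel_units <- match.arg(accel_units)
  accel <- as.matrix(accel)
  if (ncol(accel) != 3L) {
    abort("`accel` must have exactly three columns (ax, ay, az).")
  }
  storage.mode(accel) <- "double"
  if (accel_units == "g") accel <- accel * 9.80665
  if (!is.numeric(fs_accel) || length(fs_accel) != 1L || fs_accel <= 0) {
    abort("`fs_accel` must be a single positive number (Hz).")
  }
  if (!is.numeric(fs_depth) || length(fs_depth) != 1L || fs_depth <= 0) {
    abort("`fs_depth` must be a single positive number (Hz).")
  }
  n_acc <- nrow(accel)
  duration_s <- n_acc / fs_accel
  if (duration_s <= 0) abort("Record must have positive duration.")
  if (length(roll) != n_acc) {
    abort(sprintf(
      "Alignment error: `roll` has %d samples but `accel` has %d rows (roll is sampled at fs_accel).",
      length(roll), n_acc
    ))
  }
  if (any(abs(roll) > 180 + 1e-9, na.rm = TRUE)) {
    abort("`roll` must lie in [-180, 180] degrees.")
  }
  n_depth_expect <- round(fs_depth * duration_s)
  if (abs(length(depth) - n_depth_expect) > 1L) {
    abort(sprintf(
      "Alignment error: `depth` has %d samples; expected %d at fs_depth = %g Hz over %.3f s.",
      length(depth), n_depth_expect, fs_depth, duration_s
    ))
  }
  if (any(depth < -1e-9, na.rm = TRUE)) abort("`depth` must be non-negative (meters, positive down).")

  flow <- NULL
  if (!is.null(flow_db)) {
    n_flow_expect <- round(flow_rate_hz * duration_s)
    if (abs(length(flow_db) - n_flow_expect) > 1L) {
      abort(sprintf(
        "Alignment error: `flow_db` has %d samples; expected %d at %g Hz over %.3f s.",
        length(flow_db), n_flow_expect, flow_rate_hz, duration_s
      ))
    }
    flow <- tibble(
      t_s = (seq_along(flow_db) - 1) / flow_rate_hz,
      flow_db = as.numeric(flow_db)
    )
  }
  audio_field <- NULL
  if (!is.null(audio)) {
    if (is.null(fs_audio)) abort("`fs_audio` is required when `audio` is supplied.")
    audio_field <- list(samples = as.numeric(audio), fs = fs_audio)
  }

  structure(
    list(
      whale_id = as.character(whale_id),
      fs_accel = fs_accel,
      fs_depth = fs_depth,
      flow_rate_hz = flow_rate_hz,
      duration_s = duration_s,
      motion = tibble(
        t_s = (seq_len(n_acc) - 1) / fs_accel,
        ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
        roll_deg = as.numeric(roll)
      ),
      depth = tibble(
        t_s = (seq_along(depth) - 1) / fs_depth,
        depth_m = as.numeric(depth)
      ),
      flow = flow,
      audio = audio_field
    ),
    class = "tag_record"
  )
}

#' @export
print.tag_record <- function(x, ...) {
  cat(sprintf(
    "<tag_record> whale '%s': %.1f s at %g Hz accel / %g Hz depth%s%s\n",
    x$whale_id, x$duration_s, x$fs_accel, x$fs_depth,
    if (!is.null(x$flow)) sprintf(", flow noise at %g Hz", x$flow_rate_hz) else ", no flow noise",
    if (!is.null(x$audio)) sprintf(", audio at %g Hz", x$audio$fs) else ""
  ))
  cat(sprintf(
    "  depth range %.1f-%.1f m\n",
    min(x$depth$depth_m), max(x$depth$depth_m)
  ))
  invisible(x)
}

#' Interpolated depth at arbitrary times
#'
#' Linear interpolation of the depth series, clamped to the record ends.
#'
#' @param record A [tag_record()].
#' @param times_s Numeric vector of times, seconds from record start.
#' @return Numeric vector of depths, meters.
#' @export
depth_at <- function(record, times_s) {
  if (length(times_s) == 0L) return(numeric(0))
  if (nrow(record$depth) == 1L) return(rep(record$depth$depth_m, length(times_s)))
  approx(record$depth$t_s, record$depth$depth_m, xout = times_s, rule = 2)$y
}

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)
flow_path <- function(path) sub("\\.[Cc][Ss][Vv]$", "_flow.csv", path)

#' Read / write a tag record in the columnar sensor format
#'
#' The on-disk format is a plain CSV of the motion-rate streams (`t_s`, `ax`,
#' `ay`, `az`, `depth_m`, `roll_deg`) plus a JSON sidecar (same basename,
#' `.json`) holding `whale_id`, `fs_accel`, `fs_depth` and `accel_units`.
#' A 5 Hz flow-noise series, when present, travels in a second CSV
#' (`<base>_flow.csv`, columns `t_s`, `flow_db`). Acceleration is canonicalized
#' to m/s² at read time, so jerk is in m/s³ regardless of the tag's native
#' units. This format stores depth at the accelerometer rate; records with
#' `fs_depth != fs_accel` must be resampled before writing.
#'
#' @param path CSV file path.
#' @param accel_units Override for the sidecar's `accel_units` (`"m/s2"` or
#'   `"g"`); `NULL` (default) trusts the sidecar.
#' @return `read_record()` returns a [tag_record()]; `write_record()` returns
#'   `path` invisibly.
#' @export
read_record <- function(path, accel_units = NULL) {
  if (!file.exists(path)) abort(sprintf("Record file not found: %s", path))
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) abort(sprintf("Missing JSON sidecar: %s", sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (f in c("whale_id", "fs_accel", "fs_depth")) {
    if (is.null(sc[[f]])) abort(sprintf("Sidecar %s lacks required field '%s'.", sc_path, f))
  }
  units <- accel_units %||% sc$accel_units %||% "m/s2"
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t_s", "ax", "ay", "az", "depth_m", "roll_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Format error: sensor CSV lacks column(s) %s.", paste(missing_cols, collapse = ", ")))
  }
  flow_db <- NULL
  flow_rate <- sc$flow_rate_hz %||% 5
  fpath <- flow_path(path)
  if (file.exists(fpath)) {
    fdf <- readr::read_csv(fpath, show_col_types = FALSE, progress = FALSE)
    if (!all(c("t_s", "flow_db") %in% names(fdf))) {
      abort(sprintf("Format error: flow CSV %s lacks t_s/flow_db columns.", fpath))
    }
    flow_db <- fdf$flow_db
  }
  tag_record(
    whale_id = sc$whale_id,
    accel = as.matrix(df[, c("ax", "ay", "az")]),
    fs_accel = sc$fs_accel,
    depth = df$depth_m,
    fs_depth = sc$fs_depth,
    roll = df$roll_deg,
    flow_db = flow_db,
    flow_rate_hz = flow_rate,
    accel_units = units
  )
}

#' @rdname read_record
#' @param record A [tag_record()].
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "tag_record"))
  if (!isTRUE(all.equal(record$fs_depth, record$fs_accel))) {
    abort(paste(
      "The sensor CSV format stores depth at the accelerometer rate;",
      "resample depth to fs_accel before writing (fs_depth != fs_accel)."
    ))
  }
  df <- record$motion
  df$depth_m <- record$depth$depth_m[seq_len(nrow(df))]
  readr::write_csv(
    df[, c("t_s", "ax", "ay", "az", "depth_m", "roll_deg")],
    path
  )
  jsonlite::write_json(
    list(
      whale_id = record$whale_id,
      fs_accel = record$fs_accel,
      fs_depth = record$fs_depth,
      accel_units = "m/s2",
      flow_rate_hz = record$flow_rate_hz
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(record$flow)) {
    readr::write_csv(record$flow, flow_path(path))
  }
  invisible(path)
}

#' Read / write detection and ground-truth lists
#'
#' Detections and manually audited lunge times share one columnar format:
#' `time_s` (seconds from record start), `depth_m`, `category`
#' (`"shallow"`/`"deep"`).
#'
#' @param x A tibble with columns `time_s`, `depth_m`, `category`.
#' @param path CSV file path.
#' @return `read_detections()` returns a tibble sorted by `time_s`;
#'   `write_detections()` returns `path` invisibly.
#' @export
write_detections <- function(x, path) {
  need <- c("time_s", "depth_m", "category")
  if (!all(need %in% names(x))) {
    abort("Detections need columns time_s, depth_m, category.")
  }
  readr::write_csv(as_tibble(x)[, need], path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "depth_m", "category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Format error: %s lacks column(s) %s.", path, paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(df$category), c("shallow", "deep"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown category value(s): %s.", paste(bad, collapse = ", ")))
  }
  arrange(as_tibble(df[, need]), .data$time_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
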