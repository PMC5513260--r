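test_that("record construction aligns series and canonicalizes units", {
  fs <- 50
  n <- 60 * fs
  rec <- tag_record(
    whale_id = "w", accel = matrix(0, n, 3), fs_accel = fs,
    depth = rep(5, n), roll = rep(0, n)
  )
  expect_equal(nrow(rec$motion), 3000)
  expect_equal(rec$duration_s, 60)

  rec_g <- tag_record(
    whale_id = "w", accel = cbind(0, 0, rep(1, n)), fs_accel = fs,
    depth = rep(5, n), roll = rep(0, n), accel_units = "g"
  )
  expect_equal(rec_g$motion$az[1], 9.80665)

  # misaligned series are rejected with the offending stream named
  expect_error(
    tag_record("w", matrix(0, n, 3), fs, depth = rep(5, n / 2), roll = rep(0, n)),
    "depth"
  )
  expect_error(
    tag_record("w", matrix(0, n, 3), fs, depth = rep(5, n), roll = rep(0, 10)),
    "roll"
  )
  expect_error(
    tag_record("w", matrix(0, n, 3), fs, depth = rep(5, n), roll = rep(0, n),
               flow_db = rep(90, 37)),
    "flow_db"
  )
})

test_that("records round-trip through the CSV + sidecar format", {
  out <- generate_record(synthetic_spec(n_lunges = 2, seed = 11))
  rec <- out$record
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_record(rec, path)
  back <- read_record(path)

  expect_equal(back$whale_id, rec$whale_id)
  expect_equal(back$fs_accel, rec$fs_accel)
  expect_equal(back$duration_s, rec$duration_s)
  for (col in c("ax", "ay", "az", "roll_deg")) {
    expect_equal(back$motion[[col]], rec$motion[[col]], tolerance = 1e-9)
  }
  expect_equal(back$depth$depth_m, rec$depth$depth_m, tolerance = 1e-9)
  expect_equal(back$flow$flow_db, rec$flow$flow_db, tolerance = 1e-9)

  # sidecar units are honored on read
  sc <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  sc$accel_units <- "g"
  jsonlite::write_json(sc, sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  back_g <- read_record(path)
  expect_equal(back_g$motion$ax, rec$motion$ax * 9.80665, tolerance = 1e-9)

  expect_error(read_record(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("read_record rejects malformed sensor files", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  readr::write_csv(tibble::tibble(t_s = 0:9, ax = 0, ay = 0), path)
  jsonlite::write_json(
    list(whale_id = "w", fs_accel = 1, fs_depth = 1),
    file.path(dir, "bad.json"),
    auto_unbox = TRUE
  )
  expect_error(read_record(path), "az.*depth_m|lacks column")
})

test_that("default configuration pins the published decision table", {
  cfg <- default_config()
  expect_identical(cfg$shallow$peak_top_fraction, 0.16)
  expect_identical(cfg$deep$peak_top_fraction, 0.22)
  expect_identical(cfg$shallow$jerk_bottom_fraction, 0.32)
  expect_identical(cfg$deep$jerk_bottom_fraction, 0.66)
  expect_identical(cfg$shallow$flow_drop_db, 10)
  expect_identical(cfg$deep$flow_drop_db, 15)
  expect_identical(cfg$shallow$min_peak_run_bins, 2)
  expect_identical(cfg$pair_window_flow_jerk_s, 5)
  expect_identical(cfg$pair_window_roll_s, 10)
  expect_identical(cfg$drop_window_s, c(8, 12))
  expect_identical(cfg$jerk_min_window_s, 15)
  expect_identical(cfg$surfacing_exclusion_s, 4)
  expect_identical(cfg$roll_mode_threshold_deg, 20)
  expect_identical(cfg$roll_consecutive_bins, 3)
  expect_identical(cfg$dedup_window_s, 15)
  expect_identical(cfg$depth_split_m, 30)
  expect_identical(cfg$match_tolerance_s, 10)
  expect_identical(cfg$bin_width_s, 1)
  expect_identical(cfg$flow_band_hz, c(66, 94))
  expect_identical(cfg$flow_rate_hz, 5)
})

test_that("config JSON loading overrides, validates and round-trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "c.json")

  writeLines("{}", p)
  expect_equal(load_config(p), default_config())

  writeLines('{"deep": {"flow_drop_db": 12}}', p)
  cfg <- load_config(p)
  expect_equal(cfg$deep$flow_drop_db, 12)
  ref <- default_config()
  ref$deep$flow_drop_db <- 12
  expect_equal(cfg, ref)

  writeLines('{"deeep": {"flow_drop_db": 12}}', p)
  expect_error(load_config(p), "Unknown config key")
  writeLines('{"deep": {"flow_drop_dbb": 12}}', p)
  expect_error(load_config(p), "Unknown config key")
  writeLines('{"shallow": {"peak_top_fraction": 1.4}}', p)
  expect_error(load_config(p), "peak_top_fraction")
  writeLines('{"drop_window_s": [12, 8]}', p)
  expect_error(load_config(p), "drop_window_s")

  write_config(default_config(), p)
  expect_equal(load_config(p), default_config())
})

test_that("detections round-trip through CSV", {
  det <- tibble::tibble(
    time_s = c(10.5, 200.25), depth_m = c(12.125, 61.5),
    category = c("shallow", "deep")
  )
  p <- file.path(withr::local_tempdir(), "det.csv")
  write_detections(det, p)
  expect_equal(read_detections(p), det, tolerance = 1e-9)

  readr::write_csv(tibble::tibble(time_s = 1, depth_m = 2, category = "abyssal"), p)
  expect_error(read_detections(p), "category")
})
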