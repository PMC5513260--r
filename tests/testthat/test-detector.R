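test_that("top-fraction peak finder matches the brute-force oracle", {
  expect_equal(nrow(find_top_peaks(rep(3, 50), 0.22)), 0) # constant: strict > never fires

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(100)
    for (frac in c(0.16, 0.22, 0.5)) {
      got <- find_top_peaks(x, frac)
      want <- oracle_top_peaks(x, frac)
      expect_equal(got$time_s, want$time, info = sprintf("seed %d frac %g", seed, frac))
      expect_equal(got$value, want$value)
      expect_equal(as.numeric(got$run_length_bins), want$run_len)
    }
  }

  # one run of 4 supra-threshold bins collapses to its argmax
  x <- c(rep(0, 10), 5, 7, 9, 6, rep(0, 10))
  got <- find_top_peaks(x, 0.25)
  expect_equal(nrow(got), 1)
  expect_equal(got$time_s, 12) # 0-based bin of the 9
  expect_equal(got$run_length_bins, 4L)
})

test_that("jerk-drop finder returns the first bin of each low run", {
  # monotonically decreasing series: a single run starting at the first
  # sub-median bin
  x <- seq(100, 1, length.out = 50)
  got <- find_jerk_drops(x, 0.5)
  expect_equal(got, oracle_jerk_drops(x, 0.5))
  expect_length(got, 1)

  expect_length(find_jerk_drops(rep(2, 30), 0.5), 0) # all-equal: strict <

  # two separated low plateaus -> two drop times at the plateau starts
  x <- c(rep(10, 5), rep(0, 4), rep(10, 5), rep(0, 4), rep(10, 5))
  got <- find_jerk_drops(x, 0.32)
  expect_equal(got, c(5, 14))
  expect_equal(got, oracle_jerk_drops(x, 0.32))

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(80)
    expect_equal(find_jerk_drops(x, 0.66), oracle_jerk_drops(x, 0.66))
  }
})

test_that("short supra-threshold runs are removed in the shallow branch", {
  x <- c(rep(0, 5), 9, rep(0, 5), 5, 6, rep(0, 5)) # 1-bin spike + 2-bin run
  peaks <- find_top_peaks(x, 0.3)
  expect_equal(nrow(peaks), 2)
  kept <- filter_short_runs(peaks, min_run_bins = 2)
  expect_equal(kept$time_s, 12) # the 2-bin run survives, the spike dies

  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(120)
    want <- oracle_top_peaks(x, 0.16)
    want <- want[want$run_len >= 2, ]
    got <- filter_short_runs(find_top_peaks(x, 0.16), 2)
    expect_equal(got$time_s, want$time)
  }
})

test_that("roll criterion keeps peaks flanked by a sustained >20 degree roll", {
  roll_sd_peak <- find_top_peaks(c(rep(0, 10), 8, rep(0, 10)), 0.3)
  expect_equal(roll_sd_peak$time_s, 10)

  roll3 <- rep(0, 21); roll3[10:12] <- 25 # 3 consecutive bins centered on the peak
  expect_equal(nrow(roll_criterion_filter(roll_sd_peak, roll3)), 1)

  roll2 <- rep(0, 21); roll2[10:11] <- 25 # only 2 consecutive
  expect_equal(nrow(roll_criterion_filter(roll_sd_peak, roll2)), 0)

  expect_equal(nrow(roll_criterion_filter(roll_sd_peak, rep(0, 21))), 0)

  # negative roll counts via |mode|; run must lie wholly inside +/- 3 s
  rollneg <- rep(0, 21); rollneg[10:12] <- -25
  expect_equal(nrow(roll_criterion_filter(roll_sd_peak, rollneg)), 1)
  rollfar <- rep(0, 21); rollfar[15:17] <- 25 # starts 5 bins after the peak
  expect_equal(nrow(roll_criterion_filter(roll_sd_peak, rollfar)), 0)

  expect_error(
    roll_criterion_filter(roll_sd_peak, roll3, n_consecutive = 6, window_s = 2),
    "window"
  )
})

# A hand-built feature scene holding one deep-lunge candidate whose rule
# margins can be perturbed one at a time.
deep_scene <- function(jerk_offset_s = 4, drop_db = 16, drop_at_s = 10,
                       jerk_drop_s = 6, spoil_drop_peak = FALSE, n_bins = 120) {
  t <- 60 # the flow peak
  flow <- rep(95, n_bins) # baseline high enough that only a true drop passes
  flow[t + 1 + (-2:2)] <- c(97, 100, 106, 100, 97) # ramp to a peak at bin 60
  flow[t + 1 + drop_at_s] <- 106 - drop_db
  jerk <- rep(5, n_bins)
  jerk[t + jerk_offset_s + 1 + 0:1] <- c(40, 30) # 2-bin jerk run, peak paired with flow
  tj <- t + jerk_offset_s
  jerk[tj + jerk_drop_s + 1 + 0:2] <- 0 # low-jerk run after the jerk peak
  if (spoil_drop_peak) jerk[tj + jerk_drop_s + 1 + 3] <- 40 # jerk peak adjacent to the minimum
  list(flow = flow, jerk = jerk)
}

run_deep_scene <- function(sc, config = default_config()) {
  flow_peaks <- find_top_peaks(sc$flow, config$deep$peak_top_fraction)
  jerk_peaks <- find_top_peaks(sc$jerk, config$deep$peak_top_fraction)
  roll_peaks <- find_top_peaks(rep(0, length(sc$flow)), config$deep$peak_top_fraction)
  drops <- find_jerk_drops(sc$jerk, config$deep$jerk_bottom_fraction)
  pair_and_filter(flow_peaks, jerk_peaks, roll_peaks, drops, sc$flow,
    branch = "deep", config = config
  )
}

test_that("pairing and exclusion rules accept/reject constructed candidates", {
  # canonical deep candidate: jerk peak 4 s away, 16 dB drop at +10 s,
  # jerk drop 6 s after the jerk peak with no adjacent jerk peak
  expect_equal(run_deep_scene(deep_scene()), 60)

  # jerk peak 6 s from the flow peak: pairing window (5 s) fails
  expect_length(run_deep_scene(deep_scene(jerk_offset_s = 6)), 0)

  # only 12 dB of flow drop: deep branch demands 15
  expect_length(run_deep_scene(deep_scene(drop_db = 12)), 0)

  # drop outside the 8-12 s window fails
  expect_length(run_deep_scene(deep_scene(drop_at_s = 14)), 0)

  # a jerk peak within 4 s of the jerk minimum marks a surfacing: excluded
  expect_length(run_deep_scene(deep_scene(spoil_drop_peak = TRUE)), 0)

  # jerk minimum later than 15 s after the jerk peak fails
  expect_length(run_deep_scene(deep_scene(jerk_drop_s = 16)), 0)

  # a flow peak whose drop window runs off the record end is discarded
  sc <- deep_scene(n_bins = 71) # record ends 10 bins after the peak
  expect_length(run_deep_scene(sc), 0)
  aud <- pair_and_filter(
    find_top_peaks(sc$flow, 0.22), find_top_peaks(sc$jerk, 0.22),
    find_top_peaks(rep(0, 71), 0.22), find_jerk_drops(sc$jerk, 0.66),
    sc$flow, branch = "deep", debug = TRUE
  )
  expect_false(aud$in_record[aud$time_s == 60])
})

test_that("duplicate detections collapse transitively to the last time", {
  expect_equal(dedup_detections(c(100, 110), 15), 110)
  expect_equal(dedup_detections(42, 15), 42)
  expect_equal(dedup_detections(c(0, 10, 20, 30), 15), 30) # transitive chain
  expect_equal(dedup_detections(c(0, 10, 30, 100), 15), c(10, 30, 100))
  expect_error(dedup_detections(c(5, 1), 15), "sorted")

  # gap invariant on random sets
  for (seed in 1:5) {
    set.seed(seed)
    times <- sort(runif(30, 0, 400))
    out <- dedup_detections(times, 15)
    expect_true(all(diff(out) >= 15))
    expect_true(all(out %in% times))
  }
})

test_that("end-to-end detection recovers injected lunges and their categories", {
  # a quiet record produces no detections
  quiet <- generate_record(quiet_spec(seed = 2))
  expect_equal(nrow(detect_lunges(quiet$record)), 0)

  # five canonical deep lunges, all recovered within the match tolerance
  deep5 <- generate_record(synthetic_spec(n_lunges = 5, lunge_depths_m = rep(60, 5), seed = 31))
  det <- detect_lunges(deep5$record)
  expect_equal(nrow(det), 5)
  expect_true(all(det$category == "deep"))
  m <- match_detections(det, deep5$truth, tolerance_s = 10)
  expect_equal(nrow(m), 5)

  # lunges at 15 m and 60 m are categorized by interpolated depth
  mix <- generate_record(synthetic_spec(
    n_lunges = 2, lunge_times_s = c(60, 120), lunge_depths_m = c(15, 60),
    duration_s = 170, seed = 32
  ))
  det2 <- detect_lunges(mix$record)
  expect_equal(nrow(det2), 2)
  expect_equal(det2$category, c("shallow", "deep"))
  expect_true(all(abs(det2$depth_m - c(15, 60)) < 3))
  # every detection sits where the depth rule says its category must be
  expect_equal(det2$category, ifelse(det2$depth_m < 30, "shallow", "deep"))
})

test_that("detection is deterministic and monotone in the required flow drop", {
  out <- generate_record(synthetic_spec(seed = 33))
  a <- detect_lunges(out$record)
  b <- detect_lunges(out$record)
  expect_identical(a, b)

  # raising the required drop can only remove detections
  base <- detect_lunges(out$record)
  for (extra in c(3, 8, 30)) {
    cfg <- as_lunge_config(list(
      shallow = list(flow_drop_db = 10 + extra),
      deep = list(flow_drop_db = 15 + extra)
    ))
    stricter <- detect_lunges(out$record, cfg)
    expect_lte(nrow(stricter), nrow(base))
    expect_true(all(stricter$time_s %in% base$time_s))
  }
})
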