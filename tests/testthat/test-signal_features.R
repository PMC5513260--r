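test_that("flow-noise level behaves on silence and pure tones", {
  fs <- 1000
  silent <- compute_flow_noise(rep(0, fs * 2), fs, floor_db = -120)
  expect_true(all(silent$flow_db == -120))
  expect_equal(nrow(silent), 10)

  # 80 Hz unit sine sits mid-band; 0.2 s windows hold 16 full cycles,
  # so the level is the sinusoid RMS 1/sqrt(2) = -3.01 dB (up to the
  # filter's in-band ripple)
  x <- sin(2 * pi * 80 * (0:(4 * fs - 1)) / fs)
  lev <- compute_flow_noise(x, fs)
  expect_equal(lev$flow_db[5:15], rep(20 * log10(1 / sqrt(2)), 11), tolerance = 0.1)

  expect_error(compute_flow_noise(x, fs, band = c(66, 600)), "Nyquist")
  expect_error(compute_flow_noise(x[1:50], fs), "shorter")
})

test_that("band RMS agrees with an independent Fourier band-power oracle", {
  fs <- 1000
  set.seed(91)
  x <- rnorm(fs * 6)
  got <- compute_flow_noise(x, fs)
  want <- oracle_fft_band_db(x, fs, c(66, 94), 5)
  d <- got$flow_db - want
  # few Fourier bins per 0.2 s window, so individual windows scatter;
  # the two estimates agree on average well within 1 dB
  expect_lt(mean(abs(d)), 1)
  expect_lt(max(abs(d)), 3)
})

test_that("flow-noise level is invariant to audio polarity", {
  fs <- 1000
  set.seed(14)
  x <- rnorm(fs * 3)
  a <- compute_flow_noise(x, fs)
  b <- compute_flow_noise(-x, fs)
  expect_equal(a$flow_db, b$flow_db, tolerance = 0.1)
})

test_that("jerk is the rate-scaled norm of successive accelerometer differences", {
  # constant acceleration carries no jerk
  const <- compute_jerk(matrix(5, 100, 3), fs_accel = 50)
  expect_true(all(const$jerk == 0))
  expect_equal(nrow(const), 99)

  # a single (1, 2, 2) m/s² step at 50 Hz: 50 * sqrt(1+4+4) = 150 m/s³
  a <- rbind(c(0, 0, 0), c(1, 2, 2))
  expect_equal(compute_jerk(a, fs_accel = 50)$jerk, 150)

  # random series pinned against an element-wise loop oracle, exactly
  set.seed(7)
  m <- matrix(rnorm(300), ncol = 3)
  got <- compute_jerk(m, fs_accel = 250)
  want <- sapply(1:99, function(i) {
    250 * sqrt(sum((m[i + 1, ] - m[i, ])^2))
  })
  expect_identical(got$jerk, want)

  expect_error(compute_jerk(m[1, , drop = FALSE], fs_accel = 50), "at least 2")
})

test_that("jerk is invariant under constant acceleration offsets", {
  set.seed(8)
  m <- matrix(rnorm(600), ncol = 3)
  for (shift in list(c(1, -2, 9.81), c(100, 0, 0))) {
    shifted <- sweep(m, 2, shift, "+")
    expect_equal(
      compute_jerk(shifted, fs_accel = 50)$jerk,
      compute_jerk(m, fs_accel = 50)$jerk,
      tolerance = 1e-9
    )
  }
})

test_that("quantized mode counts after rounding and breaks ties low", {
  expect_equal(quantized_mode(c(rep(1.0, 30), rep(2.0, 20)), 0.5), 1.0)
  expect_equal(quantized_mode(c(1, 1, 2, 2), 1), 1) # tie -> smallest
  expect_equal(quantized_mode(c(0.24, 0.26, 0.26), 0.5), 0.5)
  expect_true(is.na(quantized_mode(numeric(0), 1)))
})

make_flat_record <- function(duration, fs = 50, roll = 10, depth = 5) {
  n <- round(duration * fs)
  tag_record(
    whale_id = "flat", accel = matrix(0, n, 3), fs_accel = fs,
    depth = rep(depth, n), roll = rep(roll, n),
    flow_db = rep(90, round(duration * 5))
  )
}

test_that("binned features: bin count, constant-roll bins, and modes", {
  feats <- bin_features(make_flat_record(61.4))
  expect_equal(nrow(feats), 61)
  expect_true(all(feats$roll_mode == 10))
  expect_true(all(feats$roll_sd == 0))
  expect_true(all(feats$depth_m == 5))
  expect_true(all(feats$flow_mode == 90))

  # a bin containing 30 samples of one level and 20 of another votes for
  # the majority level
  fs <- 50
  rec <- make_flat_record(2, fs = fs)
  rec$motion$roll_deg <- c(rep(1, 30), rep(2, 20), rep(2, 30), rep(1, 20))
  feats2 <- bin_features(rec)
  expect_equal(feats2$roll_mode, c(1, 2))
})

test_that("binned features have no cross-bin leakage", {
  out <- generate_record(synthetic_spec(n_lunges = 3, seed = 21))
  rec <- out$record
  cfg <- as_lunge_config(list(quant_jerk_step = 0.1)) # absolute step so halves are comparable
  full <- bin_features(rec, cfg)

  # rebuild the record from an aligned sub-interval and re-bin
  a <- 50; b <- 150
  fs <- rec$fs_accel
  idx_m <- which(rec$motion$t_s >= a & rec$motion$t_s < b)
  idx_f <- which(rec$flow$t_s >= a & rec$flow$t_s < b)
  sub <- tag_record(
    whale_id = "sub",
    accel = as.matrix(rec$motion[idx_m, c("ax", "ay", "az")]),
    fs_accel = fs,
    depth = rec$depth$depth_m[idx_m],
    roll = rec$motion$roll_deg[idx_m],
    flow_db = rec$flow$flow_db[idx_f]
  )
  sub_feats <- bin_features(sub, cfg)
  full_slice <- full[full$bin_start_s >= a & full$bin_start_s < b, ]
  for (col in c("jerk_mode", "flow_mode", "roll_mode", "roll_sd", "depth_m")) {
    expect_equal(sub_feats[[col]], full_slice[[col]], tolerance = 1e-9, info = col)
  }
})

test_that("binning reports gaps by bin", {
  rec <- make_flat_record(10)
  rec$flow <- rec$flow[-(21:25), ] # remove all 5 samples of bin 4
  expect_error(bin_features(rec), "bin 4")
})
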