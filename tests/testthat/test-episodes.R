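const_baseline <- function(n, fs = 4, level = 140) {
  structure(list(baseline_bpm = rep(level, n),
                 floating_line_bpm = rep(level, n), fs_hz = fs),
            class = "baseline_result")
}

# record with one clean trapezoidal excursion on a 140 bpm carrier
excursion_record <- function(amp, duration_s, start_s = 300,
                             total_min = 20, fs = 4) {
  n <- total_min * 60 * fs
  fhr <- 140 + amp * ctgsuite:::trapezoid_profile(n, fs, start_s, duration_s)
  ctg_record(fhr, fs_hz = fs)
}

test_that("FIGO accelerations and decelerations are detected with flags", {
  rec <- excursion_record(+20, 30)
  ep <- detect_accel_decel(rec, const_baseline(length(rec$fhr_bpm)))
  acc <- ep[ep$kind == "acceleration", ]
  expect_equal(nrow(acc), 1)
  expect_true(acc$figo_valid)
  expect_equal(acc$peak_deviation_bpm, 20)
  # above-threshold time of a 30-s/20-bpm trapezoid with 5-s ramps:
  # the +15 bpm level is crossed 15/20 of the way up each ramp
  expect_equal(acc$duration_s, 30 - 2 * 5 * 15 / 20, tolerance = 0.75)

  # 10 s is below the 15 s FIGO minimum
  ep10 <- detect_accel_decel(excursion_record(+20, 10),
                             const_baseline(length(rec$fhr_bpm)))
  expect_equal(sum(ep10$kind == "acceleration" & ep10$figo_valid), 0)

  # a 4-min deceleration is prolonged (240 s > 180 s)
  epd <- detect_accel_decel(excursion_record(-20, 240),
                            const_baseline(length(rec$fhr_bpm)))
  dec <- epd[epd$kind == "deceleration", ]
  expect_equal(nrow(dec), 1)
  expect_true(dec$prolonged)
  expect_true(dec$figo_valid)
  expect_equal(dec$peak_deviation_bpm, -20)
})

test_that("events supported by long interpolation are not FIGO-valid", {
  rec <- excursion_record(+20, 30, start_s = 300)
  # knock out 16 s of the acceleration's plateau, then refill
  gap <- (306 * 4):(322 * 4)
  fhr <- rec$fhr_bpm
  fhr[gap] <- 0
  rec2 <- interpolate_gaps(ctg_record(fhr, fs_hz = 4))
  ep <- detect_accel_decel(rec2, const_baseline(length(fhr)))
  acc <- ep[ep$kind == "acceleration", ]
  expect_gte(nrow(acc), 1)
  expect_true(all(!acc$figo_valid))
  expect_true(any(acc$overlaps_long_interpolation))
})

test_that("arrhythmia runs follow the threshold/duration definitions", {
  fs <- 4
  # normal band: nothing detected either way
  calm <- rep(150, 30 * 60 * fs)
  expect_equal(nrow(detect_arrhythmia(calm, "tachycardia", fs_hz = fs)), 0)
  expect_equal(nrow(detect_arrhythmia(calm, "bradycardia", fs_hz = fs)), 0)

  # 12 min above 160 -> one tachycardia of 12 min
  bl <- c(rep(140, 2400), rep(165, 12 * 60 * fs), rep(140, 2400))
  tach <- detect_arrhythmia(bl, "tachycardia", fs_hz = fs)
  expect_equal(nrow(tach), 1)
  expect_equal(tach$duration_s, 720)
  expect_false(tach$severe)

  # 2 min below 110 does not qualify (needs more than 3 min)
  bl2 <- c(rep(140, 2400), rep(105, 2 * 60 * fs), rep(140, 2400))
  expect_equal(nrow(detect_arrhythmia(bl2, "bradycardia", fs_hz = fs)), 0)

  # 11 min at 185 -> severe tachycardia
  bl3 <- c(rep(140, 2400), rep(185, 11 * 60 * fs), rep(140, 2400))
  tach3 <- detect_arrhythmia(bl3, "tachycardia", fs_hz = fs)
  expect_equal(nrow(tach3), 1)
  expect_true(tach3$severe)
})

test_that("duration bounds are inclusive for tachycardia, exclusive for bradycardia", {
  fs <- 4
  pad <- rep(140, 1200)
  # exactly 10 min above threshold qualifies ("at least 10 min")
  exactly10 <- c(pad, rep(161, 10 * 60 * fs), pad)
  expect_equal(nrow(detect_arrhythmia(exactly10, "tachycardia", fs_hz = fs)), 1)
  just_under <- c(pad, rep(161, 10 * 60 * fs - 1), pad)
  expect_equal(nrow(detect_arrhythmia(just_under, "tachycardia", fs_hz = fs)), 0)
  # exactly 3 min below threshold does NOT qualify ("more than 3 min")
  exactly3 <- c(pad, rep(109, 3 * 60 * fs), pad)
  expect_equal(nrow(detect_arrhythmia(exactly3, "bradycardia", fs_hz = fs)), 0)
  just_over <- c(pad, rep(109, 3 * 60 * fs + 1), pad)
  expect_equal(nrow(detect_arrhythmia(just_over, "bradycardia", fs_hz = fs)), 1)
  # samples exactly at the threshold never qualify (strict inequality)
  at160 <- c(pad, rep(160, 15 * 60 * fs), pad)
  expect_equal(nrow(detect_arrhythmia(at160, "tachycardia", fs_hz = fs)), 0)
})

test_that("arrhythmia detection agrees with the brute-force run oracle", {
  set.seed(99)
  fs <- 4
  for (trial in 1:200) {
    # random piecewise-constant baseline with segments around the thresholds
    n_seg <- sample(3:10, 1)
    lev <- sample(c(100, 105, 109, 110, 111, 140, 159, 160, 161, 170, 185),
                  n_seg, replace = TRUE)
    len <- sample(c(30, 170, 180, 190, 400, 590, 600, 610, 800), n_seg,
                  replace = TRUE) * fs
    bl <- rep(lev, times = len)
    valid <- rep(TRUE, length(bl))
    if (trial %% 3 == 0) valid[sample.int(length(bl), 50)] <- FALSE
    for (kind in c("tachycardia", "bradycardia")) {
      got <- detect_arrhythmia(bl, kind, fs_hz = fs, valid = valid)
      want <- oracle_arrhythmia(bl, fs, kind, valid = valid)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start_idx, want[, 1])
        expect_equal(got$end_idx - 1L, want[, 2])
      }
    }
  }
})

test_that("episodes of one kind never overlap and counts ignore in-band padding", {
  fs <- 4
  bl <- c(rep(140, 1200), rep(165, 2500), rep(150, 400), rep(170, 2600),
          rep(140, 1200))
  tach <- detect_arrhythmia(bl, "tachycardia", fs_hz = fs)
  expect_equal(nrow(tach), 2)
  expect_true(all(tach$end_idx[-nrow(tach)] <= tach$start_idx[-1]))
  # adding in-band samples at the edges leaves counts unchanged
  bl_pad <- c(rep(120, 2000), bl, rep(155, 2000))
  expect_equal(nrow(detect_arrhythmia(bl_pad, "tachycardia", fs_hz = fs)), 2)
})

test_that("an injected event round-trips through generation and detection", {
  cfg <- synthetic_config(duration_min = 20, variability_sd_bpm = 0,
                          lf_amp_bpm = 0, hf_amp_bpm = 0,
                          events = list(list(kind = "acceleration",
                                             start_s = 400, duration_s = 40,
                                             amplitude_bpm = 22)),
                          uc_count = 0L, seed = 5)
  rec <- generate_record(cfg)$record
  bl <- estimate_baseline(rec)
  ep <- detect_accel_decel(rec, bl)
  acc <- ep[ep$kind == "acceleration" & ep$figo_valid, ]
  expect_equal(nrow(acc), 1)
  expect_equal(acc$peak_deviation_bpm, 22, tolerance = 1)
  # the detected interval is the stretch above +15 bpm: the trapezoid
  # crosses 15/22 of the 5-s ramp in, and back out at the far edge
  cross <- 5 * 15 / 22
  expect_equal(acc$start_s, 400 + cross, tolerance = 0.5)
  expect_equal(acc$end_s, 440 - cross, tolerance = 0.5)
})
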