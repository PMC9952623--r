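# Episode tables: one row per detected interval event. Columns:
#   kind        "acceleration" | "deceleration" | "tachycardia" | "bradycardia"
#   start_idx   first sample of the run (1-based, inclusive)
#   end_idx     one past the last sample (half-open, so end_idx - start_idx
#               is the run length in samples)
#   start_s/end_s/duration_s   timing in seconds
#   peak_deviation_bpm  signed extreme deviation (from the baseline for
#               accelerations/decelerations, from the 110-160 bpm normal
#               band edge for arrhythmias)
#   mean_bpm    mean FHR (or baseline) level over the run
#   prolonged   deceleration longer than the prolonged threshold
#   severe      tachycardia run with mean level above the severe threshold
#   figo_valid  episode satisfies the FIGO definition and is not supported
#               by long interpolation
#   overlaps_long_interpolation  any sample of the run lies in a long
#               interpolated gap

empty_episode_table <- function() {
  data.frame(kind = character(0), start_idx = integer(0), end_idx = integer(0),
             start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
             peak_deviation_bpm = numeric(0), mean_bpm = numeric(0),
             prolonged = logical(0), severe = logical(0),
             figo_valid = logical(0),
             overlaps_long_interpolation = logical(0))
}

episode_row <- function(kind, start, end_incl, fs, peak_dev, mean_bpm,
                        prolonged = FALSE, severe = FALSE,
                        figo_valid = TRUE, overlaps_long = FALSE) {
  data.frame(kind = kind, start_idx = as.integer(start),
             end_idx = as.integer(end_incl) + 1L,
             start_s = (start - 1L) / fs, end_s = end_incl / fs,
             duration_s = (end_incl - start + 1L) / fs,
             peak_deviation_bpm = peak_dev, mean_bpm = mean_bpm,
             prolonged = prolonged, severe = severe, figo_valid = figo_valid,
             overlaps_long_interpolation = overlaps_long)
}

#' Detect accelerations and decelerations
#'
#' Scans the deviation of the FHR from the baseline for FIGO-style events:
#' accelerations are excursions of at least `min_amplitude_bpm` above the
#' baseline sustained for at least `min_duration_s`; decelerations are the
#' mirrored excursions below. An acceleration lasting `max_accel_duration_s`
#' or longer is considered a baseline shift rather than an event and a
#' deceleration longer than `prolonged_decel_s` is flagged `prolonged`.
#' Episodes overlapping a long interpolated gap (see [interpolate_gaps()])
#' are kept in the table but marked `figo_valid = FALSE`, so they are
#' excluded from feature counts. Excursions shorter than `candidate_min_s`
#' are treated as noise and not reported; excursions between
#' `candidate_min_s` and `min_duration_s` are reported with
#' `figo_valid = FALSE`.
#'
#' Events are macroscopic excursions, so the threshold scan runs on the
#' deviation smoothed with a `smooth_s`-second centered moving average;
#' beat-to-beat variability would otherwise fragment a genuine event into
#' sub-threshold-duration pieces. Peak deviations are read off the raw
#' (unsmoothed) deviation.
#'
#' @param record an interpolated [ctg_record()].
#' @param baseline the matching [estimate_baseline()] result.
#' @param min_amplitude_bpm FIGO amplitude threshold, bpm (default 15).
#' @param min_duration_s FIGO duration threshold, seconds (default 15).
#' @param max_accel_duration_s accelerations at or above this duration are
#'   not FIGO-valid (default 600 s).
#' @param prolonged_decel_s decelerations strictly longer than this are
#'   flagged prolonged (default 180 s).
#' @param candidate_min_s shortest excursion reported at all (default 10 s).
#' @param smooth_s moving-average length for the threshold scan, seconds;
#'   0 disables smoothing.
#' @return An episode table (see package source for the column contract),
#'   sorted by start index; episodes of one kind never overlap.
#' @export
detect_accel_decel <- function(record, baseline, min_amplitude_bpm = 15,
                               min_duration_s = 15,
                               max_accel_duration_s = 600,
                               prolonged_decel_s = 180,
                               candidate_min_s = 10, smooth_s = 5) {
  stopifnot(inherits(record, "ctg_record"), inherits(baseline, "baseline_result"))
  if (length(baseline$baseline_bpm) != length(record$fhr_bpm)) {
    stop_contract("baseline length does not match the record")
  }
  fs <- record$fs_hz
  dev <- record$fhr_bpm - baseline$baseline_bpm
  k <- max(1L, as.integer(round(smooth_s * fs)))
  dev_smooth <- if (k > 1L) {
    sm <- as.numeric(stats::filter(dev, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- dev[is.na(sm)]
    sm
  } else {
    dev
  }
  out <- empty_episode_table()
  eps <- 1e-9

  scan_one <- function(kind, mask, sign) {
    runs <- logical_runs(mask)
    rows <- lapply(seq_len(nrow(runs)), function(i) {
      s <- runs$start[i]; e <- runs$end[i]
      dur <- (e - s + 1L) / fs
      if (dur + eps < candidate_min_s) return(NULL)
      seg <- dev[s:e]
      peak <- if (sign > 0) max(seg) else min(seg)
      overlaps <- any(record$long_interp_mask[s:e])
      meets_figo <- dur + eps >= min_duration_s
      if (kind == "acceleration") {
        meets_figo <- meets_figo && dur < max_accel_duration_s - eps
      }
      episode_row(kind, s, e, fs, peak,
                  mean_bpm = mean(record$fhr_bpm[s:e]),
                  prolonged = kind == "deceleration" && dur > prolonged_decel_s + eps,
                  figo_valid = meets_figo && !overlaps,
                  overlaps_long = overlaps)
    })
    do.call(rbind, c(list(empty_episode_table()), rows))
  }

  out <- rbind(scan_one("acceleration", dev_smooth >= min_amplitude_bpm, +1),
               scan_one("deceleration", dev_smooth <= -min_amplitude_bpm, -1))
  out[order(out$start_idx), , drop = FALSE]
}

#' Detect tachycardia or bradycardia on the baseline vector
#'
#' Tachycardia is a rise of the baseline FHR above `tachy_bpm` (default
#' 160 bpm, strict inequality) lasting at least `tachy_min_s` (default
#' 10 min); a run whose mean level exceeds `severe_tachy_bpm` (default
#' 180 bpm) is flagged `severe`. Bradycardia is a decline below `brady_bpm`
#' (default 110 bpm, strict) lasting strictly more than `brady_min_s`
#' (default 3 min). Samples marked invalid in `valid` (for instance samples
#' that were originally missing) terminate a run.
#'
#' @param baseline a [estimate_baseline()] result or a numeric baseline
#'   vector in bpm.
#' @param kind `"tachycardia"` or `"bradycardia"`.
#' @param fs_hz sampling frequency; taken from `baseline` when it is a
#'   `baseline_result`.
#' @param valid optional logical vector; `FALSE` samples break runs.
#' @param tachy_bpm,brady_bpm level thresholds in bpm.
#' @param tachy_min_s minimum tachycardia duration, seconds (inclusive).
#' @param brady_min_s bradycardia duration bound, seconds (exclusive).
#' @param severe_tachy_bpm severe-tachycardia mean-level threshold, bpm.
#' @return An episode table with one row per qualifying run.
#' @export
#' @examples
#' bl <- c(rep(140, 2400), rep(165, 2880), rep(140, 2400))
#' detect_arrhythmia(bl, "tachycardia", fs_hz = 4)
detect_arrhythmia <- function(baseline, kind = c("tachycardia", "bradycardia"),
                              fs_hz = NULL, valid = NULL,
                              tachy_bpm = 160, brady_bpm = 110,
                              tachy_min_s = 600, brady_min_s = 180,
                              severe_tachy_bpm = 180) {
  kind <- match.arg(kind)
  if (inherits(baseline, "baseline_result")) {
    fs_hz <- fs_hz %||% baseline$fs_hz
    baseline <- baseline$baseline_bpm
  }
  if (is.null(fs_hz)) stop_contract("fs_hz is required for a bare baseline vector")
  if (length(baseline) == 0L) stop_contract("baseline vector is empty")
  valid <- valid %||% rep(TRUE, length(baseline))
  stopifnot(length(valid) == length(baseline))

  if (kind == "tachycardia") {
    mask <- valid & baseline > tachy_bpm
    min_n <- as.integer(ceiling(tachy_min_s * fs_hz - 1e-9))   # "at least"
  } else {
    mask <- valid & baseline < brady_bpm
    min_n <- as.integer(floor(brady_min_s * fs_hz + 1e-9)) + 1L # "more than"
  }
  runs <- logical_runs(mask)
  runs <- runs[runs$length >= min_n, , drop = FALSE]
  rows <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    seg <- baseline[s:e]
    m <- mean(seg)
    peak <- if (kind == "tachycardia") max(seg) - tachy_bpm else min(seg) - brady_bpm
    episode_row(kind, s, e, fs_hz, peak, mean_bpm = m,
                severe = kind == "tachycardia" && m > severe_tachy_bpm)
  })
  do.call(rbind, c(list(empty_episode_table()), rows))
}

#' Detect all episode kinds of a record
#'
#' Convenience wrapper running [detect_accel_decel()] and both
#' [detect_arrhythmia()] kinds and returning one combined episode table.
#'
#' The arrhythmia run scan uses the floating line (the 2-minute median
#' trend): it is insensitive to FIGO-duration accelerations and
#' decelerations yet responsive enough to resolve the 3-minute bradycardia
#' duration bound, which a 10-minute baseline trend cannot represent.
#' Because arrhythmia episodes live on a 3--10-minute scale, runs are not
#' broken by interpolated dropouts (the reconstructed trend inside a
#' sustained episode inherits the elevated/depressed level of its flanks);
#' instead, an episode in which more than `max_long_interp_fraction` of the
#' samples come from long interpolation is considered unsupported by
#' measured data and discarded.
#'
#' @inheritParams detect_accel_decel
#' @param max_long_interp_fraction largest tolerated fraction of
#'   long-interpolation samples inside an arrhythmia episode.
#' @param ... passed on to [detect_accel_decel()].
#' @return combined episode table sorted by start index.
#' @export
detect_episodes <- function(record, baseline, max_long_interp_fraction = 0.5,
                            ...) {
  arr <- rbind(
    detect_arrhythmia(baseline$floating_line_bpm, "tachycardia",
                      fs_hz = baseline$fs_hz),
    detect_arrhythmia(baseline$floating_line_bpm, "bradycardia",
                      fs_hz = baseline$fs_hz)
  )
  if (nrow(arr) > 0L) {
    frac <- vapply(seq_len(nrow(arr)), function(i) {
      mean(record$long_interp_mask[arr$start_idx[i]:(arr$end_idx[i] - 1L)])
    }, numeric(1))
    arr$overlaps_long_interpolation <- frac > 0
    arr <- arr[frac <= max_long_interp_fraction, , drop = FALSE]
  }
  ep <- rbind(detect_accel_decel(record, baseline, ...), arr)
  ep[order(ep$start_idx), , drop = FALSE]
}
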