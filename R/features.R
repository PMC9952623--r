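#' CTG feature row
#'
#' The per-trace feature vector consumed by annotation and classification:
#' mean baseline level (BL), bradycardia and tachycardia episode counts
#' (BRAD, TACH), FIGO-valid acceleration and deceleration counts (ACC,
#' DEC), uterine contraction count (UC), the mean short-term variability
#' (STV), the spectral band powers (VLF, LF, HF), total power, and the
#' sympatho-vagal balance (SVB), plus the derived alarm flags
#' `severe_tach`, `prolonged_dec` and `stv_absent`.
#'
#' @param bl_bpm mean baseline level, bpm.
#' @param brad,tach,acc,dec,uc_count non-negative episode/contraction counts.
#' @param severe_tach any tachycardia episode with mean level above 180 bpm.
#' @param prolonged_dec any deceleration longer than 3 min.
#' @param stv mean STV, bpm.
#' @param stv_absent STV below the absent-variability alarm level (0.02).
#' @param vlf,lf,hf,total_power spectral band powers, bpm^2.
#' @param svb sympatho-vagal balance (LF/HF); `NA` when undefined.
#' @param record_id identifier carried through reports.
#' @return An object of class `ctg_features` (named list).
#' @export
#' @examples
#' ctg_features(acc = 8, stv = 1.46, vlf = 4.36, lf = 2.61, hf = 0.22)
ctg_features <- function(bl_bpm = NA_real_, brad = 0L, tach = 0L,
                         severe_tach = FALSE, acc = 0L, dec = 0L,
                         prolonged_dec = FALSE, uc_count = 0L,
                         stv = NA_real_, stv_absent = FALSE,
                         vlf = NA_real_, lf = NA_real_, hf = NA_real_,
                         total_power = NA_real_, svb = NULL,
                         record_id = "ctg") {
  if (is.null(svb)) {
    svb <- if (!is.na(hf) && !is.na(lf) && hf > 0) lf / hf else NA_real_
  }
  counts <- c(brad = brad, tach = tach, acc = acc, dec = dec, uc = uc_count)
  if (any(counts < 0)) stop_contract("episode counts must be non-negative")
  if (severe_tach && tach < 1) {
    stop_contract("severe_tach requires at least one tachycardia episode")
  }
  if (!is.na(stv) && stv < 0) stop_contract("stv must be non-negative")
  structure(list(
    record_id = record_id, bl_bpm = bl_bpm,
    brad = as.integer(brad), tach = as.integer(tach),
    severe_tach = isTRUE(severe_tach),
    acc = as.integer(acc), dec = as.integer(dec),
    prolonged_dec = isTRUE(prolonged_dec),
    uc_count = as.integer(uc_count),
    stv = stv, stv_absent = isTRUE(stv_absent),
    vlf = vlf, lf = lf, hf = hf, total_power = total_power, svb = svb
  ), class = "ctg_features")
}

#' @export
print.ctg_features <- function(x, ...) {
  cat(sprintf("<ctg_features> %s\n", x$record_id))
  cat(sprintf("  BL %.2f | BRAD %d | TACH %d%s | ACC %d | DEC %d%s | UC %d\n",
              x$bl_bpm, x$brad, x$tach, if (x$severe_tach) " (severe)" else "",
              x$acc, x$dec, if (x$prolonged_dec) " (prolonged)" else "",
              x$uc_count))
  cat(sprintf("  STV %.2f%s | VLF %.2f | LF %.2f | HF %.2f | SVB %s\n",
              x$stv, if (x$stv_absent) " (absent)" else "",
              x$vlf, x$lf, x$hf,
              if (is.na(x$svb)) "undefined" else sprintf("%.2f", x$svb)))
  invisible(x)
}

#' @export
as.data.frame.ctg_features <- function(x, ...) {
  data.frame(record_id = x$record_id, BL = x$bl_bpm, BRAD = x$brad,
             TACH = x$tach, severe_tach = x$severe_tach, ACC = x$acc,
             DEC = x$dec, prolonged_dec = x$prolonged_dec, UC = x$uc_count,
             STV = x$stv, stv_absent = x$stv_absent, VLF = x$vlf, LF = x$lf,
             HF = x$hf, TotalPower = x$total_power, SVB = x$svb)
}

#' Count uterine contractions
#'
#' Contractions are counted as connected regions of the smoothed UC trace
#' rising at least `rise_au` arbitrary units above the basal tone (the
#' 10th percentile of the trace) for at least `min_duration_s` seconds.
#'
#' @param record a [ctg_record()] with a UC channel.
#' @param rise_au minimum rise above basal tone, arbitrary units.
#' @param min_duration_s minimum contraction duration, seconds.
#' @param smooth_s moving-average smoothing length, seconds.
#' @return integer contraction count (0 when no UC channel is present).
#' @export
count_contractions <- function(record, rise_au = 10, min_duration_s = 30,
                               smooth_s = 15) {
  stopifnot(inherits(record, "ctg_record"))
  if (is.null(record$uc)) return(0L)
  fs <- record$fs_hz
  k <- max(1L, as.integer(round(smooth_s * fs)))
  uc <- as.numeric(stats::filter(record$uc, rep(1 / k, k), sides = 2))
  uc[is.na(uc)] <- record$uc[is.na(uc)]
  tone <- stats::quantile(uc, 0.10, names = FALSE)
  runs <- logical_runs(uc > tone + rise_au)
  sum(runs$length / fs >= min_duration_s)
}

#' Extract the full feature row of a CTG record
#'
#' Runs the complete analysis pipeline: gap interpolation, baseline and
#' floating-line estimation, acceleration/deceleration and arrhythmia
#' detection, contraction counting, STV, and STFT band powers, and collects
#' the results into a [ctg_features()] row. Counts include FIGO-valid
#' episodes only.
#'
#' @param record a [ctg_record()] (interpolated or not).
#' @param spectral a [spectral_config()].
#' @param stv_window_s STV analysis window, seconds.
#' @param long_gap_s long-interpolation threshold passed to
#'   [interpolate_gaps()].
#' @param ... further arguments passed to [detect_accel_decel()].
#' @return a [ctg_features()] object.
#' @export
extract_features <- function(record, spectral = spectral_config(),
                             stv_window_s = 30, long_gap_s = 15, ...) {
  record <- interpolate_gaps(record, long_gap_s = long_gap_s)
  bl <- estimate_baseline(record)
  ep <- detect_episodes(record, bl, ...)

  acc <- ep[ep$kind == "acceleration" & ep$figo_valid, , drop = FALSE]
  dec <- ep[ep$kind == "deceleration" & ep$figo_valid, , drop = FALSE]
  tach <- ep[ep$kind == "tachycardia", , drop = FALSE]
  brad <- ep[ep$kind == "bradycardia", , drop = FALSE]

  fhrv <- compute_fhrv(record, bl, window_s = stv_window_s)
  stv <- compute_stv(fhrv, window_s = stv_window_s)
  est <- compute_mean_psd(fhrv, spectral)

  ctg_features(
    bl_bpm = mean(bl$baseline_bpm),
    brad = nrow(brad), tach = nrow(tach),
    severe_tach = any(tach$severe),
    acc = nrow(acc), dec = nrow(dec),
    prolonged_dec = any(dec$prolonged),
    uc_count = count_contractions(record),
    stv = stv$stv_mean, stv_absent = stv$stv_absent,
    vlf = est$band_power[["VLF"]], lf = est$band_power[["LF"]],
    hf = est$band_power[["HF"]], total_power = est$total_power,
    svb = est$svb, record_id = record$record_id
  )
}
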