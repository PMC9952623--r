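#' Quality screening of a CTG record
#'
#' Computes duration, signal loss and outlier percentages, and checks the
#' record against the eligibility criteria used for antepartum CTG studies:
#' antepartum recording between gestational weeks 36 and 40, duration above
#' 20 minutes, signal loss below 30%, outliers below 5%, and a singleton
#' pregnancy. Ineligibility is a report outcome, never an error, so
#' ineligible records can still be inspected.
#'
#' Signal loss counts samples that were never measured (sentinel 0 or `NA`).
#' Outliers count measured samples rejected by the artifact rules of
#' [ctg_record()] (outside the physiological range, or isolated jumps above
#' `max_jump_bpm`). Both percentages are relative to the total sample count.
#'
#' @param record a [ctg_record()].
#' @param min_duration_min minimum recording duration in minutes (exclusive).
#' @param max_loss_pct maximum tolerated signal loss, percent (exclusive).
#' @param max_outlier_pct maximum tolerated outlier percentage (exclusive).
#' @param week_range inclusive gestational-week window for eligibility.
#' @return An object of class `quality_report`: list with `duration_min`,
#'   `signal_loss_pct`, `outlier_pct`, `eligible` and `reasons` (character
#'   vector of failed-criterion labels, empty when eligible).
#' @export
#' @examples
#' rec <- ctg_record(rep(140, 4 * 60 * 30), fs_hz = 4)
#' assess_quality(rec)
assess_quality <- function(record, min_duration_min = 20,
                           max_loss_pct = 30, max_outlier_pct = 5,
                           week_range = c(36L, 40L)) {
  stopifnot(inherits(record, "ctg_record"))
  n <- length(record$fhr_bpm)
  cls <- derive_valid_mask(record$fhr_bpm, record$phys_range,
                           record$max_jump_bpm)
  # Interpolated samples were originally missing: count them as loss.
  missing <- cls$missing | record$interpolated_mask
  outlier <- cls$outlier & !record$interpolated_mask
  duration_min <- record_duration_min(record)
  signal_loss_pct <- 100 * sum(missing) / n
  outlier_pct <- 100 * sum(outlier) / n

  reasons <- character(0)
  if (!record$antepartum) reasons <- c(reasons, "not_antepartum")
  wk <- record$gestational_week
  if (is.na(wk) || wk < week_range[1] || wk > week_range[2]) {
    reasons <- c(reasons, "gestational_week_out_of_range")
  }
  if (!(duration_min > min_duration_min)) reasons <- c(reasons, "duration_too_short")
  if (!(signal_loss_pct < max_loss_pct)) reasons <- c(reasons, "signal_loss_too_high")
  if (!(outlier_pct < max_outlier_pct)) reasons <- c(reasons, "outliers_too_high")
  if (!record$singleton) reasons <- c(reasons, "not_singleton")

  structure(list(
    record_id = record$record_id,
    duration_min = duration_min,
    signal_loss_pct = signal_loss_pct,
    outlier_pct = outlier_pct,
    eligible = length(reasons) == 0L,
    reasons = reasons
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s\n", x$record_id))
  cat(sprintf("  duration: %.1f min, signal loss: %.1f%%, outliers: %.1f%%\n",
              x$duration_min, x$signal_loss_pct, x$outlier_pct))
  if (x$eligible) cat("  eligible: yes\n")
  else cat("  eligible: no (", paste(x$reasons, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Fill invalid samples by linear interpolation
#'
#' Missing and artifact samples are replaced by linear interpolation between
#' the flanking valid samples; leading and trailing invalid runs are filled
#' by extending the nearest valid value. Runs of invalid samples longer than
#' `long_gap_s` seconds are additionally flagged in `long_interp_mask` so
#' that event detection can invalidate episodes supported only by long
#' stretches of reconstructed signal. The operation is idempotent.
#'
#' @param record a [ctg_record()] with at least two valid samples.
#' @param long_gap_s gap duration (seconds) above which interpolated samples
#'   are flagged as long interpolation. Default 15 s.
#' @return The record with all samples filled, `interpolated_mask` marking
#'   reconstructed samples and `long_interp_mask` marking long-gap fills.
#' @export
interpolate_gaps <- function(record, long_gap_s = 15) {
  stopifnot(inherits(record, "ctg_record"))
  n <- length(record$fhr_bpm)
  has_value <- record$valid_mask | record$interpolated_mask
  if (sum(record$valid_mask) < 2L) {
    stop_insufficient("interpolate_gaps needs at least two valid samples")
  }
  if (all(has_value)) return(record)

  anchor_idx <- which(record$valid_mask)
  filled <- record$fhr_bpm
  to_fill <- which(!has_value)
  filled[to_fill] <- stats::approx(
    x = anchor_idx, y = record$fhr_bpm[anchor_idx],
    xout = to_fill, method = "linear", rule = 2
  )$y

  record$fhr_bpm <- filled
  record$interpolated_mask <- record$interpolated_mask | !has_value

  gap_runs <- logical_runs(!record$valid_mask)
  long <- gap_runs[gap_runs$length / record$fs_hz > long_gap_s, , drop = FALSE]
  if (nrow(long) > 0L) {
    for (i in seq_len(nrow(long))) {
      record$long_interp_mask[long$start[i]:long$end[i]] <- TRUE
    }
  }
  record
}
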