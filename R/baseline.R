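#' Baseline and floating-line estimation
#'
#' Estimates two trend lines from an interpolated FHR trace:
#'
#' * the **baseline**: the slowly varying mean FHR level, insensitive to
#'   accelerations and decelerations. It is computed as an iterative trimmed
#'   running median: starting from a plain running median over
#'   `trend_window_min` minutes, samples deviating more than `trim_bpm` from
#'   the current estimate (i.e. samples inside events) are replaced by the
#'   estimate and the median is recomputed, for `iterations` rounds.
#' * the **floating line**: a short running median (`float_window_min`
#'   minutes) that follows the signal through accelerations and
#'   decelerations; subtracting it yields the FHR variability (FHRV) signal.
#'
#' @param record an interpolated [ctg_record()] (see [interpolate_gaps()]).
#' @param trend_window_min baseline running-median window, minutes.
#' @param float_window_min floating-line running-median window, minutes.
#' @param trim_bpm deviation (bpm) beyond which samples are excluded from
#'   the baseline estimate as event samples.
#' @param iterations number of trimming rounds.
#' @return An object of class `baseline_result`: list with per-sample
#'   numeric vectors `baseline_bpm` and `floating_line_bpm`, plus `fs_hz`.
#' @export
#' @examples
#' rec <- ctg_record(rep(140, 4 * 60 * 30), fs_hz = 4)
#' bl <- estimate_baseline(rec)
#' range(bl$baseline_bpm)
estimate_baseline <- function(record, trend_window_min = 10,
                              float_window_min = 2, trim_bpm = 15,
                              iterations = 3L) {
  stopifnot(inherits(record, "ctg_record"))
  x <- record$fhr_bpm
  n <- length(x)
  fs <- record$fs_hz
  if (n < round(trend_window_min * 60 * fs)) {
    stop_insufficient(sprintf(
      "record (%.1f min) shorter than the baseline trend window (%g min)",
      n / fs / 60, trend_window_min))
  }
  if (any(!(record$valid_mask | record$interpolated_mask))) {
    stop_contract("record still contains unfilled samples; run interpolate_gaps() first")
  }

  k_trend <- odd_window(trend_window_min * 60, fs, n)
  k_float <- odd_window(float_window_min * 60, fs, n)

  work <- x
  baseline <- stats::runmed(work, k_trend, endrule = "median")
  for (i in seq_len(iterations)) {
    work <- ifelse(abs(x - baseline) > trim_bpm, baseline, x)
    baseline <- stats::runmed(work, k_trend, endrule = "median")
  }
  baseline <- pmin(pmax(baseline, record$phys_range[1]), record$phys_range[2])

  floating <- stats::runmed(x, k_float, endrule = "median")
  floating <- pmin(pmax(floating, record$phys_range[1]), record$phys_range[2])

  structure(list(
    baseline_bpm = as.numeric(baseline),
    floating_line_bpm = as.numeric(floating),
    fs_hz = fs
  ), class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> %d samples @ %.3g Hz\n",
              length(x$baseline_bpm), x$fs_hz))
  cat(sprintf("  baseline: %.1f-%.1f bpm (mean %.1f)\n",
              min(x$baseline_bpm), max(x$baseline_bpm), mean(x$baseline_bpm)))
  invisible(x)
}
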