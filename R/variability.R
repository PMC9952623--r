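#' FHR variability signal
#'
#' The FHRV signal is the FHR trace minus the floating line (the short
#' median trend that follows the signal through accelerations and
#' decelerations), leaving the beat-to-beat variability around the local
#' trend. Window quality is tracked per analysis window: a window is good
#' when fewer than half of its samples are interpolated and none of them
#' lie in a long interpolated gap.
#'
#' @param record an interpolated [ctg_record()].
#' @param baseline the matching [estimate_baseline()] result (supplies the
#'   floating line).
#' @param window_s quality-bookkeeping window length in seconds (default 30,
#'   the STV analysis window).
#' @return An object of class `fhrv_signal`: list with `values_bpm`,
#'   `fs_hz`, `window_s`, `window_quality` (one logical per complete
#'   window), and copies of the record's interpolation masks.
#' @export
compute_fhrv <- function(record, baseline, window_s = 30) {
  stopifnot(inherits(record, "ctg_record"), inherits(baseline, "baseline_result"))
  if (length(baseline$floating_line_bpm) != length(record$fhr_bpm)) {
    stop_contract("floating line length does not match the record")
  }
  values <- record$fhr_bpm - baseline$floating_line_bpm
  structure(list(
    values_bpm = as.numeric(values),
    fs_hz = record$fs_hz,
    window_s = window_s,
    window_quality = window_quality_flags(record$interpolated_mask,
                                          record$long_interp_mask,
                                          record$fs_hz, window_s),
    interpolated_mask = record$interpolated_mask,
    long_interp_mask = record$long_interp_mask
  ), class = "fhrv_signal")
}

# One flag per complete non-overlapping window: good iff < 50% interpolated
# samples and no long-interpolation sample.
window_quality_flags <- function(interpolated_mask, long_interp_mask,
                                 fs_hz, window_s) {
  n <- length(interpolated_mask)
  n_w <- as.integer(round(window_s * fs_hz))
  n_windows <- n %/% n_w
  if (n_windows == 0L) return(logical(0))
  vapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1L) * n_w + 1L):(w * n_w)
    mean(interpolated_mask[idx]) < 0.5 && !any(long_interp_mask[idx])
  }, logical(1))
}

#' Short-term variability (STV) index
#'
#' For each complete analysis window (default 30 s, non-overlapping) the STV
#' is the sample standard deviation of the FHRV samples in the window,
#'
#' \deqn{STV = \sqrt{\frac{1}{n-1}\sum_{i=1}^{n}(F(i)-\bar F)^2},}
#'
#' where \eqn{F(i)} are the window's FHRV samples, \eqn{\bar F} their mean
#' and \eqn{n} the number of samples in the window (evenly sampled branch).
#' The summary `stv_mean` is the arithmetic mean of the per-window values
#' over good-quality windows only; the trailing partial window is discarded.
#'
#' @param fhrv a [compute_fhrv()] result.
#' @param window_s analysis window length, seconds (default 30).
#' @param hop_s window hop, seconds; default equal to `window_s`
#'   (non-overlapping tiling). Smaller values give overlapping windows.
#' @return An object of class `stv_result`: list with `stv_per_window`
#'   (one value per complete window), `window_good` (logical), `stv_mean`,
#'   `n_windows_used`, and `stv_absent` (`stv_mean` below the
#'   absent-variability alarm level 0.02 bpm).
#' @export
#' @examples
#' rec <- ctg_record(140 + rep(c(-1, 1), 3600), fs_hz = 4)
#' bl <- estimate_baseline(rec)
#' stv <- compute_stv(compute_fhrv(rec, bl))
#' stv$stv_mean
compute_stv <- function(fhrv, window_s = 30, hop_s = window_s) {
  stopifnot(inherits(fhrv, "fhrv_signal"))
  fs <- fhrv$fs_hz
  n <- length(fhrv$values_bpm)
  n_w <- as.integer(round(window_s * fs))
  hop <- as.integer(round(hop_s * fs))
  if (n_w < 2L) stop_contract("window too short for a standard deviation")
  if (n < n_w) stop_insufficient("record shorter than one STV window")
  starts <- seq.int(1L, n - n_w + 1L, by = hop)

  good <- vapply(starts, function(s) {
    idx <- s:(s + n_w - 1L)
    mean(fhrv$interpolated_mask[idx]) < 0.5 && !any(fhrv$long_interp_mask[idx])
  }, logical(1))
  stv <- vapply(starts, function(s) {
    stats::sd(fhrv$values_bpm[s:(s + n_w - 1L)])
  }, numeric(1))

  if (!any(good)) stop_insufficient("no good-quality STV window available")
  stv_mean <- mean(stv[good])
  structure(list(
    stv_per_window = stv,
    window_good = good,
    window_start_s = (starts - 1L) / fs,
    stv_mean = stv_mean,
    n_windows_used = sum(good),
    stv_absent = stv_mean < 0.02
  ), class = "stv_result")
}

#' @export
print.stv_result <- function(x, ...) {
  cat(sprintf("<stv_result> mean STV %.3f bpm over %d/%d windows%s\n",
              x$stv_mean, x$n_windows_used, length(x$stv_per_window),
              if (x$stv_absent) " [absent variability]" else ""))
  invisible(x)
}
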