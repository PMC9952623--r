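#' Spectral analysis configuration
#'
#' Settings for the short-time Fourier transform (STFT) estimate of the
#' FHRV power spectral density and its band powers. Defaults follow common
#' computerized-CTG practice: Hanning window of 32 s, resampling step
#' 0.25 s (4 Hz), 1024-point spectrum, 50% frame overlap, and the bands
#' VLF 0--0.05 Hz, LF 0.05--0.2 Hz, HF 0.2--1 Hz.
#'
#' @param window_type `"hanning"`, `"hamming"` or `"rectangular"`.
#' @param window_len_s STFT frame length in seconds.
#' @param resample_step_s sampling step the signal is (re)interpolated to
#'   before the STFT, seconds.
#' @param nfft number of points of the frequency grid (must be at least the
#'   frame length in samples).
#' @param overlap_fraction fraction of frame overlap in `[0, 1)`; 0 gives
#'   disjoint frames.
#' @param bands named list of `c(low, high)` frequency intervals in Hz;
#'   must be disjoint, ordered, and within the Nyquist range.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(window_type = c("hanning", "hamming", "rectangular"),
                            window_len_s = 32, resample_step_s = 0.25,
                            nfft = 1024, overlap_fraction = 0.5,
                            bands = list(VLF = c(0, 0.05),
                                         LF = c(0.05, 0.2),
                                         HF = c(0.2, 1))) {
  window_type <- match.arg(window_type)
  fs <- 1 / resample_step_s
  L <- as.integer(round(window_len_s * fs))
  if (nfft < L) stop_contract("nfft must be at least the window length in samples")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_contract("overlap_fraction must lie in [0, 1)")
  }
  lows <- vapply(bands, `[`, numeric(1), 1L)
  highs <- vapply(bands, `[`, numeric(1), 2L)
  if (any(highs <= lows)) stop_contract("each band needs low < high")
  if (is.unsorted(lows) || any(lows[-1] < highs[-length(highs)])) {
    stop_contract("bands must be ordered and disjoint")
  }
  if (max(highs) > fs / 2 + 1e-12) {
    stop_contract("upper band edge exceeds the Nyquist frequency")
  }
  structure(list(window_type = window_type, window_len_s = window_len_s,
                 resample_step_s = resample_step_s, nfft = as.integer(nfft),
                 overlap_fraction = overlap_fraction, bands = bands),
            class = "spectral_config")
}

stft_window <- function(type, L) {
  switch(type,
         hanning = signal::hanning(L),
         hamming = signal::hamming(L),
         rectangular = rep(1, L))
}

#' Mean power spectral density of the FHRV signal via STFT
#'
#' The signal is cubic-spline interpolated to the configured sampling step
#' when needed, cut into frames of `window_len_s` seconds, each frame
#' mean-subtracted, tapered with the configured window \eqn{w(n)} and
#' zero-padded to `nfft` points. The per-frame PSD is
#' \eqn{P_i(\omega) = |FT(\omega)|^2 / (L\,U\,f_s)} with the window power
#' normalization \eqn{U = \frac{1}{L}\sum_n w(n)^2}, scaled one-sided
#' (factor 2 on non-DC, non-Nyquist bins) so that the frequency integral of
#' the PSD equals the signal variance (Parseval). The reported spectrum is
#' the average of the per-frame PSDs over the `n_frames` frames. Band
#' powers, total power and the sympatho-vagal balance are attached via
#' [band_powers()].
#'
#' @param fhrv a [compute_fhrv()] result (or any list with `values_bpm` and
#'   `fs_hz`).
#' @param config a [spectral_config()].
#' @return An object of class `spectral_estimate`: list with `freqs_hz`,
#'   `mean_psd` (bpm^2/Hz), `band_power` (named numeric, bpm^2),
#'   `total_power`, `svb`, `n_frames`, `fs_hz`, `config`.
#' @export
compute_mean_psd <- function(fhrv, config = spectral_config()) {
  stopifnot(inherits(config, "spectral_config"))
  x <- fhrv$values_bpm
  fs_in <- fhrv$fs_hz
  fs <- 1 / config$resample_step_s
  if (abs(fs_in - fs) > 1e-9) {
    t_in <- (seq_along(x) - 1L) / fs_in
    t_out <- seq(0, t_in[length(t_in)], by = 1 / fs)
    x <- stats::spline(t_in, x, xout = t_out, method = "fmm")$y
  }
  L <- as.integer(round(config$window_len_s * fs))
  if (length(x) < L) {
    stop_insufficient("signal shorter than one spectral analysis window")
  }
  w <- stft_window(config$window_type, L)
  U <- mean(w^2)
  hop <- max(1L, as.integer(round(L * (1 - config$overlap_fraction))))
  starts <- seq.int(1L, length(x) - L + 1L, by = hop)
  nfft <- config$nfft
  half <- nfft %/% 2L

  acc <- numeric(half + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - L)))
    p <- (Mod(X[1:(half + 1L)])^2) / (L * U * fs)
    p[2:half] <- 2 * p[2:half]  # one-sided scaling, DC and Nyquist excluded
    acc <- acc + p
  }
  mean_psd <- acc / length(starts)
  freqs <- (0:half) * fs / nfft

  est <- structure(list(freqs_hz = freqs, mean_psd = mean_psd,
                        band_power = NULL, total_power = NULL, svb = NULL,
                        n_frames = length(starts), fs_hz = fs,
                        config = config),
                   class = "spectral_estimate")
  bp <- band_powers(est, config$bands)
  est$band_power <- bp$band_power
  est$total_power <- bp$total_power
  est$svb <- bp$svb
  est
}

#' Band powers, total power and sympatho-vagal balance
#'
#' Integrates the mean PSD over each configured frequency band (trapezoidal
#' rule on the piecewise-linear interpolant, with exact band edges). The
#' total power is the sum of the band powers and the sympatho-vagal balance
#' (SVB) is the LF/HF power ratio; when the HF power is zero the SVB is
#' reported as `NA` (undefined), never as infinity.
#'
#' @param est a [compute_mean_psd()] result, or a list with numeric
#'   `freqs_hz` and `mean_psd`.
#' @param bands named list of `c(low, high)` intervals in Hz; must contain
#'   `LF` and `HF` entries for the SVB.
#' @return list with `band_power` (named numeric), `total_power`, `svb`.
#' @export
#' @examples
#' flat <- list(freqs_hz = seq(0, 2, by = 0.01), mean_psd = as.numeric(seq(0, 2, by = 0.01) <= 1))
#' band_powers(flat)$band_power
band_powers <- function(est, bands = list(VLF = c(0, 0.05),
                                          LF = c(0.05, 0.2),
                                          HF = c(0.2, 1))) {
  f <- est$freqs_hz
  p <- est$mean_psd
  if (length(f) != length(p)) stop_contract("freqs_hz and mean_psd differ in length")
  bp <- vapply(bands, function(b) trapz_band(f, p, b[1], b[2]), numeric(1))
  hf <- if ("HF" %in% names(bp)) bp[["HF"]] else NA_real_
  lf <- if ("LF" %in% names(bp)) bp[["LF"]] else NA_real_
  svb <- if (is.na(hf) || is.na(lf)) NA_real_
         else if (hf == 0) NA_real_
         else lf / hf
  list(band_power = bp, total_power = sum(bp), svb = svb)
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d frames, %d frequency bins up to %.2f Hz\n",
              x$n_frames, length(x$freqs_hz), max(x$freqs_hz)))
  bp <- x$band_power
  cat(sprintf("  band power: %s; total %.3g bpm^2; SVB %s\n",
              paste(sprintf("%s=%.3g", names(bp), bp), collapse = ", "),
              x$total_power,
              if (is.na(x$svb)) "undefined" else sprintf("%.3g", x$svb)))
  invisible(x)
}
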