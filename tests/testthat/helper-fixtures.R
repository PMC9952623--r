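# Shared fixtures and independent oracles for the test suite.

# A constant-FHR record of the given duration.
make_const_record <- function(duration_min = 30, fs_hz = 4, level = 140, ...) {
  ctg_record(rep(level, round(duration_min * 60 * fs_hz)), fs_hz = fs_hz, ...)
}

# Build an fhrv_signal directly (bypassing the pipeline) for STV/spectral
# unit tests.
make_fhrv <- function(values, fs_hz = 4, window_s = 30,
                      interpolated = rep(FALSE, length(values)),
                      long_interp = rep(FALSE, length(values))) {
  structure(list(
    values_bpm = as.numeric(values), fs_hz = fs_hz, window_s = window_s,
    window_quality = NULL,
    interpolated_mask = interpolated, long_interp_mask = long_interp
  ), class = "fhrv_signal")
}

# Independent two-pass variance oracle for the STV of one window.
oracle_window_sd <- function(x) {
  m <- sum(x) / length(x)
  ss <- sum((x - m)^2)
  sqrt(ss / (length(x) - 1))
}

# Brute-force arrhythmia oracle: explicit per-sample scan of every maximal
# run against the threshold/duration rule. Returns a matrix with one row
# per episode: start, end (inclusive).
oracle_arrhythmia <- function(baseline, fs_hz, kind, valid = NULL) {
  n <- length(baseline)
  if (is.null(valid)) valid <- rep(TRUE, n)
  hit <- if (kind == "tachycardia") valid & baseline > 160
         else valid & baseline < 110
  runs <- matrix(numeric(0), ncol = 2)
  s <- NA_integer_
  for (i in seq_len(n + 1L)) {
    inside <- i <= n && hit[i]
    if (inside && is.na(s)) s <- i
    if (!inside && !is.na(s)) {
      dur <- (i - s) / fs_hz
      keep <- if (kind == "tachycardia") dur >= 600 else dur > 180
      if (keep) runs <- rbind(runs, c(s, i - 1L))
      s <- NA_integer_
    }
  }
  runs
}

# Independent brute-force implementation of the suspicion rules, coded
# directly from the four criteria.
oracle_annotation <- function(mask, acc, severe_tach, brad) {
  bits <- as.logical(mask)
  names(bits) <- names(mask)
  non_acc_bits <- bits[c("BRAD", "TACH", "DEC", "STV", "SVB")]
  c1 <- (acc == 0) && any(non_acc_bits)
  c2 <- (acc >= 1) && (sum(bits) >= 2)
  c3 <- isTRUE(severe_tach)
  c4 <- brad >= 1
  if (c1 || c2 || c3 || c4) "suspicious" else "normal"
}

# Hand-computed metric fractions from raw counts (integer arithmetic held
# as long as possible).
oracle_metrics <- function(tp, fn, fp, tn) {
  list(
    accuracy = 100 * (tp + tn) / (tp + fn + fp + tn),
    sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
    precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  )
}

# Write a record CSV + JSON sidecar by hand (independent of
# save_ctg_record) and return the csv path.
write_manual_record <- function(dir, fhr, fs_hz = 4, uc = NULL,
                                id = "manual", week = 38L) {
  csv <- file.path(dir, paste0(id, ".csv"))
  tab <- data.frame(time_s = (seq_along(fhr) - 1) / fs_hz, fhr_bpm = fhr)
  if (!is.null(uc)) tab$uc <- uc
  utils::write.csv(tab, csv, row.names = FALSE)
  writeLines(sprintf(
    '{"record_id":"%s","fs_hz":%g,"gestational_week":%d,"singleton":true,"antepartum":true}',
    id, fs_hz, week), file.path(dir, paste0(id, ".json")))
  csv
}
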