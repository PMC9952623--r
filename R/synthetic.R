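#' Synthetic CTG generator configuration
#'
#' Describes one synthetic CTG recording: a stable baseline in the normal
#' 110--160 bpm band, band-limited beat-to-beat variability with a target
#' standard deviation, embedded LF and HF oscillations that set the
#' spectral balance, trapezoidal FIGO-scale events (accelerations,
#' decelerations) and arrhythmia episodes (tachycardia, bradycardia),
#' bell-shaped uterine contractions, and injected signal loss and outlier
#' artifacts. All randomness is driven by `seed`.
#'
#' @param duration_min recording length, minutes (default 30, an eligible
#'   antepartum duration).
#' @param fs_hz sampling frequency, Hz (default 4).
#' @param baseline_bpm resting baseline level, bpm.
#' @param variability_sd_bpm target standard deviation of the band-limited
#'   variability component, bpm.
#' @param lf_amp_bpm,hf_amp_bpm amplitudes of the embedded LF and HF
#'   sinusoids, bpm.
#' @param lf_freq_hz,hf_freq_hz frequencies of the embedded oscillations,
#'   Hz (defaults 0.1 and 0.4, inside the LF and HF bands).
#' @param events list of events, each a list with `kind`
#'   (`"acceleration"`, `"deceleration"`, `"tachycardia"`,
#'   `"bradycardia"`), `start_s`, `duration_s` and `amplitude_bpm`
#'   (positive for accelerations/tachycardia, negative for
#'   decelerations/bradycardia).
#' @param signal_loss_fraction fraction of samples dropped in gap segments.
#' @param outlier_fraction fraction of samples replaced by artifact spikes.
#' @param uc_count number of uterine contractions to embed.
#' @param gestational_week,singleton,antepartum record metadata.
#' @param record_id identifier.
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_min = 30, fs_hz = 4,
                             baseline_bpm = 140, variability_sd_bpm = 2,
                             lf_amp_bpm = 3, hf_amp_bpm = 1,
                             lf_freq_hz = 0.1, hf_freq_hz = 0.4,
                             events = list(),
                             signal_loss_fraction = 0, outlier_fraction = 0,
                             uc_count = 3L, gestational_week = 38L,
                             singleton = TRUE, antepartum = TRUE,
                             record_id = "synthetic", seed = 1L) {
  if (duration_min <= 0 || fs_hz <= 0) {
    stop_contract("duration_min and fs_hz must be positive")
  }
  if (signal_loss_fraction < 0 || signal_loss_fraction >= 1 ||
      outlier_fraction < 0 || outlier_fraction >= 1) {
    stop_contract("loss and outlier fractions must lie in [0, 1)")
  }
  dur_s <- duration_min * 60
  for (ev in events) {
    if (!all(c("kind", "start_s", "duration_s", "amplitude_bpm") %in% names(ev))) {
      stop_contract("each event needs kind, start_s, duration_s, amplitude_bpm")
    }
    if (ev$start_s < 0 || ev$start_s + ev$duration_s > dur_s) {
      stop_contract(sprintf("event (%s at %gs) does not fit inside the record",
                            ev$kind, ev$start_s))
    }
    pos_kind <- ev$kind %in% c("acceleration", "tachycardia")
    if (pos_kind && ev$amplitude_bpm <= 0) {
      stop_contract(sprintf("%s amplitude must be positive", ev$kind))
    }
    if (!pos_kind && ev$amplitude_bpm >= 0) {
      stop_contract(sprintf("%s amplitude must be negative", ev$kind))
    }
  }
  structure(list(duration_min = duration_min, fs_hz = fs_hz,
                 baseline_bpm = baseline_bpm,
                 variability_sd_bpm = variability_sd_bpm,
                 lf_amp_bpm = lf_amp_bpm, hf_amp_bpm = hf_amp_bpm,
                 lf_freq_hz = lf_freq_hz, hf_freq_hz = hf_freq_hz,
                 events = events,
                 signal_loss_fraction = signal_loss_fraction,
                 outlier_fraction = outlier_fraction,
                 uc_count = as.integer(uc_count),
                 gestational_week = as.integer(gestational_week),
                 singleton = singleton, antepartum = antepartum,
                 record_id = record_id, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Trapezoid of unit height over [start_s, start_s + duration_s] with linear
# ramps of ramp_s at both ends, evaluated on the sample grid.
trapezoid_profile <- function(n, fs, start_s, duration_s, ramp_s = 5) {
  t <- (seq_len(n) - 1) / fs
  end_s <- start_s + duration_s
  ramp <- min(ramp_s, duration_s / 2)
  up <- pmin(pmax((t - start_s) / ramp, 0), 1)
  down <- pmin(pmax((end_s - t) / ramp, 0), 1)
  pmin(up, down)
}

# Band-limited Gaussian noise: white noise low-pass filtered below 1 Hz
# (the physiological FHRV band), rescaled to the exact target SD.
band_limited_noise <- function(n, fs, target_sd, cutoff_hz = 1) {
  if (target_sd <= 0) return(numeric(n))
  wn <- min(cutoff_hz / (fs / 2), 0.99)
  x <- stats::rnorm(n)
  if (wn < 0.99) {
    bf <- signal::butter(4, wn)
    x <- signal::filtfilt(bf, x)
  }
  x * target_sd / stats::sd(x)
}

#' Generate one synthetic CTG record with ground truth
#'
#' Builds an FHR trace as baseline + trapezoidal events + band-limited
#' variability + LF/HF sinusoids, embeds bell-shaped uterine contractions,
#' and injects signal-loss gaps (encoded with the missing sentinel 0) and
#' isolated outlier spikes at the configured fractions. The same seed
#' always reproduces the same record.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `record` (a [ctg_record()]) and
#'   `ground_truth`: list with `true_events` (data.frame of embedded
#'   events), `true_stv` (bpm; standard deviation of the embedded
#'   variability including the oscillations), `true_svb_proxy`
#'   (`lf_amp^2/hf_amp^2`), `intended_label`, and the generating `config`.
#' @export
#' @examples
#' gen <- generate_record(synthetic_config(duration_min = 21, seed = 7))
#' gen$record
generate_record <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs_hz
  n <- as.integer(round(config$duration_min * 60 * fs))
  t <- (seq_len(n) - 1) / fs

  with_seed(config$seed, {
    level <- rep(config$baseline_bpm, n)
    for (ev in config$events) {
      prof <- trapezoid_profile(n, fs, ev$start_s, ev$duration_s)
      level <- level + ev$amplitude_bpm * prof
    }
    noise <- band_limited_noise(n, fs, config$variability_sd_bpm)
    lf <- config$lf_amp_bpm * sin(2 * pi * config$lf_freq_hz * t +
                                  stats::runif(1, 0, 2 * pi))
    hf <- config$hf_amp_bpm * sin(2 * pi * config$hf_freq_hz * t +
                                  stats::runif(1, 0, 2 * pi))
    fhr <- level + noise + lf + hf

    uc <- rep(10, n)
    if (config$uc_count > 0L) {
      dur_s <- config$duration_min * 60
      # contraction centers at least 3 min apart so pulses stay distinct
      centers <- numeric(0)
      guard <- 0L
      while (length(centers) < config$uc_count && guard < 5000L) {
        guard <- guard + 1L
        cand <- stats::runif(1, 90, dur_s - 90)
        if (all(abs(cand - centers) >= 180)) centers <- c(centers, cand)
      }
      centers <- sort(centers)
      widths <- stats::runif(config$uc_count, 20, 32)
      amps <- stats::runif(config$uc_count, 30, 55)
      for (i in seq_along(centers)) {
        uc <- uc + amps[i] * exp(-((t - centers[i])^2) / (2 * widths[i]^2))
      }
    }
    uc <- uc + stats::rnorm(n, 0, 0.5)

    missing <- rep(FALSE, n)
    if (config$signal_loss_fraction > 0) {
      target <- config$signal_loss_fraction * n
      guard <- 0L
      while (sum(missing) < target && guard < 10000L) {
        guard <- guard + 1L
        len <- as.integer(round(stats::runif(1, 2, 30) * fs))
        start <- sample.int(max(1L, n - len), 1L)
        missing[start:min(n, start + len - 1L)] <- TRUE
      }
    }
    outlier_idx <- integer(0)
    if (config$outlier_fraction > 0) {
      candidates <- which(!missing)
      k <- min(length(candidates),
               as.integer(round(config$outlier_fraction * n)))
      # isolated spikes: keep selected samples at least 2 samples apart
      sel <- sort(sample(candidates, k))
      sel <- sel[c(TRUE, diff(sel) > 2L)]
      outlier_idx <- sel
    }

    fhr_raw <- fhr
    fhr_raw[missing] <- 0
    if (length(outlier_idx) > 0L) {
      spike <- sample(c(-1, 1), length(outlier_idx), replace = TRUE) *
        stats::runif(length(outlier_idx), 40, 90)
      fhr_raw[outlier_idx] <- pmax(fhr[outlier_idx] + spike, 1)
    }

    record <- ctg_record(
      fhr_bpm = fhr_raw, fs_hz = fs, uc = uc,
      record_id = config$record_id,
      gestational_week = config$gestational_week,
      singleton = config$singleton, antepartum = config$antepartum
    )

    true_events <- if (length(config$events) > 0L) {
      do.call(rbind, lapply(config$events, function(ev) {
        data.frame(kind = ev$kind, start_s = ev$start_s,
                   duration_s = ev$duration_s,
                   amplitude_bpm = ev$amplitude_bpm)
      }))
    } else {
      data.frame(kind = character(0), start_s = numeric(0),
                 duration_s = numeric(0), amplitude_bpm = numeric(0))
    }
    true_stv <- sqrt(config$variability_sd_bpm^2 +
                     config$lf_amp_bpm^2 / 2 + config$hf_amp_bpm^2 / 2)
    true_svb <- if (config$hf_amp_bpm > 0) {
      config$lf_amp_bpm^2 / config$hf_amp_bpm^2
    } else {
      NA_real_
    }
    list(record = record,
         ground_truth = list(true_events = true_events,
                             true_stv = true_stv,
                             true_svb_proxy = true_svb,
                             intended_label = intended_label(config),
                             config = config))
  })
}

# Label implied by the generating parameters under the annotation rules.
intended_label <- function(config) {
  kinds <- vapply(config$events, `[[`, character(1), "kind")
  amps <- vapply(config$events, `[[`, numeric(1), "amplitude_bpm")
  durs <- vapply(config$events, `[[`, numeric(1), "duration_s")
  has_acc <- any(kinds == "acceleration")
  severe_tach <- any(kinds == "tachycardia" &
                     config$baseline_bpm + amps > 180 & durs >= 600)
  brady <- any(kinds == "bradycardia" &
               config$baseline_bpm + amps < 110 & durs > 180)
  stv_low <- sqrt(config$variability_sd_bpm^2 + config$lf_amp_bpm^2 / 2 +
                  config$hf_amp_bpm^2 / 2) < 1.70
  svb_low <- config$hf_amp_bpm > 0 &&
    (config$lf_amp_bpm^2 / config$hf_amp_bpm^2) < 8.20
  n_alarm_bits <- stv_low + svb_low +
    any(kinds == "tachycardia" & durs >= 600) + brady
  suspicious <- (!has_acc && n_alarm_bits >= 1) ||
    (has_acc && (n_alarm_bits + !has_acc) >= 2) ||
    severe_tach || brady
  if (suspicious) "suspicious" else "normal"
}

# Sample n non-overlapping event start times of the given durations inside
# (margin_s, total_s - margin_s), by rejection; `blocked` is an optional
# 2-column matrix of already-occupied [start, end] intervals.
place_events <- function(durations_s, total_s, margin_s = 60,
                         blocked = NULL, max_tries = 200L) {
  starts <- if (is.null(blocked)) numeric(0) else blocked[, 1]
  ends <- if (is.null(blocked)) numeric(0) else blocked[, 2]
  out <- numeric(length(durations_s))
  for (i in seq_along(durations_s)) {
    ok <- FALSE
    for (tries in seq_len(max_tries)) {
      s <- stats::runif(1, margin_s, total_s - margin_s - durations_s[i])
      e <- s + durations_s[i]
      if (all(e < starts - 20 | s > ends + 20)) { ok <- TRUE; break }
    }
    if (!ok) stop_contract("could not place events without overlap")
    starts <- c(starts, s)
    ends <- c(ends, e)
    out[i] <- s
  }
  out
}

# Injected accelerations are drawn to satisfy the FIGO definition by
# geometry: a trapezoid of amplitude A with 5-s ramps stays above the
# +15 bpm threshold for duration - 2*5*(15/A) seconds, so amplitudes of
# 21-28 bpm and durations of 28-50 s leave a comfortable margin over the
# 15-s minimum even under the embedded oscillations.
draw_accelerations <- function(n_acc, total_s, blocked = NULL) {
  if (n_acc == 0L) return(list())
  durs <- stats::runif(n_acc, 28, 50)
  starts <- place_events(durs, total_s, blocked = blocked)
  lapply(seq_len(n_acc), function(i) {
    list(kind = "acceleration", start_s = starts[i], duration_s = durs[i],
         amplitude_bpm = stats::runif(1, 21, 28))
  })
}

# Parameter draw for one normal record: reactive trace with accelerations,
# healthy variability and a sympathetic-dominant spectral balance. The
# amplitude families keep the measured SVB above the 8.20 cutoff: the
# broadband variability spreads over the whole 0-1 Hz band, so its HF-band
# share bounds the noise SD that a given LF oscillation can carry.
draw_normal_params <- function(duration_min) {
  total_s <- duration_min * 60
  list(baseline_bpm = stats::runif(1, 125, 150),
       variability_sd_bpm = stats::runif(1, 0.7, 1.1),
       lf_amp_bpm = stats::runif(1, 3.4, 5.0),
       hf_amp_bpm = stats::runif(1, 0.25, 0.5),
       events = draw_accelerations(sample(2:6, 1), total_s),
       signal_loss_fraction = stats::runif(1, 0.02, 0.12),
       outlier_fraction = stats::runif(1, 0, 0.01))
}

# Parameter draw for one suspicious record; `mode` picks which annotation
# rule the trace violates.
draw_suspicious_params <- function(duration_min,
                                   mode = c("no_accel_low_svb", "low_stv",
                                            "severe_tachycardia",
                                            "bradycardia")) {
  mode <- match.arg(mode)
  total_s <- duration_min * 60
  base <- list(baseline_bpm = stats::runif(1, 125, 150),
               variability_sd_bpm = stats::runif(1, 0.7, 1.1),
               lf_amp_bpm = stats::runif(1, 3.4, 5.0),
               hf_amp_bpm = stats::runif(1, 0.25, 0.5),
               events = list(),
               signal_loss_fraction = stats::runif(1, 0.02, 0.12),
               outlier_fraction = stats::runif(1, 0, 0.01))
  if (mode == "no_accel_low_svb") {
    # vagal-dominant balance below (but near) the 8.20 cutoff
    base$variability_sd_bpm <- stats::runif(1, 0.7, 1.0)
    base$lf_amp_bpm <- stats::runif(1, 2.2, 3.2)
    base$hf_amp_bpm <- stats::runif(1, 0.7, 0.95)
  } else if (mode == "low_stv") {
    base$variability_sd_bpm <- stats::runif(1, 0.4, 0.8)
    base$lf_amp_bpm <- stats::runif(1, 0.8, 1.6)
    base$hf_amp_bpm <- stats::runif(1, 0.2, 0.5)
  } else if (mode == "severe_tachycardia") {
    amp <- stats::runif(1, 183, 192) - base$baseline_bpm
    dur <- stats::runif(1, 630, 750)
    start <- stats::runif(1, 90, total_s - 90 - dur)
    base$events <- c(
      list(list(kind = "tachycardia", start_s = start, duration_s = dur,
                amplitude_bpm = amp)),
      draw_accelerations(sample(0:3, 1), total_s,
                         blocked = matrix(c(start, start + dur), 1)))
  } else if (mode == "bradycardia") {
    amp <- stats::runif(1, 98, 106) - base$baseline_bpm
    dur <- stats::runif(1, 220, 330)
    start <- stats::runif(1, 90, total_s - 90 - dur)
    base$events <- c(
      list(list(kind = "bradycardia", start_s = start, duration_s = dur,
                amplitude_bpm = amp)),
      draw_accelerations(sample(0:3, 1), total_s,
                         blocked = matrix(c(start, start + dur), 1)))
  }
  base$mode <- mode
  base
}

#' Generate a labeled cohort of synthetic CTG records
#'
#' Normal records are reactive: several FIGO-valid accelerations, healthy
#' variability (STV well above the 1.70 cutoff), a sympathetic-dominant
#' spectral balance (SVB above the 8.20 cutoff) and no arrhythmia.
#' Suspicious records violate the annotation rules in one randomly sampled
#' way: no accelerations with vagal-dominant balance (low SVB), low
#' variability (low STV, no accelerations), severe tachycardia, or
#' bradycardia. Every record is independently reproducible: the cohort seed
#' deterministically derives one seed per record.
#'
#' @param n_normal,n_suspicious record counts per class.
#' @param seed integer cohort seed.
#' @param duration_min record duration, minutes.
#' @param suspicious_weights sampling weights of the four suspicious modes
#'   (order: no_accel_low_svb, low_stv, severe_tachycardia, bradycardia).
#' @return An object of class `ctg_cohort`: list with `records` (list of
#'   [ctg_record()]), `ground_truth` (list, one per record), `labels`
#'   (intended labels, character) and `manifest` (data.frame with
#'   record_id, intended_label, mode and key generating parameters).
#' @export
#' @examples
#' coh <- generate_cohort(3, 2, seed = 7, duration_min = 21)
#' coh$manifest[, c("record_id", "intended_label", "mode")]
generate_cohort <- function(n_normal, n_suspicious, seed = 1L,
                            duration_min = 30,
                            suspicious_weights = c(1, 1, 1, 1)) {
  if (n_normal < 1L || n_suspicious < 1L) {
    stop_contract("both classes need at least one record")
  }
  modes <- c("no_accel_low_svb", "low_stv", "severe_tachycardia",
             "bradycardia")
  n_total <- n_normal + n_suspicious
  spec <- with_seed(seed, {
    record_seeds <- sample.int(2147483646L, n_total)
    lapply(seq_len(n_total), function(i) {
      is_normal <- i <= n_normal
      params <- if (is_normal) {
        c(draw_normal_params(duration_min), list(mode = "normal"))
      } else {
        draw_suspicious_params(duration_min,
                               sample(modes, 1, prob = suspicious_weights))
      }
      params$seed <- record_seeds[i]
      params$label <- if (is_normal) "normal" else "suspicious"
      params$record_id <- sprintf("%s_%03d",
                                  if (is_normal) "norm" else "susp", i)
      params
    })
  })
  gens <- lapply(spec, function(p) {
    cfg <- synthetic_config(
      duration_min = duration_min,
      baseline_bpm = p$baseline_bpm,
      variability_sd_bpm = p$variability_sd_bpm,
      lf_amp_bpm = p$lf_amp_bpm, hf_amp_bpm = p$hf_amp_bpm,
      events = p$events,
      signal_loss_fraction = p$signal_loss_fraction,
      outlier_fraction = p$outlier_fraction,
      gestational_week = sample(36:40, 1),
      record_id = p$record_id, seed = p$seed
    )
    g <- generate_record(cfg)
    g$ground_truth$intended_label <- p$label
    g$ground_truth$mode <- p$mode
    g
  })
  manifest <- do.call(rbind, lapply(seq_along(gens), function(i) {
    p <- spec[[i]]
    gt <- gens[[i]]$ground_truth
    data.frame(record_id = p$record_id, intended_label = p$label,
               mode = p$mode, seed = p$seed,
               baseline_bpm = p$baseline_bpm,
               variability_sd_bpm = p$variability_sd_bpm,
               lf_amp_bpm = p$lf_amp_bpm, hf_amp_bpm = p$hf_amp_bpm,
               n_events = length(p$events),
               true_stv = gt$true_stv,
               true_svb_proxy = gt$true_svb_proxy)
  }))
  structure(list(records = lapply(gens, `[[`, "record"),
                 ground_truth = lapply(gens, `[[`, "ground_truth"),
                 labels = vapply(spec, `[[`, character(1), "label"),
                 manifest = manifest, seed = seed),
            class = "ctg_cohort")
}

#' @export
print.ctg_cohort <- function(x, ...) {
  cat(sprintf("<ctg_cohort> %d records (%d normal, %d suspicious), seed %d\n",
              length(x$records), sum(x$labels == "normal"),
              sum(x$labels == "suspicious"), x$seed))
  invisible(x)
}

#' Extract the feature table of a cohort
#'
#' Runs [extract_features()] on every record of a cohort and binds the
#' rows, carrying the intended label along.
#'
#' @param cohort a [generate_cohort()] result (or a plain list of records).
#' @param ... passed to [extract_features()].
#' @return data.frame with one feature row per record plus
#'   `intended_label` when the input is a cohort.
#' @export
cohort_features <- function(cohort, ...) {
  records <- if (inherits(cohort, "ctg_cohort")) cohort$records else cohort
  rows <- lapply(records, function(r) as.data.frame(extract_features(r, ...)))
  out <- do.call(rbind, rows)
  if (inherits(cohort, "ctg_cohort")) out$intended_label <- cohort$labels
  out
}
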