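#' CTG record
#'
#' Container for one cardiotocographic recording: an evenly sampled fetal
#' heart rate (FHR) trace in beats per minute, an optional uterine activity
#' (UC) trace in arbitrary units, per-sample validity and interpolation
#' masks, and recording metadata. Missing FHR samples are encoded with the
#' sentinel value 0 in the raw trace, the convention used by common CTG
#' monitor exports.
#'
#' A sample is invalid when it is missing (sentinel 0 or `NA`), falls outside
#' the physiological range `phys_range` (default 50--240 bpm), or is an
#' isolated artifact spike: it differs by more than `max_jump_bpm` (default
#' 25 bpm) from the measured samples on both sides. Invalid samples are kept
#' in the trace; [interpolate_gaps()] fills them.
#'
#' @param fhr_bpm numeric vector of FHR samples (bpm; 0 = missing).
#' @param fs_hz sampling frequency in Hz (samples per second).
#' @param uc optional numeric vector of uterine-activity samples, same
#'   length as `fhr_bpm`.
#' @param record_id character identifier.
#' @param gestational_week integer gestational age in weeks.
#' @param singleton logical, singleton pregnancy.
#' @param antepartum logical, recording taken before labor.
#' @param phys_range length-2 numeric, physiological FHR range in bpm.
#' @param max_jump_bpm maximum plausible sample-to-sample change in bpm;
#'   larger isolated jumps are flagged as outliers.
#' @param valid_mask,interpolated_mask optional logical vectors overriding
#'   the masks derived from `fhr_bpm` (used when reloading saved records).
#'
#' @return An object of class `ctg_record`: a list with elements
#'   `record_id`, `fs_hz`, `fhr_bpm`, `uc`, `valid_mask`,
#'   `interpolated_mask`, `long_interp_mask`, `gestational_week`,
#'   `singleton`, `antepartum`, `phys_range`, `max_jump_bpm`.
#' @seealso [assess_quality()], [interpolate_gaps()], [load_ctg_record()]
#' @export
#' @examples
#' rec <- ctg_record(c(140, 141, 0, 139), fs_hz = 4)
#' rec$valid_mask
ctg_record <- function(fhr_bpm, fs_hz, uc = NULL, record_id = "ctg",
                       gestational_week = 38L, singleton = TRUE,
                       antepartum = TRUE, phys_range = c(50, 240),
                       max_jump_bpm = 25,
                       valid_mask = NULL, interpolated_mask = NULL) {
  fhr_bpm <- as.numeric(fhr_bpm)
  n <- length(fhr_bpm)
  if (n == 0L) stop_contract("fhr_bpm must be non-empty")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop_contract("fs_hz must be a single positive number")
  }
  if (!is.null(uc)) {
    uc <- as.numeric(uc)
    if (length(uc) != n) stop_contract("uc must have the same length as fhr_bpm")
  }
  if (is.null(valid_mask)) {
    valid_mask <- derive_valid_mask(fhr_bpm, phys_range, max_jump_bpm)$valid
  }
  if (is.null(interpolated_mask)) interpolated_mask <- rep(FALSE, n)
  stopifnot(length(valid_mask) == n, length(interpolated_mask) == n)
  if (any(interpolated_mask & valid_mask)) {
    stop_contract("interpolated samples must originate from invalid samples")
  }
  structure(list(
    record_id = as.character(record_id),
    fs_hz = fs_hz,
    fhr_bpm = fhr_bpm,
    uc = uc,
    valid_mask = as.logical(valid_mask),
    interpolated_mask = as.logical(interpolated_mask),
    long_interp_mask = rep(FALSE, n),
    gestational_week = as.integer(gestational_week),
    singleton = isTRUE(singleton),
    antepartum = isTRUE(antepartum),
    phys_range = phys_range,
    max_jump_bpm = max_jump_bpm
  ), class = "ctg_record")
}

# Classify each raw FHR sample as missing, out-of-range, spike or valid.
# Spike rejection is a sequential scan: an in-range sample deviating more
# than max_jump_bpm from the last accepted sample is a spike, unless the
# following in-range sample stays with it (two consecutive deviating
# samples indicate a genuine level shift, not an artifact).
derive_valid_mask <- function(fhr, phys_range, max_jump_bpm) {
  n <- length(fhr)
  missing <- is.na(fhr) | fhr == 0
  in_range <- !missing & fhr >= phys_range[1] & fhr <= phys_range[2]
  out_range <- !missing & !in_range
  spike <- rep(FALSE, n)
  idx <- which(in_range)
  last <- NA_real_
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (is.na(last) || abs(fhr[i] - last) <= max_jump_bpm) {
      last <- fhr[i]
    } else {
      follower_stays <- j < length(idx) &&
        abs(fhr[idx[j + 1L]] - fhr[i]) <= max_jump_bpm
      if (follower_stays) last <- fhr[i] else spike[i] <- TRUE
    }
  }
  list(valid = in_range & !spike, missing = missing,
       outlier = out_range | spike)
}

#' @export
print.ctg_record <- function(x, ...) {
  n <- length(x$fhr_bpm)
  cat(sprintf("<ctg_record> %s\n", x$record_id))
  cat(sprintf("  %d samples @ %.3g Hz (%.1f min), week %d, %s, %s\n",
              n, x$fs_hz, n / x$fs_hz / 60, x$gestational_week,
              if (x$singleton) "singleton" else "multiple",
              if (x$antepartum) "antepartum" else "intrapartum"))
  cat(sprintf("  valid: %d (%.1f%%), interpolated: %d, UC: %s\n",
              sum(x$valid_mask), 100 * mean(x$valid_mask),
              sum(x$interpolated_mask),
              if (is.null(x$uc)) "absent" else "present"))
  invisible(x)
}

#' Record length and duration
#'
#' @param record a [ctg_record()].
#' @return `record_duration_s()`: duration in seconds;
#'   `record_duration_min()`: duration in minutes.
#' @export
record_duration_s <- function(record) {
  length(record$fhr_bpm) / record$fs_hz
}

#' @rdname record_duration_s
#' @export
record_duration_min <- function(record) record_duration_s(record) / 60

#' Read and write CTG records
#'
#' The CSV dialect has the header `time_s,fhr_bpm,uc`, one row per sample at
#' a fixed step of `1/fs_hz` seconds; missing FHR is encoded as 0 and the
#' `uc` column is optional. Metadata travel in a JSON sidecar
#' (`<stem>.json`) with fields `record_id`, `fs_hz`, `gestational_week`,
#' `singleton`, `antepartum`. The `json-bundle` format stores samples and
#' metadata in a single JSON file.
#'
#' @param path file path. For `format = "csv"`, the path of the `.csv`
#'   sample file; its sidecar is looked up next to it.
#' @param format `"csv"` (CSV + JSON sidecar) or `"json-bundle"`.
#' @param record a [ctg_record()] to write.
#' @return `load_ctg_record()` returns a [ctg_record()];
#'   `save_ctg_record()` returns `path` invisibly.
#' @export
load_ctg_record <- function(path, format = c("csv", "json-bundle")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_contract(sprintf("file not found: %s", path))
  if (format == "csv") {
    tab <- tryCatch(
      utils::read.csv(path, check.names = FALSE),
      error = function(e) stop_contract(sprintf("malformed CSV %s: %s", path,
                                                conditionMessage(e))))
    req <- c("time_s", "fhr_bpm")
    missing_cols <- setdiff(req, names(tab))
    if (length(missing_cols) > 0L) {
      stop_contract(sprintf("malformed CSV %s: missing column(s) %s",
                            path, paste(missing_cols, collapse = ", ")))
    }
    meta_path <- paste0(sub("\\.csv$", "", path), ".json")
    if (!file.exists(meta_path)) {
      stop_contract(sprintf("metadata sidecar not found: %s", meta_path))
    }
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(meta$fs_hz)) {
      stop_contract(sprintf("configuration error: fs_hz missing in %s", meta_path))
    }
    ctg_record(
      fhr_bpm = tab$fhr_bpm, fs_hz = meta$fs_hz,
      uc = if ("uc" %in% names(tab)) tab$uc else NULL,
      record_id = meta$record_id %||% basename(path),
      gestational_week = meta$gestational_week %||% 38L,
      singleton = meta$singleton %||% TRUE,
      antepartum = meta$antepartum %||% TRUE
    )
  } else {
    b <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(b$fs_hz)) {
      stop_contract(sprintf("configuration error: fs_hz missing in %s", path))
    }
    if (is.null(b$fhr_bpm)) {
      stop_contract(sprintf("malformed bundle %s: field fhr_bpm missing", path))
    }
    ctg_record(
      fhr_bpm = b$fhr_bpm, fs_hz = b$fs_hz, uc = b$uc,
      record_id = b$record_id %||% basename(path),
      gestational_week = b$gestational_week %||% 38L,
      singleton = b$singleton %||% TRUE,
      antepartum = b$antepartum %||% TRUE
    )
  }
}

#' @rdname load_ctg_record
#' @export
save_ctg_record <- function(record, path, format = c("csv", "json-bundle")) {
  format <- match.arg(format)
  meta <- list(record_id = record$record_id, fs_hz = record$fs_hz,
               gestational_week = record$gestational_week,
               singleton = record$singleton, antepartum = record$antepartum)
  if (format == "csv") {
    n <- length(record$fhr_bpm)
    tab <- data.frame(time_s = (seq_len(n) - 1L) / record$fs_hz,
                      fhr_bpm = record$fhr_bpm)
    if (!is.null(record$uc)) tab$uc <- record$uc
    utils::write.csv(tab, path, row.names = FALSE)
    jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    b <- c(meta, list(fhr_bpm = record$fhr_bpm, uc = record$uc))
    jsonlite::write_json(b[!vapply(b, is.null, logical(1))], path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
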