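#' Build the six-bit alarm feature mask
#'
#' Converts a feature row into the ordered six-bit alarm mask
#' `(BRAD, TACH, ACC, DEC, STV, SVB)`, where a bit of 1 flags an alarm
#' condition:
#'
#' * `BRAD`: at least one bradycardia episode;
#' * `TACH`: at least one tachycardia episode;
#' * `ACC`: absence of accelerations (count equals zero);
#' * `DEC`: presence of prolonged decelerations (or of any deceleration
#'   when `dec_any = TRUE`);
#' * `STV`: mean STV strictly below `stv_th` (default cutoff 1.70);
#' * `SVB`: sympatho-vagal balance strictly below `svb_th` (default cutoff
#'   8.20). An undefined SVB (zero HF power) is treated as non-reactive and
#'   sets the bit.
#'
#' The STV and SVB cutoffs are the minimum values these indexes take across
#' gestational weeks 24--42 in normal pregnancies; an absent-variability
#' flag (`stv_absent`, STV below 0.02) necessarily also sets the STV bit.
#'
#' @param f a [ctg_features()] row.
#' @param stv_th STV cutoff in bpm (default 1.70).
#' @param svb_th SVB cutoff, dimensionless (default 8.20).
#' @param dec_any set the DEC bit on any deceleration rather than only on
#'   prolonged ones.
#' @return An object of class `feature_mask`: a named logical vector of
#'   length 6 in the fixed order BRAD, TACH, ACC, DEC, STV, SVB.
#' @export
#' @examples
#' build_feature_mask(ctg_features(acc = 0, stv = 1.72, lf = 1, hf = 1/1.71))
build_feature_mask <- function(f, stv_th = 1.70, svb_th = 8.20,
                               dec_any = FALSE) {
  stopifnot(inherits(f, "ctg_features"))
  svb_bit <- if (is.na(f$svb)) TRUE else f$svb < svb_th
  mask <- c(
    BRAD = f$brad >= 1L,
    TACH = f$tach >= 1L,
    ACC = f$acc == 0L,
    DEC = if (dec_any) f$dec >= 1L else isTRUE(f$prolonged_dec),
    STV = f$stv < stv_th || isTRUE(f$stv_absent),
    SVB = svb_bit
  )
  structure(mask, class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat("<feature_mask> ",
      paste(sprintf("%s=%d", names(x), as.integer(x)), collapse = " "), "\n")
  invisible(x)
}

#' Annotate a CTG trace as normal or suspicious
#'
#' Applies the rule-based suspicion criteria to a feature row and its alarm
#' mask. A trace is suspicious when at least one of the following holds:
#'
#' 1. absence of accelerations and at least one further alarm bit set
#'    (by default the ACC bit itself, which is necessarily 1 in this case,
#'    is not counted; see `criterion1_excludes_acc_bit`);
#' 2. presence of accelerations and at least two alarm bits set;
#' 3. presence of severe tachycardia (mean level above 180 bpm);
#' 4. presence of bradycardia (below 110 bpm for more than 3 min).
#'
#' The labeling pass is repeated once for verification; a disagreement
#' between the two passes would indicate an internal invariant violation
#' and raises an error.
#'
#' @param f a [ctg_features()] row.
#' @param mask optional [build_feature_mask()] result; built from `f` with
#'   the given thresholds when omitted.
#' @param stv_th,svb_th,dec_any passed to [build_feature_mask()] when
#'   `mask` is omitted.
#' @param criterion1_excludes_acc_bit when `TRUE` (default) criterion 1
#'   requires an alarm bit other than ACC; when `FALSE` the ACC bit itself
#'   satisfies it, making criterion 1 fire for every trace without
#'   accelerations.
#' @return An object of class `annotation_result`: list with `label`
#'   (`"normal"` or `"suspicious"`), `mask`, and `triggered_criteria`
#'   (integer subset of 1:4, empty for normal traces).
#' @export
#' @examples
#' f <- ctg_features(acc = 0, stv = 1.72, lf = 1, hf = 1/1.71)
#' annotate_trace(f)
annotate_trace <- function(f, mask = NULL, stv_th = 1.70, svb_th = 8.20,
                           dec_any = FALSE,
                           criterion1_excludes_acc_bit = TRUE) {
  stopifnot(inherits(f, "ctg_features"))
  if (is.null(mask)) {
    mask <- build_feature_mask(f, stv_th = stv_th, svb_th = svb_th,
                               dec_any = dec_any)
  }
  stopifnot(inherits(mask, "feature_mask"), length(mask) == 6L)

  label_once <- function() {
    non_acc <- unclass(mask)[setdiff(names(mask), "ACC")]
    crit <- c(
      `1` = f$acc == 0L && if (criterion1_excludes_acc_bit) any(non_acc) else any(mask),
      `2` = f$acc >= 1L && sum(mask) >= 2L,
      `3` = isTRUE(f$severe_tach),
      `4` = f$brad >= 1L
    )
    which(crit)
  }
  triggered <- label_once()
  verification <- label_once()  # repeated labeling pass
  if (!identical(triggered, verification)) {
    stop("annotation verification pass disagreed with the first pass")
  }
  structure(list(
    record_id = f$record_id,
    label = if (length(triggered) > 0L) "suspicious" else "normal",
    mask = mask,
    triggered_criteria = as.integer(triggered)
  ), class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s: %s", x$record_id, x$label))
  if (length(x$triggered_criteria) > 0L) {
    cat(" (criteria ", paste(x$triggered_criteria, collapse = ","), ")", sep = "")
  }
  cat("\n  mask: ", paste(sprintf("%s=%d", names(x$mask),
                                  as.integer(x$mask)), collapse = " "), "\n")
  invisible(x)
}

#' Annotate a table of feature rows
#'
#' @param features a data.frame with the columns of
#'   [as.data.frame.ctg_features()] (at least BRAD, TACH, ACC, DEC, STV and
#'   SVB; severe_tach, prolonged_dec and stv_absent default to values
#'   consistent with the counts when absent).
#' @param ... passed to [annotate_trace()].
#' @return the input with columns `label` and `criteria` appended.
#' @export
annotate_features <- function(features, ...) {
  stopifnot(is.data.frame(features))
  res <- lapply(seq_len(nrow(features)), function(i) {
    r <- features[i, ]
    f <- ctg_features(
      bl_bpm = r$BL %||% NA_real_, brad = r$BRAD, tach = r$TACH,
      severe_tach = isTRUE(r$severe_tach), acc = r$ACC, dec = r$DEC,
      prolonged_dec = isTRUE(r$prolonged_dec),
      uc_count = r$UC %||% 0L, stv = r$STV,
      stv_absent = isTRUE(r$stv_absent) || (!is.na(r$STV) && r$STV < 0.02),
      vlf = r$VLF %||% NA_real_, lf = r$LF %||% NA_real_,
      hf = r$HF %||% NA_real_, svb = r$SVB,
      record_id = as.character(r$record_id %||% i)
    )
    annotate_trace(f, ...)
  })
  features$label <- vapply(res, `[[`, character(1), "label")
  features$criteria <- vapply(res, function(a) {
    paste(a$triggered_criteria, collapse = ",")
  }, character(1))
  features
}
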