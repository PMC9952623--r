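#' Confusion matrix for binary CTG classification
#'
#' Counts of true positives, false negatives, false positives and true
#' negatives. Following the convention used for CTG screening studies, the
#' positive class is the *normal* trace: sensitivity then measures the
#' ability to recognize normal traces and specificity the ability to
#' recognize suspicious ones.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @param positive_class label of the positive class (default `"normal"`);
#'   the other label defaults to `"suspicious"`.
#' @param negative_class label of the negative class.
#' @return An object of class `confusion_matrix`.
#' @export
#' @examples
#' confusion_matrix(29, 1, 3, 17)
confusion_matrix <- function(tp, fn, fp, tn, positive_class = "normal",
                             negative_class = if (positive_class == "normal")
                               "suspicious" else "normal") {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_contract("confusion-matrix counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_contract("empty confusion matrix")
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 positive_class = positive_class,
                 negative_class = negative_class),
            class = "confusion_matrix")
}

# Swap the positive class: positives become negatives.
swap_confusion <- function(cm) {
  confusion_matrix(tp = cm$tn, fn = cm$fp, fp = cm$fn, tn = cm$tp,
                   positive_class = cm$negative_class,
                   negative_class = cm$positive_class)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(
                paste("actual", c(x$positive_class, x$negative_class)),
                paste("predicted", c(x$positive_class, x$negative_class))))
  cat(sprintf("<confusion_matrix> positive class: %s\n", x$positive_class))
  print(m)
  invisible(x)
}

pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

# Core metric set for one positive class. Percent scale except f_beta.
metrics_one_class <- function(cm, beta = 1) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  sens <- pct(cm$tp, cm$tp + cm$fn)
  spec <- pct(cm$tn, cm$tn + cm$fp)
  prec <- pct(cm$tp, cm$tp + cm$fp)
  fb <- if (is.na(prec) || is.na(sens) || (beta^2 * prec + sens) == 0) NA_real_
        else (1 + beta^2) * (prec / 100) * (sens / 100) /
             (beta^2 * (prec / 100) + (sens / 100))
  c(accuracy = pct(cm$tp + cm$tn, total),
    misclassification_error = pct(cm$fn + cm$fp, total),
    sensitivity = sens, specificity = spec, precision = prec,
    f_beta = fb, g_mean = g_mean(sens, spec))
}

#' Classification metric suite
#'
#' Computes, from a binary confusion matrix, accuracy, misclassification
#' error, sensitivity (recall), specificity, precision, the F-beta score
#' and the G-mean:
#' \deqn{Accuracy = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{Sensitivity = TP/(TP+FN), \quad Specificity = TN/(TN+FP)}
#' \deqn{Precision = TP/(TP+FP)}
#' \deqn{F_\beta = (1+\beta^2)\,\frac{Precision \cdot Sensitivity}
#'       {\beta^2 Precision + Sensitivity}}
#' \deqn{G = \sqrt{Sensitivity \cdot Specificity}}
#' All rate metrics are reported in percent; \eqn{F_\beta} lies in
#' \eqn{[0, 1]}. Metrics are computed per class (each class in turn as the
#' positive one) and aggregated as the plain arithmetic mean and as the
#' class-size-weighted mean (class size over total sample size as weight).
#' Ratios with a zero denominator are reported as `NA` (undefined).
#'
#' @param cm a [confusion_matrix()].
#' @param beta positive F-score weight; 1 gives precision and sensitivity
#'   equal importance.
#' @return An object of class `metrics_report`: list with `per_class`
#'   (data.frame, one row per class), `overall_arithmetic`,
#'   `overall_weighted` (named numeric vectors), `class_sizes`, `beta` and
#'   the source `cm`.
#' @export
#' @examples
#' compute_metrics(confusion_matrix(29, 1, 3, 17))
compute_metrics <- function(cm, beta = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (beta <= 0) stop_contract("beta must be positive")
  pos <- metrics_one_class(cm, beta)
  neg <- metrics_one_class(swap_confusion(cm), beta)
  sizes <- c(cm$tp + cm$fn, cm$fp + cm$tn)
  per_class <- rbind(as.data.frame(t(pos)), as.data.frame(t(neg)))
  per_class <- cbind(class = c(cm$positive_class, cm$negative_class),
                     n = sizes, per_class)
  agg <- function(metric) {
    aggregate_metrics(per_class[[metric]], sizes)
  }
  metrics <- setdiff(names(per_class), c("class", "n"))
  arith <- vapply(metrics, function(m) agg(m)$arithmetic, numeric(1))
  weighted <- vapply(metrics, function(m) agg(m)$weighted, numeric(1))
  structure(list(per_class = per_class, overall_arithmetic = arith,
                 overall_weighted = weighted, class_sizes = sizes,
                 beta = beta, cm = cm),
            class = "metrics_report")
}

#' Aggregate per-class metric values
#'
#' @param values numeric vector of per-class metric values (one per class).
#' @param class_sizes positive class sizes, same length.
#' @return list with `arithmetic` (unweighted mean) and `weighted` (mean
#'   weighted by class size over total size).
#' @export
#' @examples
#' aggregate_metrics(c(96.7, 85.0), c(30, 20))
aggregate_metrics <- function(values, class_sizes) {
  if (length(values) != length(class_sizes) || any(class_sizes <= 0)) {
    stop_contract("values and positive class_sizes must have equal length")
  }
  list(arithmetic = mean(values),
       weighted = sum(values * class_sizes) / sum(class_sizes))
}

#' Geometric mean of sensitivity and specificity
#'
#' @param sensitivity,specificity values in percent (0--100).
#' @return G-mean in percent: `sqrt(sensitivity * specificity)`.
#' @export
#' @examples
#' g_mean(92.0, 89.7)
g_mean <- function(sensitivity, specificity) {
  if (any(is.na(c(sensitivity, specificity)))) return(NA_real_)
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100)
  sqrt(sensitivity * specificity)
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  fmt <- function(v, f = digits) {
    ifelse(is.na(v), "-", formatC(v, format = "f", digits = f))
  }
  cat(sprintf("<metrics_report> positive class: %s (beta = %g)\n",
              x$cm$positive_class, x$beta))
  tab <- x$per_class
  rows <- rbind(
    cbind(label = paste0(tab$class, " class (n=", tab$n, ")"),
          as.data.frame(lapply(tab[-(1:2)], identity))),
    cbind(label = "Overall (arithmetic mean)", as.data.frame(t(x$overall_arithmetic))),
    cbind(label = "Overall (weighted mean)", as.data.frame(t(x$overall_weighted)))
  )
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    cat(sprintf("  %-28s acc %s%%  err %s%%  sens %s%%  spec %s%%  prec %s%%  F%g %s  G %s%%\n",
                r$label, fmt(r$accuracy), fmt(r$misclassification_error),
                fmt(r$sensitivity), fmt(r$specificity), fmt(r$precision),
                x$beta, fmt(r$f_beta, 3), fmt(r$g_mean)))
  }
  invisible(x)
}
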