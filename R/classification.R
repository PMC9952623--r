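#' SVM classifier configuration
#'
#' @param kernel `"rbf"`, `"linear"` or `"polynomial_degree2"` (a
#'   second-order polynomial kernel).
#' @param cost regularization parameter C of the soft-margin SVM.
#' @param gamma RBF/polynomial kernel scale, or `"auto"` for the
#'   `1/n_features` default (with standardized features this equals
#'   `1/(n_features * variance)`).
#' @param standardize z-score the features, with the scaling fit on the
#'   training folds only.
#' @param n_folds number of cross-validation folds (default 10).
#' @param stratified preserve class ratios across folds.
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(kernel = c("rbf", "linear", "polynomial_degree2"),
                              cost = 1, gamma = "auto", standardize = TRUE,
                              n_folds = 10L, stratified = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop_contract("cost must be positive")
  if (n_folds < 2L) stop_contract("n_folds must be at least 2")
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 standardize = isTRUE(standardize),
                 n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Assign samples to cross-validation folds
#'
#' Every sample is assigned to exactly one test fold. With
#' `stratified = TRUE` each class is shuffled separately and dealt
#' round-robin over the folds, preserving the class ratio per fold.
#'
#' @param labels factor or character vector of class labels.
#' @param n_folds number of folds.
#' @param seed integer seed for the shuffle.
#' @param stratified preserve class ratios per fold.
#' @return integer vector of fold ids in `1:n_folds`, one per sample.
#' @export
make_folds <- function(labels, n_folds, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (n_folds > n) stop_contract("n_folds exceeds the number of samples")
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  folds
}

fit_svm <- function(x, y, config) {
  gamma <- if (identical(config$gamma, "auto")) 1 / ncol(x) else config$gamma
  args <- list(x = x, y = y, cost = config$cost, gamma = gamma,
               scale = config$standardize)
  args <- c(args, switch(config$kernel,
    rbf = list(kernel = "radial"),
    linear = list(kernel = "linear"),
    polynomial_degree2 = list(kernel = "polynomial", degree = 2, coef0 = 1)
  ))
  # columns constant within a training fold cannot be z-scored; e1071 leaves
  # them unscaled, which is the intended behavior here
  withCallingHandlers(
    do.call(e1071::svm, args),
    warning = function(w) {
      if (grepl("constant. Cannot scale", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' k-fold cross-validated SVM classification
#'
#' Splits the data into `n_folds` groups, trains the configured SVM on all
#' but one group and predicts the held-out group, so that every sample is
#' tested exactly once. Feature standardization (when enabled) is fit on
#' the training folds only. Both the pooled confusion matrix over all
#' held-out predictions and the per-fold accuracies are reported; the
#' pooled matrix is the default basis of the metric report.
#'
#' @param features numeric matrix or data.frame of feature columns (for CTG
#'   work typically BRAD, TACH, ACC, DEC, STV, SVB).
#' @param labels vector of class labels with exactly two distinct values;
#'   `positive_class` must be one of them.
#' @param config a [classifier_config()].
#' @param positive_class label treated as positive in the confusion matrix
#'   (default `"normal"`, falling back to the first level present).
#' @param beta F-score weight passed to [compute_metrics()].
#' @return An object of class `cv_result`: list with `predictions` (one per
#'   sample, in input order), `folds`, `cm` (pooled [confusion_matrix()]),
#'   `report` (pooled [compute_metrics()]), `fold_accuracy` (percent, one
#'   per fold) and `mean_fold_accuracy`.
#' @export
cross_validate <- function(features, labels, config = classifier_config(),
                           positive_class = NULL, beta = 1) {
  stopifnot(inherits(config, "classifier_config"))
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop_contract("features must be finite numbers")
  labels <- as.character(labels)
  n <- nrow(x)
  if (length(labels) != n) stop_contract("labels length must match the feature rows")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop_contract("cross_validate needs exactly two classes present")
  }
  if (config$n_folds > n) stop_contract("n_folds exceeds the number of samples")
  positive_class <- positive_class %||%
    (if ("normal" %in% classes) "normal" else classes[1])
  if (!positive_class %in% classes) {
    stop_contract("positive_class is not among the labels")
  }
  negative_class <- setdiff(classes, positive_class)

  # Drop constant columns: they carry no information and break z-scoring.
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop_contract("all feature columns are constant")
  x <- x[, keep, drop = FALSE]

  folds <- make_folds(labels, config$n_folds, seed = config$seed,
                      stratified = config$stratified)
  y <- factor(labels, levels = c(positive_class, negative_class))
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_acc <- numeric(config$n_folds)
  for (k in seq_len(config$n_folds)) {
    test <- folds == k
    if (!any(test)) { fold_acc[k] <- NA_real_; next }
    fit <- fit_svm(x[!test, , drop = FALSE], droplevels(y[!test]), config)
    p <- stats::predict(fit, x[test, , drop = FALSE])
    pred[test] <- as.character(p)
    fold_acc[k] <- 100 * mean(as.character(p) == labels[test])
  }

  cm <- confusion_matrix(
    tp = sum(pred == positive_class & labels == positive_class),
    fn = sum(pred == negative_class & labels == positive_class),
    fp = sum(pred == positive_class & labels == negative_class),
    tn = sum(pred == negative_class & labels == negative_class),
    positive_class = positive_class, negative_class = negative_class
  )
  structure(list(
    predictions = as.character(pred), folds = folds, cm = cm,
    report = compute_metrics(cm, beta = beta),
    fold_accuracy = fold_acc,
    mean_fold_accuracy = mean(fold_acc, na.rm = TRUE),
    config = config
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s kernel, %d-fold CV, seed %d\n",
              x$config$kernel, x$config$n_folds, x$config$seed))
  cat(sprintf("  pooled accuracy %.1f%%, mean fold accuracy %.1f%%\n",
              x$report$overall_arithmetic[["accuracy"]],
              x$mean_fold_accuracy))
  print(x$cm)
  invisible(x)
}

#' Compare SVM kernels under the same folds
#'
#' Runs [cross_validate()] once per kernel with an otherwise identical
#' configuration (same folds, cost and scaling).
#'
#' @inheritParams cross_validate
#' @param kernels character vector of kernels to compare.
#' @return data.frame with one row per kernel: pooled accuracy,
#'   sensitivity, specificity, G-mean (percent) and mean fold accuracy.
#' @export
compare_kernels <- function(features, labels,
                            kernels = c("linear", "polynomial_degree2", "rbf"),
                            config = classifier_config(), ...) {
  rows <- lapply(kernels, function(k) {
    cfg <- config
    cfg$kernel <- k
    cv <- cross_validate(features, labels, cfg, ...)
    pos <- cv$report$per_class[1, ]
    data.frame(kernel = k,
               accuracy = pos$accuracy,
               sensitivity = pos$sensitivity,
               specificity = pos$specificity,
               g_mean = pos$g_mean,
               mean_fold_accuracy = cv$mean_fold_accuracy)
  })
  do.call(rbind, rows)
}
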