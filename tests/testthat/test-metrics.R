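test_that("the published confusion matrix reproduces the full metric table", {
  cm <- confusion_matrix(tp = 29, fn = 1, fp = 3, tn = 17)
  rep <- compute_metrics(cm)
  norm <- rep$per_class[1, ]   # normal class as positive
  susp <- rep$per_class[2, ]

  expect_equal(round(norm$accuracy, 1), 92.0)
  expect_equal(round(norm$misclassification_error, 1), 8.0)
  expect_equal(round(norm$sensitivity, 1), 96.7)
  expect_equal(round(norm$specificity, 1), 85.0)
  expect_equal(round(norm$precision, 1), 90.6)
  expect_equal(norm$f_beta, 0.935, tolerance = 0.001)

  expect_equal(round(susp$sensitivity, 1), 85.0)
  expect_equal(round(susp$specificity, 1), 96.7)
  expect_equal(round(susp$precision, 1), 94.4)
  expect_equal(susp$f_beta, 0.894, tolerance = 0.001)

  expect_equal(rep$class_sizes, c(30, 20))
  expect_equal(round(rep$overall_arithmetic[["accuracy"]], 1), 92.0)
  expect_equal(round(rep$overall_arithmetic[["sensitivity"]], 1), 90.8)
})

test_that("accuracy and misclassification error always sum to 100", {
  set.seed(8)
  for (trial in 1:30) {
    counts <- sample(0:40, 4, replace = TRUE)
    if (sum(counts) == 0) next
    rep <- compute_metrics(confusion_matrix(counts[1], counts[2],
                                            counts[3], counts[4]))
    expect_equal(rep$per_class$accuracy[1] +
                   rep$per_class$misclassification_error[1], 100)
  }
})

test_that("metrics equal integer-arithmetic fractions on random matrices", {
  set.seed(9)
  for (trial in 1:50) {
    counts <- sample(0:50, 4, replace = TRUE)
    if (sum(counts) == 0) next
    cm <- confusion_matrix(counts[1], counts[2], counts[3], counts[4])
    got <- compute_metrics(cm)$per_class[1, ]
    want <- oracle_metrics(counts[1], counts[2], counts[3], counts[4])
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$precision, want$precision)
    if (!is.na(got$sensitivity) && !is.na(got$specificity)) {
      expect_equal(got$g_mean, sqrt(want$sensitivity * want$specificity))
    }
  }
})

test_that("swapping the positive class swaps the paired metrics", {
  set.seed(10)
  for (trial in 1:20) {
    counts <- sample(1:30, 4)
    rep <- compute_metrics(confusion_matrix(counts[1], counts[2],
                                            counts[3], counts[4]))
    a <- rep$per_class[1, ]; b <- rep$per_class[2, ]
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
    expect_equal(a$accuracy, b$accuracy)
  }
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(13)
  for (trial in 1:20) {
    counts <- sample(1:30, 4)
    m <- compute_metrics(confusion_matrix(counts[1], counts[2],
                                          counts[3], counts[4]))$per_class[1, ]
    p <- m$precision / 100; s <- m$sensitivity / 100
    expect_equal(m$f_beta, 2 * p * s / (p + s))
  }
  # beta weights sensitivity more heavily when > 1
  cm <- confusion_matrix(20, 10, 2, 30)
  f1 <- compute_metrics(cm, beta = 1)$per_class$f_beta[1]
  f2 <- compute_metrics(cm, beta = 2)$per_class$f_beta[1]
  expect_lt(f2, f1)   # sensitivity (66.7%) is the weaker of the pair
})

test_that("degenerate matrices give undefined markers, not errors", {
  perfect <- compute_metrics(confusion_matrix(25, 0, 0, 25))$per_class[1, ]
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$f_beta, 1)
  expect_equal(perfect$g_mean, 100)

  no_pos_pred <- compute_metrics(confusion_matrix(0, 10, 0, 10))$per_class[1, ]
  expect_true(is.na(no_pos_pred$precision))
  expect_error(confusion_matrix(0, 0, 0, 0), "empty")
  expect_error(confusion_matrix(-1, 2, 3, 4), "non-negative")
})

test_that("aggregation reproduces the published overall rows", {
  # sensitivities of the two classes, sizes 30/20
  sens <- aggregate_metrics(c(96.7, 85.0), c(30, 20))
  expect_equal(round(sens$weighted, 1), 92.0)
  expect_equal(sens$arithmetic, 90.85)
  spec <- aggregate_metrics(c(85.0, 96.7), c(30, 20))
  expect_equal(round(spec$weighted, 1), 89.7)
  # equal per-class values are invariant under both aggregations
  both <- aggregate_metrics(c(77.7, 77.7), c(12, 34))
  expect_equal(both$arithmetic, 77.7)
  expect_equal(both$weighted, 77.7)
})

test_that("the G-mean reproduces the published summary values", {
  expect_equal(round(g_mean(92.0, 89.7), 1), 90.8)
  expect_equal(round(g_mean(90.4, 73.9), 1), 81.7)
  expect_equal(g_mean(100, 0), 0)
  expect_error(g_mean(110, 50), ">= 0|<= 100")
})
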