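# Feature rows mirroring the published worked examples: a reactive normal
# trace and a non-reactive suspicious trace.
normal_example <- function() {
  ctg_features(brad = 0, tach = 0, acc = 9, dec = 0, stv = 2.77,
               lf = 8.88, hf = 1)                      # SVB 8.88
}
suspicious_example <- function() {
  ctg_features(brad = 0, tach = 0, acc = 0, dec = 0, stv = 1.72,
               lf = 1.71, hf = 1)                      # SVB 1.71
}

test_that("the two worked examples reproduce mask and label exactly", {
  m_norm <- build_feature_mask(normal_example())
  expect_equal(as.integer(m_norm), c(0, 0, 0, 0, 0, 0))
  a_norm <- annotate_trace(normal_example())
  expect_equal(a_norm$label, "normal")
  expect_length(a_norm$triggered_criteria, 0)

  m_susp <- build_feature_mask(suspicious_example())
  expect_equal(names(m_susp), c("BRAD", "TACH", "ACC", "DEC", "STV", "SVB"))
  expect_equal(as.integer(m_susp), c(0, 0, 1, 0, 0, 1))
  a_susp <- annotate_trace(suspicious_example())
  expect_equal(a_susp$label, "suspicious")
  expect_equal(a_susp$triggered_criteria, 1L)
})

test_that("the STV and SVB cutoffs are strict-below comparisons", {
  just_below <- ctg_features(acc = 5, stv = 1.69, lf = 9, hf = 1)
  expect_equal(as.integer(build_feature_mask(just_below)),
               c(0, 0, 0, 0, 1, 0))
  at_cutoff <- ctg_features(acc = 5, stv = 1.70, lf = 8.20, hf = 1)
  expect_equal(as.integer(build_feature_mask(at_cutoff)),
               c(0, 0, 0, 0, 0, 0))
  # thresholds are configurable
  expect_equal(as.integer(build_feature_mask(at_cutoff, stv_th = 2))[5], 1)
})

test_that("special feature states set the expected bits", {
  # undefined SVB counts as non-reactive
  undef <- ctg_features(acc = 3, stv = 2.5, svb = NA_real_)
  expect_equal(as.integer(build_feature_mask(undef))[6], 1)
  # absent variability necessarily sets the STV bit
  absent <- ctg_features(acc = 3, stv = 0.01, stv_absent = TRUE, lf = 9, hf = 1)
  expect_equal(as.integer(build_feature_mask(absent))[5], 1)
  # prolonged vs any deceleration policy
  dec_only <- ctg_features(acc = 3, dec = 2, prolonged_dec = FALSE,
                           stv = 2.5, lf = 9, hf = 1)
  expect_equal(as.integer(build_feature_mask(dec_only))[4], 0)
  expect_equal(as.integer(build_feature_mask(dec_only, dec_any = TRUE))[4], 1)
})

test_that("each suspicion criterion fires on its own pattern", {
  # criterion 2: accelerations present, two alarm bits
  two_bits <- ctg_features(acc = 4, stv = 1.2, lf = 2, hf = 1)
  a2 <- annotate_trace(two_bits)
  expect_equal(a2$label, "suspicious")
  expect_true(2L %in% a2$triggered_criteria)
  # one bit with accelerations present stays normal
  one_bit <- ctg_features(acc = 4, stv = 1.2, lf = 9, hf = 1)
  expect_equal(annotate_trace(one_bit)$label, "normal")
  # criterion 3: severe tachycardia alone
  sev <- ctg_features(tach = 1, severe_tach = TRUE, acc = 5, stv = 2.5,
                      lf = 20, hf = 1)
  a3 <- annotate_trace(sev)
  expect_equal(a3$label, "suspicious")
  expect_true(3L %in% a3$triggered_criteria)
  # criterion 4: any bradycardia episode
  brad <- ctg_features(brad = 1, acc = 5, stv = 2.5, lf = 20, hf = 1)
  a4 <- annotate_trace(brad)
  expect_equal(a4$label, "suspicious")
  expect_true(4L %in% a4$triggered_criteria)
})

test_that("labels match a brute-force rule oracle over the full truth table", {
  bit_grid <- expand.grid(BRAD = 0:1, TACH = 0:1, ACC = 0:1, DEC = 0:1,
                          STV = 0:1, SVB = 0:1)
  for (i in seq_len(nrow(bit_grid))) {
    bits <- unlist(bit_grid[i, ])
    for (severe in c(FALSE, TRUE)) {
      if (severe && bits[["TACH"]] == 0) next  # inconsistent state
      # construct a feature row that reproduces exactly this mask
      f <- ctg_features(
        brad = bits[["BRAD"]], tach = bits[["TACH"]],
        severe_tach = severe,
        acc = if (bits[["ACC"]] == 1) 0L else 3L,
        dec = bits[["DEC"]], prolonged_dec = bits[["DEC"]] == 1,
        stv = if (bits[["STV"]] == 1) 1.0 else 2.5,
        lf = if (bits[["SVB"]] == 1) 2 else 12, hf = 1)
      mask <- build_feature_mask(f)
      expect_equal(as.integer(mask), unname(bits))
      got <- annotate_trace(f, mask)$label
      want <- oracle_annotation(mask, acc = f$acc, severe_tach = severe,
                                brad = f$brad)
      expect_identical(got, want)
    }
  }
})

test_that("annotation is deterministic and monotone in the mask bits", {
  f <- ctg_features(acc = 0, stv = 2.5, lf = 2, hf = 1)
  expect_identical(annotate_trace(f), annotate_trace(f))
  # adding an alarm bit can never turn suspicious into normal
  bit_grid <- expand.grid(BRAD = 0:1, TACH = 0:1, ACC = 0:1, DEC = 0:1,
                          STV = 0:1, SVB = 0:1)
  label_for <- function(bits, acc) {
    mask <- structure(as.logical(bits), names = names(bits),
                      class = "feature_mask")
    f <- ctg_features(brad = bits[["BRAD"]], tach = bits[["TACH"]],
                      acc = acc, stv = 2.5, lf = 12, hf = 1)
    annotate_trace(f, mask)$label
  }
  for (i in seq_len(nrow(bit_grid))) {
    bits <- unlist(bit_grid[i, ])
    acc <- if (bits[["ACC"]] == 1) 0L else 3L
    base_label <- label_for(bits, acc)
    if (base_label == "suspicious") {
      for (j in which(bits == 0)) {
        # flipping the ACC bit changes the acc count consistently
        up <- bits; up[j] <- 1L
        acc_up <- if (up[["ACC"]] == 1) 0L else 3L
        expect_identical(label_for(up, acc_up), "suspicious")
      }
    }
  }
})

test_that("criterion 1 can be relaxed to count the ACC bit itself", {
  # no accelerations, nothing else wrong
  f <- ctg_features(acc = 0, stv = 2.5, lf = 12, hf = 1)
  expect_equal(annotate_trace(f)$label, "normal")
  relaxed <- annotate_trace(f, criterion1_excludes_acc_bit = FALSE)
  expect_equal(relaxed$label, "suspicious")
})

test_that("a feature table is annotated row-wise", {
  tab <- data.frame(record_id = c("a", "b"),
                    BRAD = c(0, 0), TACH = c(0, 0), ACC = c(9, 0),
                    DEC = c(0, 0), STV = c(2.77, 1.72), SVB = c(8.88, 1.71))
  out <- annotate_features(tab)
  expect_equal(out$label, c("normal", "suspicious"))
  expect_equal(out$criteria, c("", "1"))
})
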