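test_that("confusion counts match per-pixel enumeration", {
  set.seed(1)
  gt <- random_mask(16, 16)
  expect_identical(unclass(confusion(gt, gt))[c("fp", "fn")],
                   list(fp = 0L, fn = 0L))
  inv <- 1 - gt
  ci <- confusion(inv, gt)
  expect_identical(ci$tp, 0L)
  expect_identical(ci$tn, 0L)

  roi <- build_roi_mask(16, 16, c(0.1, 0.1, 0.1))
  for (i in 1:5) {
    pred <- random_mask(16, 16)
    gt2 <- random_mask(16, 16)
    got <- confusion(pred, gt2, roi)
    ref <- oracle_confusion(pred, gt2, roi$mask)
    expect_identical(unclass(got)[names(ref)], ref)
    expect_identical(got$tp + got$fp + got$fn + got$tn,
                     as.integer(sum(roi$mask)))
  }
})

test_that("metric formulas match their definitions", {
  cc <- structure(list(tp = 6L, fp = 2L, fn = 2L, tn = 90L),
                  class = "confusion_counts")
  expect_equal(iou(cc), 0.6)
  expect_equal(dsc(cc), 0.75)
  expect_equal(accuracy(cc), 0.96)
  expect_equal(sensitivity(cc), 0.75)
  expect_equal(specificity(cc), 90 / 92)

  perfect <- structure(list(tp = 10L, fp = 0L, fn = 0L, tn = 90L),
                       class = "confusion_counts")
  for (f in list(accuracy, sensitivity, specificity, iou, dsc)) {
    expect_equal(f(perfect), 1)
  }

  # empty prediction and empty ground truth: overlap undefined, accuracy 1
  empty <- structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 64L),
                     class = "confusion_counts")
  expect_true(is.na(iou(empty)))
  expect_true(is.na(dsc(empty)))
  expect_true(is.na(sensitivity(empty)))
  expect_equal(accuracy(empty), 1)
})

test_that("dsc and iou obey their algebraic identity", {
  set.seed(2)
  for (i in 1:20) {
    cc <- structure(as.list(stats::setNames(sample.int(50, 4),
                                            c("tp", "fp", "fn", "tn"))),
                    class = "confusion_counts")
    expect_equal(dsc(cc), 2 * iou(cc) / (1 + iou(cc)), tolerance = 1e-12)
  }
})

test_that("bootstrap CIs behave on constant, mixed, and growing samples", {
  b <- bootstrap_mean_ci(rep(0.4, 25), seed = 1L)
  expect_equal(b$mean, 0.4)
  expect_equal(b$lo, 0.4)
  expect_equal(b$hi, 0.4)

  b1 <- bootstrap_mean_ci(c(0.1, 0.5, 0.9, 0.3), seed = 9L)
  b2 <- bootstrap_mean_ci(c(0.1, 0.5, 0.9, 0.3), seed = 9L)
  expect_identical(b1, b2)

  v <- rep(c(0, 1), each = 50)
  b3 <- bootstrap_mean_ci(v, n_resamples = 1000L, seed = 3L)
  expect_lt(b3$lo, 0.5)
  expect_gt(b3$hi, 0.5)
  expect_lt(abs((b3$hi - 0.5) - (0.5 - b3$lo)), 0.05)

  # CI width shrinks with sample size
  set.seed(4)
  small <- stats::rnorm(20)
  big <- stats::rnorm(200)
  w_small <- with(bootstrap_mean_ci(small, seed = 5L), hi - lo)
  w_big <- with(bootstrap_mean_ci(big, seed = 5L), hi - lo)
  expect_lt(w_big, w_small)
  expect_error(bootstrap_mean_ci(numeric(0)), "empty")
})

test_that("paired t-test matches the closed form and flags zero variance", {
  a <- c(0.61, 0.55, 0.70, 0.48, 0.66, 0.59, 0.62, 0.51)
  z <- paired_ttest(a, a)
  expect_true(z$zero_variance)
  expect_true(is.na(z$t_statistic))

  # constant shift has zero difference variance too
  expect_true(paired_ttest(a, a + 0.1)$zero_variance)
  # with tiny jitter the shift is detected
  set.seed(6)
  b <- a + 0.1 + stats::rnorm(8, 0, 1e-3)
  pt <- paired_ttest(b, a)
  expect_lt(pt$p_value, 0.05)

  set.seed(7)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  got <- paired_ttest(x, y)
  d <- x - y
  t_ref <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(got$t_statistic, t_ref, tolerance = 1e-10)
  expect_equal(got$p_value,
               2 * stats::pt(-abs(t_ref), df = length(d) - 1),
               tolerance = 1e-10)
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("set evaluation aggregates per-frame metrics with bootstrap CIs", {
  gt <- lapply(1:4, function(i) {
    m <- matrix(0, 12, 12); m[4:6, 4:6] <- 1; m
  })
  rep_perfect <- evaluate_masks(gt, gt, seed = 1L)
  s <- rep_perfect$summary
  expect_true(all(s$mean == 1))
  expect_true(all(s$ci_lo == 1 & s$ci_hi == 1))
  expect_identical(tidy(rep_perfect), s)
  expect_equal(glance(rep_perfect)$iou, 1)
  expect_s3_class(autoplot(rep_perfect), "ggplot")

  single <- evaluate_masks(gt[1], gt[1], seed = 1L)
  expect_equal(single$summary$ci_lo, single$summary$ci_hi)

  # aggregate equals the brute-force average of hand-computed per-frame IoU
  pred <- gt
  pred[[2]][4, 4] <- 0          # one miss: tp 8, fn 1 -> IoU 8/9
  pred[[3]][10, 10] <- 1        # one false alarm: IoU 9/10
  r <- evaluate_masks(pred, gt, seed = 2L)
  expect_equal(r$summary$mean[r$summary$metric == "iou"],
               mean(c(1, 8 / 9, 9 / 10, 1)), tolerance = 1e-12)
  # undefined frames are excluded and counted
  pred2 <- list(matrix(0, 12, 12))
  gt2 <- list(matrix(0, 12, 12))
  r2 <- evaluate_masks(pred2, gt2, seed = 3L)
  expect_identical(r2$summary$n_undefined[r2$summary$metric == "iou"], 1L)
  expect_true(is.na(r2$summary$mean[r2$summary$metric == "iou"]))
})
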