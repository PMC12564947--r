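test_that("error maps are channel-averaged absolute residuals", {
  img <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  expect_true(all(boluseg:::error_map_from(img, img) == 0))

  shifted <- img
  shifted[, , 2] <- shifted[, , 2] + 0.2
  em <- boluseg:::error_map_from(img, shifted)
  expect_equal(em, matrix(0.2 / 3, 8, 8), tolerance = 1e-12)

  # random pair against direct per-pixel enumeration
  rec <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  em2 <- boluseg:::error_map_from(img, rec)
  for (i in sample(64, 8)) {
    r <- ((i - 1) %% 8) + 1; c <- ((i - 1) %/% 8) + 1
    expect_equal(em2[r, c], mean(abs(img[r, c, ] - rec[r, c, ])),
                 tolerance = 1e-12)
  }

  # a real (untrained) model: exported path equals the manual computation
  set.seed(4)
  model <- build_autoencoder(model_config(5L, c(2L, 3L, 4L)))
  enc <- assemble_input(array(stats::runif(16 * 16 * 3), c(16, 16, 3)),
                        preprocess_config(use_pe = TRUE))
  em3 <- reconstruction_error(enc, model)
  rec3 <- reconstruct(model, enc$channels)
  expect_equal(em3, boluseg:::error_map_from(enc$channels[, , 1:3], rec3))
  expect_true(all(em3 >= 0))
  expect_error(reconstruction_error(
    assemble_input(matrix(0.5, 16, 16), preprocess_config(use_pe = FALSE)),
    model), "channels")
})

test_that("threshold calibration equals the pooled ROI mean of the errors", {
  set.seed(5)
  model <- build_autoencoder(model_config(5L, c(2L, 3L, 4L)))
  inputs <- lapply(1:4, function(i) {
    assemble_input(array(stats::runif(16 * 16 * 3), c(16, 16, 3)),
                   preprocess_config(use_pe = TRUE))
  })
  roi <- build_roi_mask(16, 16, c(0.1, 0.1, 0.1))
  cal <- calibrate_threshold(model, inputs, multiplier = 1, roi = roi)
  pooled <- unlist(lapply(inputs, function(inp) {
    em <- reconstruction_error(inp, model)
    em[roi$mask > 0]
  }))
  expect_equal(cal$tau, mean(pooled), tolerance = 1e-12)
  expect_equal(cal$n_validation_frames, 4L)
  # linearity in the multiplier
  cal2 <- calibrate_threshold(model, inputs, multiplier = 2, roi = roi)
  expect_equal(cal2$tau, 2 * cal$tau, tolerance = 1e-12)
  expect_error(calibrate_threshold(model, list()), "empty")
})

test_that("thresholding is exact, monotone in tau, and ROI-contained", {
  # all-zero error map: empty mask
  z <- apply_threshold(matrix(0, 12, 12), tau = 0.1)
  expect_true(all(z$mask == 0))

  # constructed square just above tau
  em <- matrix(0, 20, 20)
  em[8:12, 8:12] <- 0.1 + 1e-6
  roi <- build_roi_mask(20, 20, c(0.1, 0.1, 0.1))
  sq <- apply_threshold(em, tau = 0.1, roi = roi)
  expect_equal(sum(sq$mask), 25)
  expect_true(all(which(sq$mask == 1) %in% which(em > 0.1)))

  # the 25-pixel component is removed when the area floor is 30
  sq2 <- apply_threshold(em, tau = 0.1, roi = roi, min_component_area = 30L)
  expect_true(all(sq2$mask == 0))
  sq3 <- apply_threshold(em, tau = 0.1, roi = roi, min_component_area = 25L)
  expect_equal(sum(sq3$mask), 25)

  # monotonicity: raising tau never adds pixels
  set.seed(6)
  em_r <- matrix(stats::runif(400), 20, 20)
  taus <- sort(stats::runif(10))
  prev <- apply_threshold(em_r, taus[1], roi = roi)$mask
  for (tau in taus[-1]) {
    cur <- apply_threshold(em_r, tau, roi = roi)$mask
    expect_true(all(cur <= prev))
    prev <- cur
  }
  # ROI containment for any tau
  expect_true(all(apply_threshold(em_r, 0.01, roi = roi)$mask * (1 - roi$mask) == 0))
})

test_that("component labelling agrees with a breadth-first-search oracle", {
  set.seed(7)
  for (i in 1:5) {
    m <- random_mask(15, 15, p = 0.35)
    ours <- boluseg:::label_components(m)
    ref <- oracle_label(m)
    expect_identical(max(ours), max(ref))
    # label partitions agree up to renumbering
    for (k in seq_len(max(ref))) {
      expect_equal(length(unique(ours[ref == k])), 1L)
    }
  }
})

test_that("dataset segmentation splits, calibrates once, and is reproducible", {
  set.seed(8)
  model <- build_autoencoder(model_config(5L, c(2L, 3L, 4L)))
  inputs <- lapply(1:10, function(i) {
    assemble_input(array(stats::runif(16 * 16 * 3), c(16, 16, 3)),
                   preprocess_config(use_pe = TRUE))
  })
  roi <- build_roi_mask(16, 16)
  seg <- segment_dataset(inputs, model, calibration_fraction = 0.1,
                         roi = roi, seed = 3L)
  expect_length(seg$calibration_idx, 1L)
  expect_length(seg$masks, 9L)
  expect_identical(sum(seg$manifest$role == "calibration"), 1L)

  seg2 <- segment_dataset(inputs, model, calibration_fraction = 0.1,
                          roi = roi, seed = 3L)
  expect_identical(seg$calibration_idx, seg2$calibration_idx)
  expect_identical(lapply(seg$masks, `[[`, "mask"),
                   lapply(seg2$masks, `[[`, "mask"))
})
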