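test_that("mean field is deterministic, bounded, and spatially structured", {
  spec <- phantom_spec(seed = 7L)
  f1 <- build_mean_field(spec)
  f2 <- build_mean_field(spec)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
  expect_identical(f1[, , 1], f1[, , 2])
  expect_identical(f1[, , 1], f1[, , 3])
  # location must matter: disjoint regions differ in mean appearance
  expect_gte(max(f1) - min(f1), 0.2)

  flat <- build_mean_field(phantom_spec(n_blobs = 0L, base_intensity = 0.3))
  expect_true(all(flat == 0.3))
})

test_that("mean field rejects degenerate specs", {
  expect_error(phantom_spec(height = 8L), "height")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
})

test_that("background sampling matches the generating model", {
  # noiseless, jitter-free limit reproduces the field exactly
  spec0 <- phantom_spec(noise_sigma = 0, jitter_px = 0L, seed = 3L)
  field0 <- build_mean_field(spec0)
  set.seed(1)
  fr0 <- sample_background_frame(field0, spec0)
  expect_identical(fr0$image, field0)
  expect_false(fr0$has_anomaly)
  expect_true(all(fr0$mask == 0))

  # replaying the same stream state reproduces the frame bit-identically
  set.seed(99)
  a <- sample_background_frame(field0, phantom_spec(seed = 3L))
  set.seed(99)
  b <- sample_background_frame(field0, phantom_spec(seed = 3L))
  expect_identical(a, b)

  # sampled noise recovers the generating sigma within 10% over 200 frames
  spec <- phantom_spec(noise_sigma = 0.05, jitter_px = 0L,
                       base_intensity = 0.3, blob_amplitude = 0.3, seed = 3L)
  field <- build_mean_field(spec)
  set.seed(42)
  devs <- unlist(lapply(1:200, function(i) {
    fr <- sample_background_frame(field, spec)
    as.vector(fr$image - field)
  }))
  expect_lt(abs(stats::sd(devs) - 0.05) / 0.05, 0.1)
})

test_that("sampled ensembles recover the mean field within Monte-Carlo error", {
  # field kept well inside [0, 1] so clipping cannot bias the ensemble mean
  spec <- phantom_spec(n_blobs = 5L, noise_sigma = 0.05, jitter_px = 0L,
                       blob_amplitude = 0.06, base_intensity = 0.4, seed = 1L)
  field <- build_mean_field(spec)
  expect_lt(max(field) + 4.5 * spec$noise_sigma, 1)
  set.seed(7)
  acc <- array(0, dim(field))
  n <- 500L
  for (i in seq_len(n)) {
    acc <- acc + sample_background_frame(field, spec)$image
  }
  emp <- acc / n
  se <- spec$noise_sigma / sqrt(n)
  # pointwise 3 SE holds for essentially all pixels; the global bound uses
  # a level adjusted for testing every pixel simultaneously
  expect_gte(mean(abs(emp - field) <= 3 * se), 0.99)
  expect_true(all(abs(emp - field) <= 4.5 * se))
})

test_that("additive anomaly injection is exact on mask pixels", {
  spec <- phantom_spec(noise_sigma = 0, jitter_px = 0L, seed = 2L)
  field <- build_mean_field(spec)
  set.seed(10)
  fr <- sample_background_frame(field, spec)

  # delta = 0: image unchanged, mask still marks the ellipse
  set.seed(11)
  null_fr <- inject_anomaly(fr, anomaly_spec(delta = 0), field)
  expect_identical(null_fr$image, fr$image)
  expect_true(null_fr$has_anomaly)
  expect_gt(sum(null_fr$mask), 0)

  # moderate delta on a zero-noise frame: exact offset inside, zero outside
  set.seed(11)
  an <- inject_anomaly(fr, anomaly_spec(delta = 0.2), field)
  d <- an$image[, , 1] - fr$image[, , 1]
  inside <- an$mask > 0
  clipped <- fr$image[, , 1][inside] + 0.2 > 1
  expect_true(all(abs(d[inside][!clipped] - 0.2) < 1e-12))
  expect_true(all(d[!inside] == 0))

  # injecting into an anomalous frame is refused
  expect_error(inject_anomaly(an, anomaly_spec(), field), "already contains")
})

test_that("anomalies that cannot fit are rejected after bounded resampling", {
  spec <- phantom_spec(noise_sigma = 0, jitter_px = 0L, seed = 2L)
  field <- build_mean_field(spec)
  set.seed(1)
  fr <- sample_background_frame(field, spec)
  big <- anomaly_spec(semi_axes = c(40, 40))
  set.seed(1)
  expect_error(inject_anomaly(fr, big, field), "could not place")
})

test_that("transplanted anomalies copy contrasting field values from elsewhere", {
  spec <- phantom_spec(noise_sigma = 0, jitter_px = 0L, seed = 4L)
  field <- build_mean_field(spec)
  set.seed(21)
  fr <- sample_background_frame(field, spec)
  a <- anomaly_spec(mode = "transplanted")
  set.seed(22)
  an <- inject_anomaly(fr, a, field)
  inside <- an$mask > 0
  # values inside the mask all occur in the mean field (globally familiar)
  expect_true(all(round(an$image[, , 1][inside], 10) %in%
                    round(as.vector(field[, , 1]), 10)))
  # and deviate from the local field mean by at least the contrast floor
  expect_gte(abs(mean(an$image[, , 1][inside]) - mean(field[, , 1][inside])),
             a$min_transplant_contrast)
})

test_that("dataset generation respects splits, determinism, and component counts", {
  spec <- phantom_spec(seed = 6L)
  ds1 <- generate_phantom_dataset(spec, n_train = 10L, n_test_clean = 2L,
                                  n_test_anom = 0L, seed = 6L)
  expect_true(all(!ds1$manifest$has_anomaly))
  expect_true(all(vapply(ds1$frames, function(f) sum(f$mask) == 0, logical(1))))

  ds2 <- generate_phantom_dataset(spec, n_train = 10L, n_test_clean = 2L,
                                  n_test_anom = 0L, seed = 6L)
  expect_identical(ds1$frames, ds2$frames)

  ds3 <- generate_phantom_dataset(spec, anomaly_spec(count_per_frame = 1L),
                                  n_train = 0L, n_test_clean = 0L,
                                  n_test_anom = 20L, seed = 8L)
  n_comp <- vapply(ds3$frames, function(f) max(oracle_label(f$mask)), integer(1))
  expect_identical(n_comp, rep(1L, 20L))
})

test_that("datasets round-trip to the frame-directory layout", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(height = 32L, width = 32L, seed = 9L)
  ds <- generate_phantom_dataset(spec, anomaly_spec(semi_axes = c(6, 4)),
                                 n_train = 3L, n_test_clean = 1L,
                                 n_test_anom = 2L, seed = 9L, dir = dir)
  expect_length(list.files(file.path(dir, "frames")), 6L)
  expect_length(list.files(file.path(dir, "masks")), 6L)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$seed, 9L)
  expect_length(man$splits$train, 3L)
  # masks stored as 0/255 binary PNG; anomalous frames have nonzero masks
  m <- png::readPNG(file.path(dir, "masks", "frame_000006.png"))
  expect_true(all(m %in% c(0, 1)))
  expect_gt(sum(m), 0)
  # quantized frames reload within 8-bit precision
  f <- png::readPNG(file.path(dir, "frames", "frame_000001.png"))
  expect_lt(max(abs(f - ds$frames[[1]]$image)), 1 / 255)
})
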