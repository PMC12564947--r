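test_that("black-border cropping removes exactly the dark margin", {
  img <- matrix(0.6, 20, 24)
  framed <- matrix(0, 26, 30)
  framed[4:23, 4:27] <- img
  cr <- crop_black_borders(framed, 0.02)
  expect_equal(unname(cr$crop_box), c(4, 23, 4, 27))
  expect_identical(cr$image, img)

  # no qualifying border: identity crop
  cr2 <- crop_black_borders(img, 0.02)
  expect_equal(unname(cr2$crop_box), c(1, 20, 1, 24))
  expect_identical(cr2$image, img)

  # left-only border: only left columns removed (brute-force scan agrees)
  left <- cbind(matrix(0, 20, 3), img)
  cr3 <- crop_black_borders(left, 0.02)
  dark_cols <- which(colMeans(left) <= 0.02)
  expect_equal(unname(cr3$crop_box["left"]), max(dark_cols) + 1L)
  expect_equal(unname(cr3$crop_box[c("top", "bottom", "right")]),
               c(1L, 20L, ncol(left)))

  expect_error(crop_black_borders(matrix(0, 5, 5)), "unusable")
})

test_that("min-max normalization maps to [0,1] and handles degenerate frames", {
  expect_equal(minmax_normalize(matrix(c(10, 20, 30), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_true(all(minmax_normalize(matrix(5, 4, 4)) == 0))
  ok <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_equal(minmax_normalize(ok), ok)
})

test_that("positional encoding matches the sinusoidal definition", {
  pe <- positional_encoding(4, 4)
  # sin at quarter periods across columns, cos at quarter periods down rows
  expect_equal(pe[1, , 1], c(0, 1, 0, -1), tolerance = 1e-12)
  expect_equal(pe[, 1, 2], c(1, 0, -1, 0), tolerance = 1e-12)

  pe2 <- positional_encoding(13, 37)
  expect_lte(max(abs(pe2)), 1)
  expect_equal(pe2[1, 1, ], c(0, 1), tolerance = 1e-15)
  # separability: channel 1 constant down columns, channel 2 along rows
  expect_true(all(apply(pe2[, , 1], 2, function(col) all(col == col[1]))))
  expect_true(all(apply(pe2[, , 2], 1, function(row) all(row == row[1]))))
})

test_that("input assembly appends PE channels and replicates grayscale", {
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  e3 <- assemble_input(img, preprocess_config(use_pe = FALSE))
  expect_equal(dim(e3$channels), c(16L, 16L, 3L))
  expect_identical(e3$channels, img)

  e5 <- assemble_input(img, preprocess_config(use_pe = TRUE))
  expect_equal(dim(e5$channels), c(16L, 16L, 5L))
  expect_identical(e5$channels[, , 4:5], positional_encoding(16, 16))
  # dropping the PE channels recovers the no-PE input exactly
  expect_identical(e5$channels[, , 1:3], e3$channels)

  gray <- matrix(stats::runif(64), 8, 8)
  eg <- assemble_input(gray, preprocess_config(use_pe = TRUE))
  expect_identical(eg$channels[, , 1], eg$channels[, , 2])
  expect_identical(eg$channels[, , 1], eg$channels[, , 3])
  expect_identical(eg$channels[, , 1], gray)
})

test_that("ROI masks exclude exactly the left/right/top margins", {
  all_in <- build_roi_mask(10, 10, c(0, 0, 0))
  expect_true(all(all_in$mask == 1))

  r <- build_roi_mask(10, 10, c(0.1, 0.1, 0.1))
  expect_equal(sum(r$mask), 72)  # 9 rows x 8 columns by direct enumeration
  expect_true(all(r$mask[, 1] == 0))
  expect_true(all(r$mask[, 10] == 0))
  expect_true(all(r$mask[1, ] == 0))
  # bottom row is always retained (margins 0.4 leave columns 5:6)
  expect_true(all(build_roi_mask(10, 10, c(0.4, 0.4, 0.4))$mask[10, 5:6] == 1))

  expect_error(build_roi_mask(10, 10, c(0.5, 0, 0)), "margins")
  expect_error(build_roi_mask(10, 10, c(-0.1, 0, 0)), "margins")
})

test_that("preprocessing is idempotent on already-processed frames", {
  set.seed(1)
  cfg <- preprocess_config(target_size = 32L)
  raw <- matrix(stats::runif(64 * 48, 0.2, 0.9), 64, 48)
  once <- preprocess_frame(raw, cfg)
  img_once <- once$channels[, , 1:3]
  twice <- preprocess_frame(img_once, cfg)
  expect_equal(twice$channels, once$channels, tolerance = 1e-12)
})

test_that("bilinear resizing preserves smooth ramps", {
  # value increases across columns, constant down each column
  ramp <- matrix(seq(0, 1, length.out = 32), 32, 32, byrow = TRUE)
  small <- resize_frame(ramp, 16, 16)
  expect_equal(dim(small), c(16L, 16L))
  expect_true(all(diff(small[8, ]) > 0))
  expect_lt(max(abs(small[1, ] - small[16, ])), 1e-9)
  # non-square targets keep the (rows, columns) orientation
  rect <- resize_frame(ramp, 8, 24)
  expect_equal(dim(rect), c(8L, 24L))
  expect_true(all(diff(rect[4, ]) > 0))
})
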