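#' Preprocessing configuration
#'
#' @param target_size Square output size in pixels after resizing (>= 16,
#'   divisible by 8 for the autoencoder).
#' @param border_threshold Mean-intensity fraction in \[0, 1\] below which a
#'   border row/column counts as black.
#' @param use_pe Append the two sinusoidal positional-encoding channels.
#' @param roi_margins Fractions `c(left, right, top)` of the frame excluded
#'   from analysis, each in \[0, 0.5).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 256L, border_threshold = 0.02,
                              use_pe = TRUE, roi_margins = c(0.1, 0.1, 0.1)) {
  stop_if_not_scalar_number(target_size, "target_size", 16)
  stop_if_not_scalar_number(border_threshold, "border_threshold", 0, 1)
  structure(list(target_size = as.integer(target_size),
                 border_threshold = border_threshold,
                 use_pe = isTRUE(use_pe),
                 roi_margins = roi_margins),
            class = "preprocess_config")
}

#' Crop black borders
#'
#' Removes the maximal contiguous border rows and columns whose mean
#' intensity (averaged over channels) is at or below `threshold`. Frames
#' with no qualifying border are returned unchanged with a full-frame crop
#' box.
#'
#' @param image An `H x W` matrix or `H x W x C` array in \[0, 1\].
#' @param threshold Intensity fraction at or below which a border row or
#'   column counts as black.
#' @return List with `image` (cropped) and `crop_box`
#'   `c(top, bottom, left, right)` — the retained 1-based inclusive range of
#'   the original frame.
#' @export
crop_black_borders <- function(image, threshold = 0.02) {
  gray <- if (is.matrix(image)) image else apply(image, c(1, 2), mean)
  H <- nrow(gray); W <- ncol(gray)
  row_dark <- rowMeans(gray) <= threshold
  col_dark <- colMeans(gray) <= threshold
  if (all(row_dark) || all(col_dark)) {
    stop("entire frame is at or below the border threshold; frame unusable",
         call. = FALSE)
  }
  run_from <- function(dark) {
    n <- 0L
    for (d in dark) {
      if (!d) break
      n <- n + 1L
    }
    n
  }
  top <- run_from(row_dark) + 1L
  bottom <- H - run_from(rev(row_dark))
  left <- run_from(col_dark) + 1L
  right <- W - run_from(rev(col_dark))
  cropped <- if (is.matrix(image)) {
    image[top:bottom, left:right, drop = FALSE]
  } else {
    image[top:bottom, left:right, , drop = FALSE]
  }
  list(image = cropped, crop_box = c(top = top, bottom = bottom,
                                     left = left, right = right))
}

#' Per-frame min-max normalization
#'
#' Rescales a frame to exactly \[0, 1\] via `(I - min) / (max - min)`.
#' Constant frames map to all-zeros.
#'
#' @param image Numeric matrix or array.
#' @return Normalized image of the same shape.
#' @export
minmax_normalize <- function(image) {
  r <- range(image)
  if (r[1] == r[2]) return(image * 0)
  (image - r[1]) / (r[2] - r[1])
}

#' Resize a frame with bilinear interpolation
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @param height,width Target size in pixels.
#' @return Resized image.
#' @export
resize_frame <- function(image, height, width) {
  out <- EBImage::resize(image, w = height, h = width, filter = "bilinear")
  if (is.matrix(image)) as.matrix(out) else array(out, c(height, width, dim(image)[3]))
}

#' Sinusoidal positional encoding
#'
#' Two fixed channels encoding pixel coordinates: channel 1 holds
#' `sin(2*pi*x / width)` (constant down columns), channel 2 holds
#' `cos(2*pi*y / height)` (constant along rows), with 0-based pixel indices
#' `x` (column) and `y` (row). Values lie in \[-1, 1\]. Note the encoding
#' spans one full period, so it is not injective: two columns (or rows) can
#' share a value.
#'
#' @param height,width Frame size in pixels (>= 1).
#' @return An `height x width x 2` array.
#' @export
positional_encoding <- function(height, width) {
  sx <- sin(2 * pi * (seq_len(width) - 1L) / width)
  cy <- cos(2 * pi * (seq_len(height) - 1L) / height)
  pe <- array(0, c(height, width, 2L))
  pe[, , 1L] <- matrix(sx, height, width, byrow = TRUE)
  pe[, , 2L] <- matrix(cy, height, width)
  pe
}

#' Assemble model input channels
#'
#' Replicates a grayscale frame to three channels if needed and, when
#' `use_pe` is set, appends the two positional-encoding channels, yielding
#' the 5-channel (or 3-channel) input representation.
#'
#' @param image Preprocessed (cropped, resized, normalized) `H x W` matrix
#'   or `H x W x {1,3}` array with values in \[0, 1\].
#' @param config A [preprocess_config()].
#' @param crop_box Optional provenance crop box from
#'   [crop_black_borders()].
#' @return An `encoded_input`: list with `channels` (`H x W x C`,
#'   `C` in \{3, 5\}) and `crop_box`.
#' @export
assemble_input <- function(image, config = preprocess_config(),
                           crop_box = NULL) {
  img <- as_rgb_array(image)
  d <- dim(img)
  channels <- if (config$use_pe) {
    out <- array(0, c(d[1], d[2], 5L))
    out[, , 1:3] <- img
    out[, , 4:5] <- positional_encoding(d[1], d[2])
    out
  } else {
    img
  }
  structure(list(channels = channels, crop_box = crop_box),
            class = "encoded_input")
}

#' @export
print.encoded_input <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<encoded_input> %dx%d, %d channels%s\n", d[1], d[2], d[3],
              if (d[3] == 5L) " (image + positional encoding)" else ""))
  invisible(x)
}

#' Build a rectangular region-of-interest mask
#'
#' Excludes the left, right, and upper borders of the frame (VFSS protocols
#' leave gaps between those borders and the head/neck); the bottom edge is
#' always retained.
#'
#' @param height,width Frame size in pixels.
#' @param margins Fractions `c(left, right, top)` in \[0, 0.5); the mask
#'   zeroes the left `floor(left * width)` columns, right
#'   `floor(right * width)` columns, and top `floor(top * height)` rows.
#' @return A `roi_mask`: list with binary `mask` and `margins`.
#' @export
build_roi_mask <- function(height, width, margins = c(0.1, 0.1, 0.1)) {
  if (length(margins) != 3L || any(margins < 0) || any(margins >= 0.5)) {
    stop("margins must be three fractions in [0, 0.5)", call. = FALSE)
  }
  if (margins[1] + margins[2] >= 1) {
    stop("left and right margins sum to >= 1; no columns would remain",
         call. = FALSE)
  }
  l <- floor(margins[1] * width)
  r <- floor(margins[2] * width)
  t <- floor(margins[3] * height)
  mask <- matrix(1, height, width)
  if (l > 0) mask[, seq_len(l)] <- 0
  if (r > 0) mask[, (width - r + 1L):width] <- 0
  if (t > 0) mask[seq_len(t), ] <- 0
  structure(list(mask = mask, margins = margins), class = "roi_mask")
}

roi_matrix <- function(roi, H, W) {
  if (is.null(roi)) return(matrix(TRUE, H, W))
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  stopifnot(identical(dim(m), c(H, W)))
  m > 0
}

#' Preprocess a raw frame end to end
#'
#' Applies the full chain: black-border crop, bilinear resize to
#' `target_size`, per-frame min-max normalization, and channel assembly
#' (with positional encoding when configured).
#'
#' @param image Raw `H x W` or `H x W x C` frame in \[0, 1\].
#' @param config A [preprocess_config()].
#' @return An `encoded_input`.
#' @export
preprocess_frame <- function(image, config = preprocess_config()) {
  cr <- crop_black_borders(image, config$border_threshold)
  rs <- resize_frame(cr$image, config$target_size, config$target_size)
  assemble_input(minmax_normalize(rs), config, crop_box = cr$crop_box)
}

#' Read a frame image from disk
#'
#' Reads 8- or 16-bit PNG (and grayscale TIFF via EBImage) into an
#' `H x W` or `H x W x C` array in \[0, 1\].
#'
#' @param path Path to a `.png` or `.tif`/`.tiff` file.
#' @return Numeric matrix or array.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) >= 2L) img <- aperm(img, c(2L, 1L, seq_along(dim(img))[-(1:2)]))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  img
}
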