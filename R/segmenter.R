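#' Per-pixel reconstruction error map
#'
#' The anomaly signal: for each pixel, the mean over the three image
#' channels of the absolute difference between the input frame and its
#' reconstruction. Zero exactly where the reconstruction matches the input
#' on all channels.
#'
#' @param input An `encoded_input` (or `[H, W, C]` array) with channel
#'   count matching the model.
#' @param model A trained `autoencoder`.
#' @return An `H x W` nonnegative matrix.
#' @export
reconstruction_error <- function(input, model) {
  ch <- if (inherits(input, "encoded_input")) input$channels else input
  if (dim(ch)[3] != model$config$in_channels) {
    stop(sprintf("input has %d channels but the model expects %d",
                 dim(ch)[3], model$config$in_channels), call. = FALSE)
  }
  recon <- reconstruct(model, ch)
  error_map_from(ch[, , 1:3, drop = FALSE], recon)
}

error_map_from <- function(image3, recon3) {
  (abs(image3[, , 1] - recon3[, , 1]) +
     abs(image3[, , 2] - recon3[, , 2]) +
     abs(image3[, , 3] - recon3[, , 3])) / 3
}

#' Calibrate the adaptive segmentation threshold
#'
#' The threshold tau is `multiplier` times the mean reconstruction error
#' pooled over all pixels of the validation frames — by default restricted
#' to pixels inside the region of interest, so excluded borders do not bias
#' the statistic.
#'
#' @param model A trained `autoencoder`.
#' @param validation_inputs Nonempty list of `encoded_input` objects (the
#'   seeded validation subset of the evaluation set).
#' @param multiplier Scale factor k applied to the pooled mean (default 1).
#' @param roi Optional `roi_mask` (or binary matrix); `NULL` pools over all
#'   pixels.
#' @return A `threshold_calibration`: list with `tau`, `multiplier`, and
#'   `n_validation_frames`.
#' @export
calibrate_threshold <- function(model, validation_inputs, multiplier = 1,
                                roi = NULL) {
  if (length(validation_inputs) == 0L) {
    stop("empty validation set", call. = FALSE)
  }
  if (inherits(validation_inputs, "encoded_input")) {
    validation_inputs <- list(validation_inputs)
  }
  pooled <- unlist(lapply(validation_inputs, function(inp) {
    err <- reconstruction_error(inp, model)
    keep <- roi_matrix(roi, nrow(err), ncol(err))
    err[keep]
  }))
  structure(list(tau = multiplier * mean(pooled), multiplier = multiplier,
                 n_validation_frames = length(validation_inputs)),
            class = "threshold_calibration")
}

#' Threshold an error map into a binary mask
#'
#' `mask = (error > tau) AND roi`; connected components (8-connectivity)
#' smaller than `min_component_area` pixels are removed when that is
#' positive. Deterministic.
#'
#' @param error_map `H x W` nonnegative matrix.
#' @param tau Threshold in error units (or a `threshold_calibration`).
#' @param roi Optional `roi_mask` or binary matrix.
#' @param min_component_area Minimum retained component size in pixels
#'   (0 disables the filter).
#' @return A `segmentation_mask`: list with binary `mask`, `roi_applied`,
#'   and `tau`.
#' @export
apply_threshold <- function(error_map, tau, roi = NULL,
                            min_component_area = 0L) {
  if (inherits(tau, "threshold_calibration")) tau <- tau$tau
  keep <- roi_matrix(roi, nrow(error_map), ncol(error_map))
  m <- (error_map > tau) & keep
  if (min_component_area > 0 && any(m)) {
    lab <- label_components(m * 1)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_component_area)
    if (length(small)) m[lab %in% small] <- FALSE
  }
  structure(list(mask = m * 1, roi_applied = !is.null(roi), tau = tau),
            class = "segmentation_mask")
}

#' Segment a single frame
#'
#' @param input An `encoded_input`.
#' @param model A trained `autoencoder`.
#' @param calibration A `threshold_calibration` from
#'   [calibrate_threshold()].
#' @param roi Optional `roi_mask`.
#' @param min_component_area Minimum retained component size in pixels.
#' @return A `segmentation_mask`.
#' @export
segment_frame <- function(input, model, calibration, roi = NULL,
                          min_component_area = 0L) {
  err <- reconstruction_error(input, model)
  apply_threshold(err, calibration, roi, min_component_area)
}

#' Segment an evaluation set with seeded threshold calibration
#'
#' Draws a seeded uniform fraction of the frames as the calibration subset,
#' computes tau once from their pooled reconstruction errors, and segments
#' the remaining frames. Calibration frames are excluded from the returned
#' segmentations so downstream evaluation never scores the frames that set
#' the threshold.
#'
#' @param inputs List of `encoded_input` objects (the evaluation set).
#' @param model A trained `autoencoder`.
#' @param calibration_fraction Fraction used for calibration (default 0.1).
#' @param multiplier Threshold multiplier k.
#' @param roi Optional `roi_mask`.
#' @param min_component_area Minimum retained component size in pixels.
#' @param seed Integer seed for the calibration split.
#' @return List with `masks` (named list of `segmentation_mask`, names =
#'   original frame indices), `calibration`, `calibration_idx`, and
#'   `manifest` (tibble: index, role).
#' @export
segment_dataset <- function(inputs, model, calibration_fraction = 0.1,
                            multiplier = 1, roi = NULL,
                            min_component_area = 0L, seed = 1L) {
  N <- length(inputs)
  if (N < 2L) stop("need at least 2 frames to calibrate and segment", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_cal <- max(1L, round(calibration_fraction * N))
  cal_idx <- sort(sample.int(N, n_cal))
  calib <- calibrate_threshold(model, inputs[cal_idx], multiplier, roi)
  seg_idx <- setdiff(seq_len(N), cal_idx)
  masks <- lapply(seg_idx, function(i) {
    segment_frame(inputs[[i]], model, calib, roi, min_component_area)
  })
  names(masks) <- seg_idx
  list(
    masks = masks, calibration = calib, calibration_idx = cal_idx,
    manifest = tibble::tibble(
      index = seq_len(N),
      role = ifelse(seq_len(N) %in% cal_idx, "calibration", "segmented")
    )
  )
}
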