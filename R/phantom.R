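#' Phantom specification
#'
#' Parameters of the synthetic fluoroscopy-like frame model used to exercise
#' the pipeline without clinical data. Background frames are drawn from a
#' location-conditioned Gaussian model: a fixed smooth mean field mu(x, y)
#' (anatomy-like Gaussian intensity blobs on a constant base), per-pixel
#' Gaussian noise of standard deviation `noise_sigma`, and a small rigid
#' per-frame translation of the structures (up to `jitter_px` pixels)
#' emulating physiologic motion such as hyoid excursion that an anomaly
#' detector must tolerate.
#'
#' @param height,width Frame size in pixels (each >= 16).
#' @param n_blobs Number of anatomy-like Gaussian intensity structures.
#' @param blob_amplitude Peak blob intensity above the base, in \[0, 1\].
#' @param noise_sigma Per-pixel Gaussian noise standard deviation in
#'   intensity units (>= 0); the same noise realization is shared by the
#'   three channels, as the anatomy is grayscale.
#' @param jitter_px Maximum per-frame translation, in pixels (>= 0).
#' @param base_intensity Background intensity of the structure-free field.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   mean field and frame stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64L, width = 64L, n_blobs = 6L,
                         blob_amplitude = 0.5, noise_sigma = 0.02,
                         jitter_px = 1L, base_intensity = 0.15, seed = 1L) {
  stop_if_not_scalar_number(height, "height", 16)
  stop_if_not_scalar_number(width, "width", 16)
  stop_if_not_scalar_number(n_blobs, "n_blobs", 0)
  stop_if_not_scalar_number(blob_amplitude, "blob_amplitude", 0, 1)
  stop_if_not_scalar_number(noise_sigma, "noise_sigma", 0)
  stop_if_not_scalar_number(jitter_px, "jitter_px", 0)
  stop_if_not_scalar_number(base_intensity, "base_intensity", 0, 1)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_blobs = as.integer(n_blobs), blob_amplitude = blob_amplitude,
    noise_sigma = noise_sigma, jitter_px = as.integer(jitter_px),
    base_intensity = base_intensity, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Anomaly specification
#'
#' Describes bolus- or residue-like elliptical anomalies injected into
#' phantom frames together with exact ground-truth masks. `additive` mode
#' offsets the intensity inside the ellipse by `delta` (a direct intensity
#' deviation from the learned mean appearance). `transplanted` mode copies
#' mean-field values from a disjoint, brighter source location, producing an
#' anomaly whose appearance is globally familiar but spatially inconsistent
#' — the scenario that distinguishes a location-aware model from a purely
#' local one.
#'
#' @param semi_axes Ellipse semi-axes `(a, b)` in pixels: `a` along x
#'   (columns), `b` along y (rows).
#' @param center_region Rectangle `c(xmin, xmax, ymin, ymax)` in pixel
#'   coordinates from which anomaly centers are drawn, or `NULL` for the
#'   central 60% of the frame.
#' @param mode `"additive"` or `"transplanted"`.
#' @param delta Intensity offset in \[-1, 1\] for additive mode (reported
#'   pre-clipping); ignored for transplanted mode.
#' @param count_per_frame Number of anomalies injected per frame (>= 1).
#' @param min_transplant_contrast Minimum excess of the source-region field
#'   mean over the target-region mean (transplanted mode), so the transplant
#'   is a real deviation and not an invisible copy.
#' @return An object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(semi_axes = c(12, 9), center_region = NULL,
                         mode = c("additive", "transplanted"), delta = 0.4,
                         count_per_frame = 1L, min_transplant_contrast = 0.15) {
  mode <- match.arg(mode)
  if (length(semi_axes) != 2L || any(semi_axes < 1)) {
    stop("semi_axes must be two values >= 1", call. = FALSE)
  }
  stop_if_not_scalar_number(delta, "delta", -1, 1)
  stop_if_not_scalar_number(count_per_frame, "count_per_frame", 1)
  structure(list(
    shape = "ellipse", semi_axes = as.numeric(semi_axes),
    center_region = center_region, mode = mode, delta = delta,
    count_per_frame = as.integer(count_per_frame),
    min_transplant_contrast = min_transplant_contrast
  ), class = "anomaly_spec")
}

phantom_frame <- function(image, mask, frame_id, has_anomaly) {
  stopifnot(identical(dim(image)[1:2], dim(mask)))
  if (has_anomaly != any(mask > 0)) {
    stop("mask must be all-zero iff has_anomaly is FALSE", call. = FALSE)
  }
  structure(list(image = image, mask = mask, frame_id = as.integer(frame_id),
                 has_anomaly = isTRUE(has_anomaly)),
            class = "phantom_frame")
}

#' Build the phantom mean field
#'
#' Deterministically constructs mu(x, y): `n_blobs` two-dimensional Gaussian
#' intensity bumps placed by the seeded stream on a constant base, clipped
#' to \[0, 1\] and replicated over three channels (grayscale anatomy). The
#' placement guarantees that disjoint regions of the field differ in mean,
#' so spatial location carries information.
#'
#' @param spec A [phantom_spec()].
#' @return An `height x width x 3` array in \[0, 1\].
#' @export
build_mean_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  f <- matrix(spec$base_intensity, H, W)
  if (spec$n_blobs > 0L) {
    ys <- matrix(seq_len(H), H, W)
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(spec$n_blobs)) {
      cy <- stats::runif(1, 0.15 * H, 0.85 * H)
      cx <- stats::runif(1, 0.15 * W, 0.85 * W)
      sy <- stats::runif(1, 0.08, 0.16) * H
      sx <- stats::runif(1, 0.08, 0.16) * W
      amp <- stats::runif(1, 0.6, 1) * spec$blob_amplitude
      f <- f + amp * exp(-((ys - cy)^2 / (2 * sy^2) + (xs - cx)^2 / (2 * sx^2)))
    }
  }
  f <- clip01(f)
  array(f, c(H, W, 3L))
}

# save/restore the session RNG so seeded builders do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# rigid translation with edge replication: shifted[h, w] = f[h - dy, w - dx]
shift_field <- function(field, dy, dx) {
  d <- dim(field)
  rows <- pmin(pmax(seq_len(d[1]) - dy, 1L), d[1])
  cols <- pmin(pmax(seq_len(d[2]) - dx, 1L), d[2])
  field[rows, cols, , drop = FALSE]
}

#' Sample an anomaly-free background frame
#'
#' Draws one frame from the phantom model: the mean field is rigidly
#' jittered by up to `jitter_px` pixels, per-pixel Gaussian noise of
#' standard deviation `noise_sigma` is added (one realization shared across
#' the three channels), and the result is clipped to \[0, 1\]. Random draws
#' come from the session RNG, so the caller controls the stream with
#' `set.seed()`.
#'
#' @param field Mean field from [build_mean_field()].
#' @param spec The matching [phantom_spec()].
#' @param frame_id Integer identifier stored on the frame.
#' @return A `phantom_frame` with an all-zero mask.
#' @export
sample_background_frame <- function(field, spec, frame_id = 0L) {
  stopifnot(identical(dim(field)[1:2], c(spec$height, spec$width)))
  img <- field
  if (spec$jitter_px > 0L) {
    dy <- sample.int(2L * spec$jitter_px + 1L, 1L) - spec$jitter_px - 1L
    dx <- sample.int(2L * spec$jitter_px + 1L, 1L) - spec$jitter_px - 1L
    img <- shift_field(img, dy, dx)
  }
  if (spec$noise_sigma > 0) {
    noise <- matrix(stats::rnorm(spec$height * spec$width, 0, spec$noise_sigma),
                    spec$height, spec$width)
    img <- img + array(noise, dim(img))
  }
  phantom_frame(clip01(img), matrix(0, spec$height, spec$width),
                frame_id, FALSE)
}

ellipse_mask <- function(H, W, cy, cx, a, b) {
  ys <- matrix(seq_len(H), H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

default_center_region <- function(H, W) {
  c(0.2 * W, 0.8 * W, 0.2 * H, 0.8 * H)
}

# draw a center from the region such that the ellipse fits inside the frame
# and avoids `avoid` (an existing mask); bounded rejection sampling
draw_center <- function(H, W, region, a, b, avoid = NULL, tries = 200L) {
  for (i in seq_len(tries)) {
    cx <- stats::runif(1, region[1], region[2])
    cy <- stats::runif(1, region[3], region[4])
    if (cx - a < 1 || cx + a > W || cy - b < 1 || cy + b > H) next
    if (!is.null(avoid)) {
      m <- ellipse_mask(H, W, cy, cx, a, b)
      if (any(m & avoid)) next
    }
    return(c(cy = cy, cx = cx))
  }
  stop("could not place anomaly: ellipse does not fit in the center region ",
       "after ", tries, " attempts", call. = FALSE)
}

#' Inject an elliptical anomaly into a frame
#'
#' Adds `count_per_frame` elliptical anomalies to an anomaly-free frame and
#' records them exactly in the ground-truth mask. In `additive` mode the
#' image inside each ellipse is offset by `delta` (then clipped); in
#' `transplanted` mode it is replaced by mean-field values read from a
#' disjoint, brighter source location, so only spatial context distinguishes
#' it from the background. Centers and source locations are drawn from the
#' session RNG with bounded rejection sampling.
#'
#' @param frame A `phantom_frame` with `has_anomaly = FALSE`.
#' @param anomaly An [anomaly_spec()].
#' @param field The mean field of the generating [phantom_spec()] (used for
#'   transplanted mode).
#' @return The modified `phantom_frame` with `has_anomaly = TRUE`.
#' @export
inject_anomaly <- function(frame, anomaly, field) {
  stopifnot(inherits(frame, "phantom_frame"), inherits(anomaly, "anomaly_spec"))
  if (frame$has_anomaly) stop("frame already contains an anomaly", call. = FALSE)
  H <- dim(frame$image)[1]; W <- dim(frame$image)[2]
  a <- anomaly$semi_axes[1]; b <- anomaly$semi_axes[2]
  region <- anomaly$center_region %||% default_center_region(H, W)
  img <- frame$image
  mask <- frame$mask > 0
  for (k in seq_len(anomaly$count_per_frame)) {
    if (anomaly$mode == "transplanted") {
      # jointly draw target and source so a sufficiently contrasting,
      # disjoint source always exists for the accepted target
      drawn <- NULL
      for (attempt in 1:20) {
        ctr_try <- draw_center(H, W, region, a, b,
                               avoid = if (any(mask)) mask else NULL)
        em_try <- ellipse_mask(H, W, ctr_try["cy"], ctr_try["cx"], a, b)
        src_try <- try(draw_transplant_source(
          field, H, W, ctr_try, a, b, em_try,
          anomaly$min_transplant_contrast, tries = 100L), silent = TRUE)
        if (!inherits(src_try, "try-error")) {
          drawn <- list(ctr = ctr_try, em = em_try, src = src_try)
          break
        }
      }
      if (is.null(drawn)) {
        stop("could not place a transplanted anomaly with the required ",
             "contrast; reduce semi_axes or min_transplant_contrast",
             call. = FALSE)
      }
      ctr <- drawn$ctr; em <- drawn$em; src <- drawn$src
    } else {
      ctr <- draw_center(H, W, region, a, b,
                         avoid = if (any(mask)) mask else NULL)
      em <- ellipse_mask(H, W, ctr["cy"], ctr["cx"], a, b)
    }
    if (anomaly$mode == "additive") {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[em] <- plane[em] + anomaly$delta
        img[, , ch] <- plane
      }
    } else {
      tgt_idx <- which(em)
      rows <- ((tgt_idx - 1L) %% H) + 1L + round(src["cy"] - ctr["cy"])
      cols <- ((tgt_idx - 1L) %/% H) + 1L + round(src["cx"] - ctr["cx"])
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[tgt_idx] <- field[cbind(rows, cols, ch)]
        img[, , ch] <- plane
      }
    }
    mask <- mask | em
  }
  phantom_frame(clip01(img), mask * 1, frame$frame_id, TRUE)
}

# source location for transplanted anomalies: same ellipse, fully inside the
# frame, disjoint from the target, with |source mean - target mean| of the
# field at least `contrast`, so the transplant is a real deviation at the
# target location while its appearance remains familiar from elsewhere
draw_transplant_source <- function(field, H, W, ctr, a, b, target_mask,
                                   contrast, tries = 400L) {
  tgt_mean <- mean(field[, , 1][target_mask])
  for (i in seq_len(tries)) {
    cx <- stats::runif(1, a + 1, W - a)
    cy <- stats::runif(1, b + 1, H - b)
    sm <- ellipse_mask(H, W, cy, cx, a, b)
    if (any(sm & target_mask)) next
    if (abs(mean(field[, , 1][sm]) - tgt_mean) < contrast) next
    return(c(cy = cy, cx = cx))
  }
  stop("could not find a disjoint transplant source with the required ",
       "contrast; reduce semi_axes or min_transplant_contrast", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a seeded phantom dataset
#'
#' Produces an anomaly-free training split and a test split mixing clean and
#' anomalous frames, with exact ground-truth masks. Fully deterministic
#' given the spec and `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param anomaly An [anomaly_spec()] (used for the anomalous test frames).
#' @param n_train,n_test_clean,n_test_anom Split sizes (>= 0).
#' @param seed Stream seed for frame sampling (defaults to `spec$seed`).
#' @param dir Optional directory; when given, frames and masks are written
#'   as 8-bit PNGs under `frames/` and `masks/` with a `manifest.yaml`.
#' @return A `phantom_dataset`: list with `frames` (list of
#'   `phantom_frame`), `field`, `manifest` (tibble with `frame_id`, `split`,
#'   `has_anomaly`), `spec`, and `anomaly`.
#' @export
generate_phantom_dataset <- function(spec, anomaly = anomaly_spec(),
                                     n_train = 200L, n_test_clean = 20L,
                                     n_test_anom = 20L, seed = spec$seed,
                                     dir = NULL) {
  stopifnot(n_train >= 0, n_test_clean >= 0, n_test_anom >= 0)
  field <- build_mean_field(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_total <- n_train + n_test_clean + n_test_anom
  frames <- vector("list", n_total)
  split <- c(rep("train", n_train), rep("test", n_test_clean + n_test_anom))
  anom <- c(rep(FALSE, n_train + n_test_clean), rep(TRUE, n_test_anom))
  for (i in seq_len(n_total)) {
    fr <- sample_background_frame(field, spec, frame_id = i)
    if (anom[i]) fr <- inject_anomaly(fr, anomaly, field)
    frames[[i]] <- fr
  }
  ds <- structure(list(
    frames = frames, field = field,
    manifest = tibble::tibble(frame_id = seq_len(n_total), split = split,
                              has_anomaly = anom),
    spec = spec, anomaly = anomaly, seed = as.integer(seed)
  ), class = "phantom_dataset")
  if (!is.null(dir)) write_phantom_dataset(ds, dir)
  ds
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %dx%d, %d train / %d test (%d anomalous)\n",
              x$spec$height, x$spec$width, sum(x$manifest$split == "train"),
              sum(x$manifest$split == "test"), sum(x$manifest$has_anomaly)))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Frame-directory layout: `frames/frame_%06d.png` (8-bit grayscale-in-RGB),
#' `masks/frame_%06d.png` (0/255 binary), and `manifest.yaml` recording the
#' spec, seed, and split membership.
#'
#' @param ds A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(ds, dir) {
  fdir <- file.path(dir, "frames"); mdir <- file.path(dir, "masks")
  for (d in c(fdir, mdir)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (fr in ds$frames) {
    fn <- sprintf("frame_%06d.png", fr$frame_id)
    ok <- try(png::writePNG(round(fr$image * 255) / 255, file.path(fdir, fn)),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("failed to write ", file.path(fdir, fn), call. = FALSE)
    }
    png::writePNG((fr$mask > 0) * 1, file.path(mdir, fn))
  }
  yaml::write_yaml(list(
    spec = unclass(ds$spec), seed = ds$seed,
    anomaly = unclass(ds$anomaly)[c("shape", "semi_axes", "mode", "delta",
                                    "count_per_frame")],
    splits = list(train = ds$manifest$frame_id[ds$manifest$split == "train"],
                  test = ds$manifest$frame_id[ds$manifest$split == "test"]),
    anomalous = ds$manifest$frame_id[ds$manifest$has_anomaly]
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
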