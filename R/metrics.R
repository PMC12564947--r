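#' Pixel-wise confusion counts
#'
#' Compares a predicted binary mask against a ground-truth mask, restricted
#' to region-of-interest pixels when an ROI is given.
#'
#' @param pred_mask,gt_mask Binary matrices (or `segmentation_mask` /
#'   `phantom_frame`-style masks) of identical size.
#' @param roi Optional `roi_mask` or binary matrix.
#' @return A `confusion_counts`: list with integers `tp`, `fp`, `fn`, `tn`
#'   summing to the number of evaluated pixels.
#' @export
confusion <- function(pred_mask, gt_mask, roi = NULL) {
  p <- as_binary_mask(pred_mask)
  g <- as_binary_mask(gt_mask)
  if (!identical(dim(p), dim(g))) {
    stop("predicted and ground-truth masks must have identical dimensions",
         call. = FALSE)
  }
  keep <- roi_matrix(roi, nrow(p), ncol(p))
  p <- p[keep]; g <- g[keep]
  structure(list(
    tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g)
  ), class = "confusion_counts")
}

as_binary_mask <- function(m) {
  if (inherits(m, "segmentation_mask")) m <- m$mask
  if (inherits(m, "phantom_frame")) m <- m$mask
  stopifnot(is.matrix(m))
  m > 0
}

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Segmentation metrics from confusion counts
#'
#' The five standard pixel-level metrics. A metric whose denominator is
#' zero is undefined and returned as `NA` (and excluded, with a count, from
#' aggregation in [evaluate_masks()]).
#'
#' @param c A `confusion_counts` from [confusion()].
#' @return A single number in \[0, 1\], or `NA` if undefined.
#' @name segmentation-metrics
NULL

#' @rdname segmentation-metrics
#' @export
accuracy <- function(c) ratio_or_na(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn)

#' @rdname segmentation-metrics
#' @export
sensitivity <- function(c) ratio_or_na(c$tp, c$tp + c$fn)

#' @rdname segmentation-metrics
#' @export
specificity <- function(c) ratio_or_na(c$tn, c$tn + c$fp)

#' @rdname segmentation-metrics
#' @export
iou <- function(c) ratio_or_na(c$tp, c$tp + c$fp + c$fn)

#' @rdname segmentation-metrics
#' @export
dsc <- function(c) ratio_or_na(2 * c$tp, 2 * c$tp + c$fp + c$fn)

#' Bootstrap mean with percentile confidence interval
#'
#' Resamples the values with replacement at the original size
#' (`n_resamples` times, seeded) and returns the sample mean with the
#' 2.5/97.5 percentile interval of the resampled means.
#'
#' @param values Nonempty numeric vector.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Named list: `mean`, `lo`, `hi`.
#' @export
bootstrap_mean_ci <- function(values, n_resamples = 1000L, seed = NULL,
                              conf = 0.95) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- length(values)
  means <- vapply(seq_len(n_resamples), function(i) {
    mean(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  a <- (1 - conf) / 2
  qs <- unname(stats::quantile(means, c(a, 1 - a), type = 7))
  list(mean = mean(values), lo = qs[1], hi = qs[2])
}

#' Paired t-test on per-frame metric values
#'
#' Standard two-sided paired t-test (via [stats::t.test()]) on the
#' frame-wise differences. When the differences have zero variance the
#' statistic is undefined; this is reported explicitly rather than as a
#' spurious result.
#'
#' @param values_a,values_b Numeric vectors of equal length (>= 2), paired
#'   by frame.
#' @return List: `t_statistic`, `p_value`, `mean_diff`, `zero_variance`,
#'   `n`.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(values_a, values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t_statistic = NA_real_, p_value = NA_real_,
                mean_diff = mean(d), zero_variance = TRUE, n = length(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d), zero_variance = FALSE, n = length(d))
}

#' Evaluate predicted masks against ground truth
#'
#' Computes the five pixel-level metrics per frame (within the ROI),
#' aggregates per-frame values by their mean over frames where the metric
#' is defined, and attaches seeded 95% percentile-bootstrap confidence
#' intervals. Undefined per-frame values (zero denominators, e.g. IoU on a
#' frame with empty ground truth and empty prediction) are excluded from
#' that metric's aggregation and counted.
#'
#' @param pred_masks,gt_masks Aligned nonempty lists of masks.
#' @param roi Optional `roi_mask`.
#' @param n_resamples Bootstrap resamples for the CIs (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A `metric_report`: list with `per_frame` (tibble), `summary`
#'   (tibble: metric, mean, ci_lo, ci_hi, n_defined, n_undefined),
#'   `n_frames`, and CI metadata.
#' @export
evaluate_masks <- function(pred_masks, gt_masks, roi = NULL,
                           n_resamples = 1000L, seed = 1L) {
  if (length(pred_masks) == 0L || length(pred_masks) != length(gt_masks)) {
    stop("pred_masks and gt_masks must be nonempty aligned lists", call. = FALSE)
  }
  rows <- lapply(seq_along(pred_masks), function(i) {
    cc <- confusion(pred_masks[[i]], gt_masks[[i]], roi)
    tibble::tibble(
      frame = i, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
      accuracy = accuracy(cc), sensitivity = sensitivity(cc),
      specificity = specificity(cc), iou = iou(cc), dsc = dsc(cc)
    )
  })
  per_frame <- dplyr::bind_rows(rows)
  metrics <- c("accuracy", "sensitivity", "specificity", "iou", "dsc")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  summary <- dplyr::bind_rows(lapply(metrics, function(m) {
    v <- per_frame[[m]]
    defined <- v[!is.na(v)]
    if (length(defined) == 0L) {
      return(tibble::tibble(metric = m, mean = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, n_defined = 0L,
                            n_undefined = sum(is.na(v))))
    }
    ci <- bootstrap_mean_ci(defined, n_resamples)
    tibble::tibble(metric = m, mean = ci$mean, ci_lo = ci$lo, ci_hi = ci$hi,
                   n_defined = length(defined), n_undefined = sum(is.na(v)))
  }))
  structure(list(per_frame = per_frame, summary = summary,
                 n_frames = length(pred_masks), n_resamples = n_resamples,
                 seed = seed, ci_method = "percentile bootstrap"),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d frames, 95%% CI by %s (%d resamples)\n",
              x$n_frames, x$ci_method, x$n_resamples))
  print(x$summary)
  invisible(x)
}
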