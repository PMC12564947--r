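#' Tidy a training result
#'
#' @param x A `train_result`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, train_loss, monitored_loss,
#'   learning_rate).
#' @export
tidy.train_result <- function(x, ...) x$history

#' @rdname tidy.train_result
#' @export
glance.train_result <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_loss = x$best_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    final_lr = x$history$learning_rate[nrow(x$history)],
    parameters = count_parameters(x$model)
  )
}

#' Tidy a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The per-metric summary tibble (mean with 95% bootstrap CI).
#' @export
tidy.metric_report <- function(x, ...) x$summary

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  tibble::as_tibble(c(wide, list(n_frames = x$n_frames)))
}

#' Plot training curves
#'
#' @param object A `train_result`.
#' @param ... Unused.
#' @return A ggplot of train and monitored loss per epoch.
#' @export
autoplot.train_result <- function(object, ...) {
  h <- object$history
  df <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, loss = h$train_loss, series = "train"),
    tibble::tibble(epoch = h$epoch, loss = h$monitored_loss, series = "monitored")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "hybrid reconstruction loss",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a metric report
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot of metric means with 95% CIs.
#' @export
autoplot.metric_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "metric (mean, 95% CI)") +
    ggplot2::theme_minimal()
}

#' Display an error map with optional mask overlays
#'
#' @param error_map `H x W` nonnegative matrix.
#' @param mask Optional binary matrix outlined in the plot (e.g. ground
#'   truth).
#' @param tau Optional threshold; pixels above it are outlined.
#' @return A ggplot raster of the error map.
#' @export
plot_error_map <- function(error_map, mask = NULL, tau = NULL) {
  H <- nrow(error_map); W <- ncol(error_map)
  df <- tibble::tibble(
    x = rep(seq_len(W), each = H), y = rep(rev(seq_len(H)), W),
    error = as.vector(error_map)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$error)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(tau)) {
    df$above <- as.vector(error_map > tau)
    p <- p + ggplot2::geom_point(
      data = df[df$above, ], ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, size = 0.1, colour = "red", alpha = 0.4)
  }
  if (!is.null(mask)) {
    dm <- df[as.vector(mask > 0), ]
    p <- p + ggplot2::geom_point(
      data = dm, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, size = 0.1, colour = "white", alpha = 0.3)
  }
  p
}
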