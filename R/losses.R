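#' Reconstruction losses
#'
#' The training objective is a hybrid of pixel-wise mean squared error and an
#' edge-aware term that compares image gradients (forward finite differences
#' along x and y), weighted by `lambda_edge`:
#' `L = L_mse + lambda * L_edge`. Both terms are normalized by their element
#' counts so the weighting stays comparable across image sizes.
#'
#' Inputs may be single frames `[H, W, C]` or batches `[H, W, N, C]`; the
#' first two dimensions are always spatial.
#'
#' @param target,reconstruction Numeric arrays of identical dimensions.
#' @param lambda_edge Nonnegative edge-term weight (default 0.05).
#' @param loss_config A [loss_config()].
#' @return A single nonnegative number.
#' @name losses
NULL

#' @rdname losses
#' @export
loss_config <- function(lambda_edge = 0.05) {
  stop_if_not_scalar_number(lambda_edge, "lambda_edge", 0)
  structure(list(lambda_edge = lambda_edge), class = "loss_config")
}

check_same_shape <- function(target, reconstruction) {
  if (!identical(dim(target), dim(reconstruction))) {
    stop("target and reconstruction must have identical dimensions", call. = FALSE)
  }
}

#' @rdname losses
#' @export
mse_loss <- function(target, reconstruction) {
  check_same_shape(target, reconstruction)
  mean((reconstruction - target)^2)
}

# forward difference along spatial dimension 1 (rows, y) or 2 (columns, x)
fdiff <- function(x, dim) {
  d <- dim(x)
  idx_hi <- lapply(seq_along(d), function(i) seq_len(d[i]))
  idx_lo <- idx_hi
  idx_hi[[dim]] <- 2:d[dim]
  idx_lo[[dim]] <- 1:(d[dim] - 1L)
  do.call(`[`, c(list(x), idx_hi, drop = FALSE)) -
    do.call(`[`, c(list(x), idx_lo, drop = FALSE))
}

#' @rdname losses
#' @export
edge_loss <- function(target, reconstruction) {
  check_same_shape(target, reconstruction)
  dy_t <- fdiff(target, 1L); dy_r <- fdiff(reconstruction, 1L)
  dx_t <- fdiff(target, 2L); dx_r <- fdiff(reconstruction, 2L)
  n <- length(dy_t) + length(dx_t)
  (sum(abs(dy_r - dy_t)) + sum(abs(dx_r - dx_t))) / n
}

#' @rdname losses
#' @export
total_loss <- function(target, reconstruction, loss_config = NULL) {
  if (is.null(loss_config)) loss_config <- boluseg::loss_config()
  mse_loss(target, reconstruction) +
    loss_config$lambda_edge * edge_loss(target, reconstruction)
}

# Gradient of total_loss with respect to the reconstruction; same dims.
loss_gradient <- function(target, reconstruction, lambda_edge = 0.05) {
  check_same_shape(target, reconstruction)
  d <- dim(reconstruction)
  g <- 2 * (reconstruction - target) / length(reconstruction)
  if (lambda_edge > 0) {
    n_d <- length(reconstruction) / d[1] * (d[1] - 1L) +
      length(reconstruction) / d[2] * (d[2] - 1L)
    add_dir <- function(g, dim) {
      s <- sign(fdiff(reconstruction, dim) - fdiff(target, dim)) *
        (lambda_edge / n_d)
      hi <- lapply(seq_along(d), function(i) seq_len(d[i]))
      lo <- hi
      hi[[dim]] <- 2:d[dim]
      lo[[dim]] <- 1:(d[dim] - 1L)
      g <- do.call(`[<-`, c(list(g), hi, list(
        do.call(`[`, c(list(g), hi, drop = FALSE)) + s)))
      do.call(`[<-`, c(list(g), lo, list(
        do.call(`[`, c(list(g), lo, drop = FALSE)) - s)))
    }
    g <- add_dir(g, 1L)
    g <- add_dir(g, 2L)
  }
  g
}
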