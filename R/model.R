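#' Autoencoder configuration
#'
#' Describes the convolutional autoencoder used for reconstruction-based
#' anomaly segmentation: a three-block encoder (3x3 convolutions with batch
#' normalization and ReLU, dropout in the first block, 2x2 max-pooling), a
#' mirrored decoder with 2x2 stride-2 transpose-convolution upsampling and
#' skip connections concatenated at matching resolutions, and a 3x3 sigmoid
#' head producing a 3-channel reconstruction in (0, 1).
#'
#' @param in_channels Number of input channels: 5 for image + positional
#'   encoding, 3 for the image-only ablation variant.
#' @param encoder_widths Integer vector of three filter counts for the
#'   encoder blocks. The decoder mirrors them.
#' @param dropout_rate Dropout rate applied after the first encoder block.
#' @param out_channels Number of reconstruction channels (always 3).
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 5L, encoder_widths = c(64L, 128L, 256L),
                         dropout_rate = 0.1, out_channels = 3L) {
  if (!in_channels %in% c(3L, 5L)) stop("in_channels must be 3 or 5", call. = FALSE)
  if (length(encoder_widths) != 3L || any(encoder_widths < 1)) {
    stop("encoder_widths must be three positive integers", call. = FALSE)
  }
  stop_if_not_scalar_number(dropout_rate, "dropout_rate", 0, 1)
  structure(list(
    in_channels = as.integer(in_channels),
    encoder_widths = as.integer(encoder_widths),
    dropout_rate = dropout_rate,
    out_channels = as.integer(out_channels)
  ), class = "model_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build the convolutional autoencoder
#'
#' Initializes all weights (He-normal, drawn from the session RNG so that
#' `set.seed()` gives reproducible models) and the batch-normalization
#' running statistics.
#'
#' @param config A [model_config()].
#' @return An object of class `autoencoder` holding the configuration, the
#'   trainable parameters, and the batch-norm running statistics.
#' @export
build_autoencoder <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  w <- config$encoder_widths
  cin <- config$in_channels
  conv_par <- function(ci, co) {
    list(w = he_init(c(3L, 3L, ci, co), 9 * ci), b = numeric(co))
  }
  tconv_par <- function(ci, co) {
    list(w = he_init(c(2L, 2L, ci, co), 4 * ci), b = numeric(co))
  }
  bn_par <- function(co) list(gamma = rep(1, co), beta = numeric(co))
  bn_state <- function(co) list(rm = numeric(co), rv = rep(1, co))

  params <- list(
    enc1 = c(conv_par(cin, w[1]), bn_par(w[1])),
    enc2 = c(conv_par(w[1], w[2]), bn_par(w[2])),
    enc3 = c(conv_par(w[2], w[3]), bn_par(w[3])),
    dec1 = c(list(tw = tconv_par(w[3], w[2])$w, tb = numeric(w[2]),
                  mw = conv_par(w[2] + w[3], w[2])$w, mb = numeric(w[2])),
             bn_par(w[2])),
    dec2 = c(list(tw = tconv_par(w[2], w[1])$w, tb = numeric(w[1]),
                  mw = conv_par(w[1] + w[2], w[1])$w, mb = numeric(w[1])),
             bn_par(w[1])),
    dec3 = c(list(tw = tconv_par(w[1], w[1])$w, tb = numeric(w[1]),
                  mw = conv_par(w[1] + w[1], w[1])$w, mb = numeric(w[1])),
             bn_par(w[1])),
    head = conv_par(w[1], config$out_channels)
  )
  state <- list(
    enc1 = bn_state(w[1]), enc2 = bn_state(w[2]), enc3 = bn_state(w[3]),
    dec1 = bn_state(w[2]), dec2 = bn_state(w[1]), dec3 = bn_state(w[1])
  )
  structure(list(config = config, params = params, state = state),
            class = "autoencoder")
}

#' Count trainable parameters
#'
#' Sums the element counts of all trainable tensors (convolution and
#' transpose-convolution weights and biases, batch-norm scale and shift).
#' Batch-norm running statistics are not trainable and are excluded.
#'
#' @param model An `autoencoder`.
#' @return Integer count of trainable parameters.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "autoencoder"))
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

#' @export
print.autoencoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<autoencoder> in_channels=%d widths=(%s) params=%s\n",
    cfg$in_channels, paste(cfg$encoder_widths, collapse = ","),
    format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

check_input_dims <- function(model, x) {
  d <- dim(x)
  if (length(d) != 4L) stop("input must be an [H, W, N, C] array", call. = FALSE)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
    stop(sprintf(
      "input spatial size %dx%d is not divisible by 8; the three 2x2 pooling stages require it",
      d[1], d[2]), call. = FALSE)
  }
  if (d[4] != model$config$in_channels) {
    stop(sprintf("input has %d channels but the model expects %d",
                 d[4], model$config$in_channels), call. = FALSE)
  }
  invisible(TRUE)
}

# Full forward pass. training=TRUE uses batch statistics, applies dropout
# (mask drawn from the session RNG), updates running statistics, and keeps
# the caches needed for ae_backward(); training=FALSE is deterministic and
# uses running statistics.
ae_forward <- function(model, x, training = FALSE) {
  check_input_dims(model, x)
  p <- model$params
  st <- model$state
  rate <- model$config$dropout_rate
  cache <- list()

  enc_block <- function(name, xin) {
    pp <- p[[name]]
    z <- conv3_forward(xin, pp$w, pp$b)
    if (training) {
      bn <- bn_forward_train(z, pp$gamma, pp$beta, st[[name]]$rm, st[[name]]$rv)
      st[[name]]$rm <<- bn$running_mean
      st[[name]]$rv <<- bn$running_var
      cache[[name]] <<- list(xin = xin, bnc = bn$cache, pre = bn$y)
      relu_forward(bn$y)
    } else {
      pre <- bn_forward_eval(z, pp$gamma, pp$beta, st[[name]]$rm, st[[name]]$rv)
      relu_forward(pre)
    }
  }

  a1 <- enc_block("enc1", x)
  if (training && rate > 0) {
    dm <- dropout_mask(dim(a1), rate)
    a1 <- a1 * dm
    cache$enc1$mask <- dm
  }
  p1 <- maxpool2_forward(a1)
  a2 <- enc_block("enc2", p1$y)
  p2 <- maxpool2_forward(a2)
  a3 <- enc_block("enc3", p2$y)
  p3 <- maxpool2_forward(a3)

  dec_block <- function(name, xin, skip) {
    pp <- p[[name]]
    u <- tconv2_forward(xin, pp$tw, pp$tb)
    cc <- concat_channels(u, skip)
    z <- conv3_forward(cc, pp$mw, pp$mb)
    if (training) {
      bn <- bn_forward_train(z, pp$gamma, pp$beta, st[[name]]$rm, st[[name]]$rv)
      st[[name]]$rm <<- bn$running_mean
      st[[name]]$rv <<- bn$running_var
      cache[[name]] <<- list(xin = xin, cc = cc, n_up = dim(u)[4],
                             bnc = bn$cache, pre = bn$y)
      relu_forward(bn$y)
    } else {
      pre <- bn_forward_eval(z, pp$gamma, pp$beta, st[[name]]$rm, st[[name]]$rv)
      relu_forward(pre)
    }
  }

  m1 <- dec_block("dec1", p3$y, a3)
  m2 <- dec_block("dec2", m1, a2)
  m3 <- dec_block("dec3", m2, a1)

  zh <- conv3_forward(m3, p$head$w, p$head$b)
  y <- sigmoid_forward(zh)

  if (training) {
    cache$pools <- list(p1 = p1$cache, p2 = p2$cache, p3 = p3$cache)
    cache$m <- list(m1 = m1, m2 = m2, m3 = m3)
    cache$y <- y
    model$state <- st
    list(y = y, cache = cache, model = model)
  } else {
    list(y = y)
  }
}

# Backward pass: dY is the gradient of the loss w.r.t. the reconstruction.
# Returns gradients with the same nesting as model$params.
ae_backward <- function(model, cache, dY) {
  p <- model$params
  g <- list()

  dzh <- sigmoid_backward(cache$y, dY)
  bw <- conv3_backward(cache$m$m3, p$head$w, dzh)
  g$head <- list(w = bw$dw, b = bw$db)
  dm3 <- bw$dx

  dec_back <- function(name, dout) {
    pp <- p[[name]]
    cc <- cache[[name]]
    dpre <- relu_backward(cc$pre, dout)
    bnb <- bn_backward(cc$bnc, pp$gamma, dpre)
    cb <- conv3_backward(cc$cc, pp$mw, bnb$dx)
    n_up <- cc$n_up
    du <- cb$dx[, , , seq_len(n_up), drop = FALSE]
    dskip <- cb$dx[, , , -seq_len(n_up), drop = FALSE]
    tb <- tconv2_backward(cc$xin, pp$tw, du)
    g[[name]] <<- list(tw = tb$dw, tb = tb$db, mw = cb$dw, mb = cb$db,
                       gamma = bnb$dgamma, beta = bnb$dbeta)
    list(dxin = tb$dx, dskip = dskip)
  }

  d3 <- dec_back("dec3", dm3)
  d2 <- dec_back("dec2", d3$dxin)
  d1 <- dec_back("dec1", d2$dxin)

  # encoder gradients; skip-connection gradients join the pooled paths
  da3 <- maxpool2_backward(cache$pools$p3, d1$dxin) + d1$dskip
  enc_back <- function(name, dact) {
    pp <- p[[name]]
    cc <- cache[[name]]
    dpre <- relu_backward(cc$pre, dact)
    bnb <- bn_backward(cc$bnc, pp$gamma, dpre)
    cb <- conv3_backward(cc$xin, pp$w, bnb$dx)
    g[[name]] <<- list(w = cb$dw, b = cb$db, gamma = bnb$dgamma, beta = bnb$dbeta)
    cb$dx
  }
  dp2 <- enc_back("enc3", da3)
  da2 <- maxpool2_backward(cache$pools$p2, dp2) + d2$dskip
  dp1 <- enc_back("enc2", da2)
  da1 <- maxpool2_backward(cache$pools$p1, dp1) + d3$dskip
  if (!is.null(cache$enc1$mask)) da1 <- da1 * cache$enc1$mask
  enc_back("enc1", da1)

  g[names(p)]
}

#' Reconstruct frames with a trained autoencoder
#'
#' Runs the model in inference mode (batch-norm running statistics, no
#' dropout) on a single encoded input or a batch.
#'
#' @param model A trained `autoencoder`.
#' @param x Either an `[H, W, C]` array (single frame) or an `[H, W, N, C]`
#'   batch with `C` matching the model's input channels.
#' @param batch_size Frames reconstructed per forward pass.
#' @return Reconstruction array of the same spatial size with 3 channels
#'   (`[H, W, 3]` for a single frame, `[H, W, N, 3]` for a batch).
#' @export
reconstruct <- function(model, x, batch_size = 8L) {
  single <- length(dim(x)) == 3L
  if (single) {
    d <- dim(x)
    x <- array(x, c(d[1], d[2], 1L, d[3]))  # inserting a singleton batch dim keeps element order
  }
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3], model$config$out_channels))
  idx <- seq_len(d[3])
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    out[, , chunk, ] <- ae_forward(model, x[, , chunk, , drop = FALSE])$y
  }
  if (single) array(out[, , 1L, ], dim = c(d[1], d[2], model$config$out_channels)) else out
}
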