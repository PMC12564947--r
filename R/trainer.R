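#' Training configuration
#'
#' Defaults follow the training protocol of the method: Adam with initial
#' learning rate 0.01 and moments (0.9, 0.999), no weight decay, batch size
#' 16, 100 epochs, reduce-on-plateau scheduling (factor 0.5 after 10 epochs
#' without improvement of the monitored loss), light Gaussian noise
#' augmentation on the image channels, and no early stopping — the returned
#' model is the one with the lowest monitored loss observed during training.
#'
#' @param learning_rate Initial Adam learning rate (> 0).
#' @param batch_size Frames per gradient step.
#' @param epochs Number of passes over the training frames (>= 1).
#' @param scheduler_factor Multiplicative learning-rate decay on plateau.
#' @param scheduler_patience Epochs without improvement before decaying.
#' @param noise_aug_sigma Std of the Gaussian noise added to the image
#'   channels of each training input (the clean frame stays the target);
#'   in \[0, 1).
#' @param validation_fraction Fraction of the *training* frames held out to
#'   monitor the plateau scheduler (test data are never used).
#' @param seed Integer seed making the whole run reproducible.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 16L, epochs = 100L,
                         scheduler_factor = 0.5, scheduler_patience = 10L,
                         noise_aug_sigma = 0.02, validation_fraction = 0.1,
                         seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(epochs, "epochs", 1)
  if (noise_aug_sigma < 0 || noise_aug_sigma >= 1) {
    stop("noise_aug_sigma must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), scheduler_factor = scheduler_factor,
    scheduler_patience = as.integer(scheduler_patience),
    noise_aug_sigma = noise_aug_sigma,
    validation_fraction = validation_fraction, seed = as.integer(seed)
  ), class = "train_config")
}

#' Gaussian noise augmentation
#'
#' Adds i.i.d. `N(0, sigma^2)` noise per element and clips to \[0, 1\].
#' `sigma = 0` is the identity. Draws come from the session RNG.
#'
#' @param x Numeric array of image channels in \[0, 1\].
#' @param sigma Noise standard deviation (>= 0).
#' @return Array of the same shape, values in \[0, 1\].
#' @export
add_gaussian_noise <- function(x, sigma) {
  stop_if_not_scalar_number(sigma, "sigma", 0)
  if (sigma == 0) return(x)
  clip01(x + array(stats::rnorm(length(x), 0, sigma), dim(x)))
}

#' Augmentations used during training
#'
#' The training loop applies Gaussian noise only. Geometric augmentations
#' (flips, rotations) are deliberately absent: they would break the fixed
#' relationship between image content and the positional-encoding channels.
#'
#' @return Character vector naming the augmentations the trainer applies.
#' @export
augmentation_registry <- function() c("gaussian_noise")

# Reduce-on-plateau scheduler state machine. The learning rate is halved
# (by `factor`) once the monitored loss has failed to improve for `patience`
# consecutive epochs; the wait counter then resets.
plateau_init <- function(lr, factor = 0.5, patience = 10L) {
  list(lr = lr, factor = factor, patience = patience,
       best = Inf, wait = 0L, improved = FALSE)
}

plateau_step <- function(st, monitored) {
  if (monitored < st$best) {
    st$best <- monitored
    st$wait <- 0L
    st$improved <- TRUE
  } else {
    st$improved <- FALSE
    st$wait <- st$wait + 1L
    if (st$wait >= st$patience) {
      st$lr <- st$lr * st$factor
      st$wait <- 0L
    }
  }
  st
}

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

# one Adam step over the nested parameter/gradient lists
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (blk in names(grads)) {
    for (pn in names(grads[[blk]])) {
      g <- grads[[blk]][[pn]]
      st <- state[[blk]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[blk]][[pn]] <- params[[blk]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
      state[[blk]][[pn]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train the autoencoder on anomaly-free frames
#'
#' Runs the denoising training loop: each step adds Gaussian noise to the
#' image channels of the input (positional-encoding channels are never
#' perturbed — they encode coordinates, not appearance), the target is the
#' clean image, and the hybrid MSE + edge loss is minimized with Adam. A
#' held-out fraction of the training frames is monitored for the plateau
#' scheduler and for lowest-loss model selection. Fully reproducible given
#' `config$seed`.
#'
#' @param model An `autoencoder` from [build_autoencoder()] (its current
#'   weights are the starting point).
#' @param x Training inputs: an `[H, W, N, C]` array or a list of
#'   `encoded_input` objects, all anomaly-free.
#' @param config A [train_config()].
#' @param loss A [loss_config()].
#' @param masks Optional `[H, W, N]` array (or list of matrices) of
#'   ground-truth masks; training aborts if any is nonzero, enforcing the
#'   anomaly-free contract for phantom data.
#' @param verbose Print per-epoch losses.
#' @return A `train_result`: list with `model` (lowest monitored loss),
#'   `final_model`, `history` (tibble: epoch, train_loss, monitored_loss,
#'   learning_rate), `best_epoch`, and `config`.
#' @export
train_autoencoder <- function(model, x, config = train_config(),
                              loss = loss_config(), masks = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(model, "autoencoder"), inherits(config, "train_config"))
  x <- stack_inputs(x)
  if (!is.null(masks)) {
    mk <- if (is.list(masks)) masks else {
      lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
    }
    if (any(vapply(mk, function(m) any(m > 0), logical(1)))) {
      stop("training frames must be anomaly-free: a nonzero mask was supplied",
           call. = FALSE)
    }
  }
  check_input_dims(model, x)
  N <- dim(x)[3]
  if (N == 0L) stop("empty training set", call. = FALSE)
  set.seed(config$seed)

  n_val <- if (config$validation_fraction > 0 && N >= 2L) {
    max(1L, round(config$validation_fraction * N))
  } else 0L
  val_idx <- if (n_val > 0L) sort(sample.int(N, n_val)) else integer(0)
  tr_idx <- setdiff(seq_len(N), val_idx)
  x_val <- if (n_val > 0L) x[, , val_idx, , drop = FALSE] else NULL

  sched <- plateau_init(config$learning_rate, config$scheduler_factor,
                        config$scheduler_patience)
  opt <- adam_init(model$params)
  t_step <- 0L
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batch_losses <- c(); batch_sizes <- c()
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xb <- x[, , idx, , drop = FALSE]
      target <- xb[, , , 1:3, drop = FALSE]
      if (config$noise_aug_sigma > 0) {
        xb[, , , 1:3] <- add_gaussian_noise(target, config$noise_aug_sigma)
      }
      fw <- ae_forward(model, xb, training = TRUE)
      model <- fw$model
      l <- total_loss(target, fw$y, loss)
      batch_losses <- c(batch_losses, l)
      batch_sizes <- c(batch_sizes, length(idx))
      if (sched$lr > 0) {
        dY <- loss_gradient(target, fw$y, loss$lambda_edge)
        grads <- ae_backward(model, fw$cache, dY)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, opt, sched$lr, t_step)
        model$params <- upd$params
        opt <- upd$state
      }
    }
    train_loss <- sum(batch_losses * batch_sizes) / sum(batch_sizes)
    monitored <- if (n_val > 0L) {
      yv <- ae_forward(model, x_val)$y
      total_loss(x_val[, , , 1:3, drop = FALSE], yv, loss)
    } else train_loss

    sched <- plateau_step(sched, monitored)
    if (sched$improved) {
      best <- list(loss = monitored, params = model$params,
                   state = model$state, epoch = epoch)
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                    monitored_loss = monitored,
                                    learning_rate = sched$lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  monitored %.5f  lr %.5f",
                      epoch, train_loss, monitored, sched$lr))
    }
  }

  best_model <- model
  best_model$params <- best$params
  best_model$state <- best$state
  structure(list(model = best_model, final_model = model,
                 history = dplyr::bind_rows(hist), best_epoch = best$epoch,
                 best_loss = best$loss, config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs, best epoch %d (monitored loss %.5g)\n",
              nrow(x$history), x$best_epoch, x$best_loss))
  invisible(x)
}

#' Stack encoded inputs into a batch array
#'
#' Combines a list of `encoded_input` objects (or `H x W x C` arrays) of
#' identical shape into the `[H, W, N, C]` batch layout used by the model
#' and trainer; a 4-D array passes through unchanged.
#'
#' @param x List of `encoded_input`s / arrays, or an `[H, W, N, C]` array.
#' @return An `[H, W, N, C]` numeric array.
#' @export
stack_inputs <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  if (inherits(x, "encoded_input")) x <- list(x)
  stopifnot(is.list(x), length(x) > 0L)
  chans <- lapply(x, function(e) {
    if (inherits(e, "encoded_input")) e$channels else e
  })
  d <- dim(chans[[1]])
  out <- array(0, c(d[1], d[2], length(chans), d[3]))
  for (i in seq_along(chans)) {
    stopifnot(identical(dim(chans[[i]]), d))
    out[, , i, ] <- chans[[i]]
  }
  out
}
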