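# Low-level neural-network layers.
#
# All layers operate on batch arrays laid out [H, W, N, C] (rows, columns,
# batch, channels) so that channel-wise reductions map onto colMeans/colSums
# of an (H*W*N) x C matrix and convolutions map onto a single BLAS matrix
# product via im2col (in compiled code for the 3x3 case). Only the configurations the autoencoder uses are
# implemented: 3x3 convolutions with stride 1 / pad 1, 2x2 stride-2
# transpose convolutions, and 2x2 stride-2 max-pooling.

# ---- 3x3 convolution (stride 1, zero padding 1) ----
# The im2col unfold/fold-back and the BLAS products live in src/conv3.cpp;
# column order (kh, kw, c) of the patch matrix matches
# dim(w) <- c(9*Cin, Cout) for w [3,3,Cin,Cout].

conv3_forward <- function(x, w, b) {
  .conv3_forward_cpp(x, w, as.numeric(b))
}

conv3_backward <- function(x, w, dy) {
  .conv3_backward_cpp(x, w, dy)
}

# ---- 2x2 stride-2 transpose convolution (exact upsampling, no overlap) ----

tconv2_forward <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; cin <- d[4]
  cout <- dim(w)[4]
  wm <- aperm(w, c(3L, 1L, 2L, 4L)); dim(wm) <- c(cin, 4L * cout)
  xm <- x; dim(xm) <- c(H * W * N, cin)
  Y <- xm %*% wm
  dim(Y) <- c(H, W, N, 2L, 2L, cout)
  y <- array(0, c(2L * H, 2L * W, N, cout))
  for (a in 1:2) {
    for (bb in 1:2) {
      y[seq(a, 2L * H, 2L), seq(bb, 2L * W, 2L), , ] <- Y[, , , a, bb, ]
    }
  }
  y + rep(b, each = 4L * H * W * N)
}

tconv2_backward <- function(x, w, dy) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; cin <- d[4]
  cout <- dim(w)[4]
  wm <- aperm(w, c(3L, 1L, 2L, 4L)); dim(wm) <- c(cin, 4L * cout)
  dY <- array(0, c(H, W, N, 2L, 2L, cout))
  for (a in 1:2) {
    for (bb in 1:2) {
      dY[, , , a, bb, ] <- dy[seq(a, 2L * H, 2L), seq(bb, 2L * W, 2L), , ]
    }
  }
  dim(dY) <- c(H * W * N, 4L * cout)
  xm <- x; dim(xm) <- c(H * W * N, cin)
  dw <- crossprod(xm, dY)
  dim(dw) <- c(cin, 2L, 2L, cout)
  dw <- aperm(dw, c(2L, 3L, 1L, 4L))
  dym <- dy; dim(dym) <- c(4L * H * W * N, cout)
  db <- colSums(dym)
  dx <- dY %*% t(wm)
  dim(dx) <- c(H, W, N, cin)
  list(dx = dx, dw = dw, db = db)
}

# ---- 2x2 stride-2 max pooling ----

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  a11 <- x[seq(1L, H, 2L), seq(1L, W, 2L), , , drop = FALSE]
  a21 <- x[seq(2L, H, 2L), seq(1L, W, 2L), , , drop = FALSE]
  a12 <- x[seq(1L, H, 2L), seq(2L, W, 2L), , , drop = FALSE]
  a22 <- x[seq(2L, H, 2L), seq(2L, W, 2L), , , drop = FALSE]
  y <- pmax(a11, a21, a12, a22)
  list(y = y, cache = list(a11 = a11, a21 = a21, a12 = a12, a22 = a22, y = y))
}

# Gradient is routed to the (first, in a fixed scan order) element attaining
# the pool maximum, so ties are broken deterministically.
maxpool2_backward <- function(cache, dy) {
  y <- cache$y
  t1 <- cache$a11 == y
  r <- !t1
  t2 <- r & (cache$a21 == y); r <- r & !t2
  t3 <- r & (cache$a12 == y); r <- r & !t3
  t4 <- r & (cache$a22 == y)
  d <- dim(y); H2 <- 2L * d[1]; W2 <- 2L * d[2]
  dx <- array(0, c(H2, W2, d[3], d[4]))
  dx[seq(1L, H2, 2L), seq(1L, W2, 2L), , ] <- dy * t1
  dx[seq(2L, H2, 2L), seq(1L, W2, 2L), , ] <- dy * t2
  dx[seq(1L, H2, 2L), seq(2L, W2, 2L), , ] <- dy * t3
  dx[seq(2L, H2, 2L), seq(2L, W2, 2L), , ] <- dy * t4
  dx
}

# ---- batch normalization (per channel) ----

bn_forward_train <- function(x, gamma, beta, running_mean, running_var,
                             momentum = 0.1, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2] * d[3]; C <- d[4]
  fw <- .bn_fw_train_cpp(x, as.numeric(gamma), as.numeric(beta), n, C, eps)
  y <- fw$y; dim(y) <- d
  unbias <- if (n > 1L) n / (n - 1) else 1
  list(
    y = y,
    running_mean = (1 - momentum) * running_mean + momentum * fw$mu,
    running_var = (1 - momentum) * running_var + momentum * fw$var * unbias,
    cache = list(xhat = fw$xhat, inv = fw$inv, n = n, C = C, dims = d)
  )
}

bn_forward_eval <- function(x, gamma, beta, running_mean, running_var, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2] * d[3]; C <- d[4]
  y <- .bn_fw_eval_cpp(x, as.numeric(running_mean),
                       as.numeric(gamma / sqrt(running_var + eps)),
                       as.numeric(beta), n, C)
  dim(y) <- d
  y
}

bn_backward <- function(cache, gamma, dy) {
  bw <- .bn_bw_cpp(dy, cache$xhat, as.numeric(gamma), cache$inv,
                   cache$n, cache$C)
  dx <- bw$dx
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = bw$dgamma, dbeta = bw$dbeta)
}

# ---- activations & dropout ----

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(x, dy) dy * (x > 0)

sigmoid_forward <- function(x) 1 / (1 + exp(-x))
sigmoid_backward <- function(y, dy) dy * y * (1 - y)

# Inverted dropout; mask drawn from the session RNG so training is
# reproducible under set.seed().
dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  m <- array((stats::runif(prod(dims)) >= rate) / (1 - rate), dims)
  m
}
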