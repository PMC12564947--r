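# Independent brute-force oracles used to check the implementation.

# per-pixel confusion counts by explicit enumeration
oracle_confusion <- function(pred, gt, roi = NULL) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (!is.null(roi) && roi[i, j] == 0) next
      p <- pred[i, j] > 0; g <- gt[i, j] > 0
      if (p && g) tp <- tp + 1L
      else if (p && !g) fp <- fp + 1L
      else if (!p && g) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# mean squared error by explicit elementwise summation
oracle_mse <- function(target, recon) {
  s <- 0
  for (i in seq_along(target)) s <- s + (recon[i] - target[i])^2
  s / length(target)
}

# edge loss by explicit forward finite differences
oracle_edge <- function(target, recon) {
  d <- dim(target)
  H <- d[1]; W <- d[2]
  planes <- prod(d[-(1:2)])
  tt <- array(target, c(H, W, planes))
  rr <- array(recon, c(H, W, planes))
  s <- 0; n <- 0
  for (p in seq_len(planes)) {
    for (i in seq_len(H - 1)) for (j in seq_len(W)) {
      s <- s + abs((rr[i + 1, j, p] - rr[i, j, p]) - (tt[i + 1, j, p] - tt[i, j, p]))
      n <- n + 1
    }
    for (i in seq_len(H)) for (j in seq_len(W - 1)) {
      s <- s + abs((rr[i, j + 1, p] - rr[i, j, p]) - (tt[i, j + 1, p] - tt[i, j, p]))
      n <- n + 1
    }
  }
  s / n
}

# 8-connectivity component labelling by breadth-first search
oracle_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (si in seq_len(H)) for (sj in seq_len(W)) {
    if (mask[si, sj] > 0 && lab[si, sj] == 0L) {
      cur <- cur + 1L
      queue <- list(c(si, sj))
      lab[si, sj] <- cur
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- q[1] + di; jj <- q[2] + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
              mask[ii, jj] > 0 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue <- c(queue, list(c(ii, jj)))
          }
        }
      }
    }
  }
  lab
}

random_mask <- function(H, W, p = 0.3) matrix(stats::runif(H * W) < p, H, W) * 1
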