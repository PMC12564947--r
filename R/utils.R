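# Internal helpers shared across modules.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @noRd
stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Replicate a single-channel H x W matrix (or pass through an H x W x 3 array)
# to the canonical H x W x 3 layout.
as_rgb_array <- function(image) {
  if (is.matrix(image)) {
    array(image, dim = c(dim(image), 3L))
  } else if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] == 1L) {
      array(image[, , 1L], dim = c(dim(image)[1:2], 3L))
    } else if (dim(image)[3] == 3L) {
      image
    } else {
      stop("image must have 1 or 3 channels", call. = FALSE)
    }
  } else {
    stop("image must be an H x W matrix or H x W x C array", call. = FALSE)
  }
}

# 8-connectivity connected-component labelling of a binary matrix.
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask > 0)
  labels <- matrix(0L, H, W)
  if (length(fg) == 0L) return(labels)
  idx <- matrix(0L, H, W)
  idx[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  edges <- integer(0)
  # neighbour offsets covering the 8-neighbourhood without double counting:
  # right, down, down-right, up-right
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    if (!any(ok)) next
    nb <- idx[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    if (!any(has)) next
    edges <- c(edges, rbind(idx[cbind(rows[ok], cols[ok])][has], nb[has]))
  }
  if (length(edges) == 0L) {
    labels[fg] <- seq_along(fg)
    return(labels)
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}
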