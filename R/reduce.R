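#' Leaky rectified linear unit
#'
#' The network nonlinearity: `f(x) = x` for `x > 0` and `f(x) = alpha * x`
#' otherwise, applied elementwise.
#'
#' @param x numeric vector, matrix or array.
#' @param alpha negative slope, default 0.01.
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  ifelse(x > 0, x, alpha * x)
}

# derivative mask, same shape as x (x = pre-activation)
.leaky_relu_grad <- function(x, alpha = 0.01) ifelse(x > 0, 1, alpha)

#' Commutative Max/Sum/Avg reduction
#'
#' Reduces an unordered collection of equal-length vectors to the
#' concatenation of their elementwise maximum, sum and average; the
#' order-invariant aggregation used both inside convolution filters and for
#' molecule-level pooling. An empty collection reduces to all zeros (so the
#' output width stays fixed), in which case `width` must be given.
#'
#' @param x numeric matrix (one vector per row) or list of equal-length
#'   numeric vectors.
#' @param width vector length, required only when `x` is empty.
#' @return numeric vector of length `3 * width`.
#' @export
commutative_reduce <- function(x, width = NULL) {
  if (is.list(x)) {
    if (length(x) && length(unique(lengths(x))) != 1L)
      stop("all vectors must have equal length")
    x <- do.call(rbind, x)
  }
  if (is.null(x) || nrow(x) == 0L) {
    if (is.null(width)) stop("width required to reduce an empty collection")
    return(numeric(3L * width))
  }
  x <- as.matrix(x)
  c(apply(x, 2L, max), colSums(x), colMeans(x))
}

# Segmented Max/Sum/Avg over the rows of M, grouped by integer segment ids.
# Returns max/sum/avg matrices (nseg x d; empty segments all-zero), the row
# index that achieved each max (NA for empty segments) for gradient routing,
# and per-segment counts. Max is accumulated slot-by-slot (at most
# max(count) passes of vectorized pmax), which keeps the training loop free
# of per-atom R loops.
segment_reduce <- function(M, seg, nseg) {
  d <- ncol(M)
  cnt <- tabulate(seg, nseg)
  S <- matrix(0, nseg, d)
  if (nrow(M)) {
    rs <- rowsum(M, seg)
    S[as.integer(rownames(rs)), ] <- rs
  }
  MX <- matrix(0, nseg, d)
  AMX <- matrix(NA_integer_, nseg, d)
  if (nrow(M)) {
    ord <- order(seg)
    slot <- integer(length(seg))
    slot[ord] <- sequence(cnt[cnt > 0L])
    for (s in seq_len(max(slot))) {
      rows <- which(slot == s)
      segs <- seg[rows]
      sub <- M[rows, , drop = FALSE]
      if (s == 1L) {
        MX[segs, ] <- sub
        AMX[segs, ] <- matrix(rows, length(rows), d)
      } else {
        cur <- MX[segs, , drop = FALSE]
        am <- AMX[segs, , drop = FALSE]
        upd <- sub > cur
        cur[upd] <- sub[upd]
        am[upd] <- matrix(rows, length(rows), d)[upd]
        MX[segs, ] <- cur
        AMX[segs, ] <- am
      }
    }
  }
  A <- S / pmax(cnt, 1L)
  list(max = MX, sum = S, avg = A, argmax = AMX, count = cnt)
}

# Gradient of segment_reduce: given upstream gradients for the concatenated
# [max | sum | avg] block (nseg x 3d), returns the gradient on M (nrow x d).
segment_reduce_backward <- function(dR, red, seg, nrowM) {
  d <- ncol(dR) / 3L
  dMX <- dR[, seq_len(d), drop = FALSE]
  dS <- dR[, d + seq_len(d), drop = FALSE]
  dA <- dR[, 2L * d + seq_len(d), drop = FALSE]
  per_seg <- dS + dA / pmax(red$count, 1L)
  dM <- per_seg[seg, , drop = FALSE]
  if (is.null(dim(dM))) dM <- matrix(dM, nrow = length(seg))
  valid <- !is.na(red$argmax)
  if (any(valid)) {
    idx <- cbind(red$argmax[valid], col(red$argmax)[valid])
    dM[idx] <- dM[idx] + dMX[valid]
  }
  dM
}
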