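## Small internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## round() in R is round-half-even; cohort rules and grid arithmetic use
## conventional half-up rounding so results are stable across platforms.
round_half_up <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary_array <- function(x) {
  u <- unique(as.vector(x))
  all(u %in% c(0, 1))
}

## Split a (X,Y,Z,C,N) feature map into contiguous channel slices.
#' Split a feature map along the channel axis
#'
#' Partitions the channels of a 5-d feature map (dims X, Y, Z, C, N) into
#' contiguous slices of the given widths, in order. Concatenating the
#' result with [concat_channels()] reproduces the input exactly. This is
#' the channel split at the entry of every bottleneck-convolution block.
#'
#' @param x numeric array with 5 dims, channel axis fourth.
#' @param widths integer vector of slice widths; must sum to `dim(x)[4]`.
#' @return List of arrays, one per width.
#' @export
split_channels <- function(x, widths) {
  d <- dim(x)
  if (length(d) != 5L) stopf("split_channels: expected a 5-d array")
  if (sum(widths) != d[4])
    stopf("split_channels: widths sum to %d but input has %d channels",
          sum(widths), d[4])
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- x[, , , at + seq_len(widths[i]), , drop = FALSE]
    at <- at + widths[i]
  }
  out
}

#' Concatenate feature maps along the channel axis
#'
#' Inverse of [split_channels()]: stacks sub-feature maps back together in
#' order along the fourth (channel) dimension.
#'
#' @param parts list of 5-d arrays agreeing on all dims but the fourth.
#' @return A single 5-d array.
#' @export
concat_channels <- function(parts) {
  d1 <- dim(parts[[1L]])
  ctot <- sum(vapply(parts, function(p) dim(p)[4], integer(1)))
  out <- array(0, c(d1[1:3], ctot, d1[5]))
  at <- 0L
  for (p in parts) {
    cw <- dim(p)[4]
    out[, , , at + seq_len(cw), ] <- p
    at <- at + cw
  }
  out
}

## Shift a 3D array by integer offsets, zero-filling exposed faces.
shift3d <- function(x, shift) {
  d <- dim(x)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) {
      src[[a]] <- seq_len(d[a] - s)
      dst[[a]] <- src[[a]] + s
    } else {
      src[[a]] <- seq_len(d[a] + s) - s
      dst[[a]] <- seq_len(d[a] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

## Softmax over columns of a (K x N) matrix.
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}
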