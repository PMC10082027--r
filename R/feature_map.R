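#' Feature maps and channel-wise operations
#'
#' A feature map is an `H x W x C` numeric array of activations (or an
#' `H x W x C x N` batch).  These helpers implement the channel-wise
#' primitives of the shared-channel residual (SCR) block: splitting a map
#' into its two channel halves and exchanging halves between two layers.
#'
#' @name feature-maps
NULL

# channel axis for a 3-d map or 4-d batch
.channel_axis <- function(x) {
  nd <- length(dim(x))
  if (nd == 3L) 3L else if (nd == 4L) 3L else
    stop("expected an H x W x C (x N) array, got ", nd, " dimensions")
}

#' Validate a feature map array
#'
#' @param x numeric array `H x W x C` (or `H x W x C x N`).
#' @return `x`, invisibly, after checking dimensions and finiteness.
#' @export
feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("a feature map must be an H x W x C (x N) array")
  if (any(d < 1L)) stop("all feature-map dimensions must be >= 1")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

#' Split a feature map into its two channel halves
#'
#' Channels `1..C/2` form the first half and `C/2+1..C` the second, in
#' their original order; concatenating the two halves along the channel
#' axis reproduces the input exactly.
#'
#' @param x feature map with an even number of channels.
#' @return list with elements `first` and `second`.
#' @export
split_channels <- function(x) {
  d <- dim(x)
  ca <- .channel_axis(x)
  C <- d[ca]
  if (C %% 2L != 0L)
    stop("split_channels: channel count must be even, got ", C)
  h <- C %/% 2L
  if (length(d) == 3L) {
    list(first = x[, , seq_len(h), drop = FALSE],
         second = x[, , h + seq_len(h), drop = FALSE])
  } else {
    list(first = x[, , seq_len(h), , drop = FALSE],
         second = x[, , h + seq_len(h), , drop = FALSE])
  }
}

#' Concatenate two feature maps along the channel axis
#'
#' @param a,b feature maps with identical spatial (and batch) dimensions.
#' @return feature map with `C_a + C_b` channels.
#' @export
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || any(da[-3L] != db[-3L]))
    stop("concat_channels: incompatible shapes")
  if (length(da) == 3L) {
    out <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
    out[, , seq_len(da[3L])] <- a
    out[, , da[3L] + seq_len(db[3L])] <- b
  } else {
    out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
    out[, , seq_len(da[3L]), ] <- a
    out[, , da[3L] + seq_len(db[3L]), ] <- b
  }
  out
}

#' Share channel halves between two layers
#'
#' The cross-layer exchange at the heart of the SCR block.  With channel
#' halves written `x = [x1, x2]` and `y = [y1, y2]`, the two outputs are
#' `x_concat = [x1, y2]` and `y_concat = [y1, x2]`: the first half of each
#' layer is concatenated with the second half of the other.  The operation
#' is parameter-free, conserves the multiset of channel slices, and is an
#' involution (applying it twice restores both inputs).
#'
#' @param x,y feature maps of identical shape with an even channel count.
#' @return list with elements `x_concat` and `y_concat`.
#' @export
share_channels <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("share_channels: x and y must have identical shapes")
  sx <- split_channels(x)
  sy <- split_channels(y)
  list(x_concat = concat_channels(sx$first, sy$second),
       y_concat = concat_channels(sy$first, sx$second))
}
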