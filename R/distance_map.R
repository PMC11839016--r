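#' Relabel an instance mask to contiguous labels 1..N
#'
#' Positive labels are renumbered in order of first appearance of their
#' sorted values; background stays 0. Idempotent on already-canonical masks.
#'
#' @param mask Integer matrix, 0 = background, positive = instance id.
#' @return Integer matrix with labels exactly `{0, 1, ..., N}`.
#' @export
canonicalize_labels <- function(mask) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0)) stop("label mask must be non-negative")
  storage.mode(mask) <- "integer"
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) == 0L) return(mask)
  out <- mask
  out[mask > 0L] <- match(mask[mask > 0L], labs)
  out
}

#' Labels present in a canonical mask
#' @noRd
n_labels <- function(mask) {
  m <- max(mask)
  if (m < 1L) 0L else as.integer(m)
}

#' Encode an instance mask as a per-cell normalized distance map
#'
#' For each cell independently, computes the exact Euclidean distance from
#' every cell pixel to the nearest pixel not belonging to that cell —
#' background, other cells, and out-of-frame all count as non-cell — and
#' divides by the cell's maximum distance. The composited map is the
#' regression target: background is exactly 0, every cell peaks at exactly
#' 1 somewhere in its interior, and a cell pixel on the boundary has raw
#' distance 1 (standard distance-transform semantics), so the map's support
#' equals the mask's support.
#'
#' @param mask Canonical integer label mask (see [canonicalize_labels()]).
#' @return Numeric matrix in \[0, 1\], same shape as `mask`.
#' @export
encode_distance_map <- function(mask) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0)) stop("label mask must be non-negative")
  out <- matrix(0, nrow(mask), ncol(mask))
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0) return(out)
  h <- nrow(mask)
  w <- ncol(mask)
  for (k in labs) {
    idx <- which(mask == k, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    bh <- r1 - r0 + 1L
    bw <- c1 - c0 + 1L
    # one-pixel zero ring makes the frame border (and the bounding-box
    # boundary, which is non-cell by construction) act as boundary
    pad <- matrix(0, bh + 2L, bw + 2L)
    pad[2:(bh + 1L), 2:(bw + 1L)] <- (mask[r0:r1, c0:c1, drop = FALSE] == k)
    d <- EBImage::distmap(pad, metric = "euclidean")
    d <- d[2:(bh + 1L), 2:(bw + 1L), drop = FALSE]
    mx <- max(d)
    sel <- pad[2:(bh + 1L), 2:(bw + 1L), drop = FALSE] > 0
    sub <- out[r0:r1, c0:c1, drop = FALSE]
    sub[sel] <- d[sel] / mx
    out[r0:r1, c0:c1] <- sub
  }
  out
}
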