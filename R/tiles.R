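#' Sliding-window tile origins along one axis
#'
#' Origins advance by `patch - 2 * margin` from 0; the final origin is
#' clamped to `dim - patch` and duplicates are dropped, so the last tile
#' always ends exactly at the frame edge.
#' @noRd
tile_origins <- function(dim, patch, margin) {
  stride <- patch - 2L * margin
  last <- dim - patch
  os <- integer(0)
  k <- 0L
  repeat {
    o <- min(k * stride, last)
    os <- c(os, o)
    if (k * stride >= last) break
    k <- k + 1L
  }
  unique(os)
}

#' Per-axis ownership intervals for stitching
#'
#' Each tile owns its central region (patch minus `margin` on each side),
#' extended to the frame edge for the first and last tiles; where the
#' clamped final tile overlaps an earlier tile's claim, the earlier tile
#' wins and the final tile owns only the remainder. Returns 0-based
#' half-open intervals `[start, end)`.
#' @noRd
ownership_intervals <- function(origins, patch, margin, dim) {
  n <- length(origins)
  starts <- ends <- integer(n)
  prev_end <- 0L
  for (i in seq_len(n)) {
    low <- if (i == 1L) 0L else origins[i] + margin
    high <- if (i == n) dim else origins[i] + patch - margin
    starts[i] <- max(low, prev_end)
    ends[i] <- max(high, starts[i])
    prev_end <- ends[i]
  }
  list(start = starts, end = ends)
}

#' Reflection-pad a matrix to at least a target size
#'
#' Pads on the bottom/right by mirroring interior pixels (the edge row is
#' not duplicated), so frames smaller than one patch can be tiled without
#' introducing artificial hard edges.
#' @noRd
reflect_pad <- function(x, min_rows, min_cols) {
  refl_idx <- function(n, m) {
    idx <- seq_len(m)
    if (n == 1L) return(rep(1L, m))
    period <- 2L * (n - 1L)
    r <- (idx - 1L) %% period
    ifelse(r < n, r + 1L, period - r + 1L)
  }
  nr <- max(nrow(x), min_rows)
  nc <- max(ncol(x), min_cols)
  if (nr == nrow(x) && nc == ncol(x)) return(x)
  x[refl_idx(nrow(x), nr), refl_idx(ncol(x), nc), drop = FALSE]
}

#' Decompose a frame into overlapping fixed-size tiles
#'
#' Cuts a full frame into `patch_size` x `patch_size` tiles whose origins
#' advance by `patch_size - 2 * margin` pixels, the final tile per axis
#' clamped to the frame edge. Frames smaller than a patch are
#' reflection-padded up to `patch_size` and cropped again by [stitch()].
#'
#' @param img Numeric matrix (a full frame, typically standardized pixels).
#' @param patch_size Tile side length in pixels; default 256.
#' @param margin Overlap margin on each side in pixels; default 32.
#' @return An object of class `tile_set`: list with `tiles` (each a list
#'   `row0`, `col0`, `patch`, origins 0-based), `patch_size`, `margin`,
#'   `frame_height`/`frame_width` (padded frame) and
#'   `orig_height`/`orig_width` (the caller's frame).
#' @export
make_tiles <- function(img, patch_size = 256L, margin = 32L) {
  stopifnot(is.matrix(img), nrow(img) >= 1, ncol(img) >= 1)
  patch_size <- as.integer(patch_size)
  margin <- as.integer(margin)
  if (patch_size <= 2L * margin) {
    stop("patch_size must exceed twice the margin (got ",
         patch_size, " vs 2*", margin, ")")
  }
  orig_h <- nrow(img)
  orig_w <- ncol(img)
  img <- reflect_pad(img, patch_size, patch_size)
  h <- nrow(img)
  w <- ncol(img)
  ro <- tile_origins(h, patch_size, margin)
  co <- tile_origins(w, patch_size, margin)
  tiles <- vector("list", length(ro) * length(co))
  k <- 1L
  for (r in ro) {
    for (cc in co) {
      tiles[[k]] <- list(
        row0 = r, col0 = cc,
        patch = img[(r + 1L):(r + patch_size), (cc + 1L):(cc + patch_size),
                    drop = FALSE]
      )
      k <- k + 1L
    }
  }
  structure(list(tiles = tiles, patch_size = patch_size, margin = margin,
                 frame_height = h, frame_width = w,
                 orig_height = orig_h, orig_width = orig_w),
            class = "tile_set")
}

#' Stitch predicted tiles back into a full frame
#'
#' The inverse of [make_tiles()]: every output pixel is taken from exactly
#' one tile, the one whose central region owns it, so stitching tiles cut
#' from a single array reproduces that array bit-exactly and predictions
#' near patch borders (where context is partially out of frame) are
#' discarded in favor of a neighboring tile's interior view.
#'
#' @param tileset A `tile_set` whose `patch` entries hold predicted values.
#' @return Numeric matrix of the original frame shape.
#' @export
stitch <- function(tileset) {
  stopifnot(inherits(tileset, "tile_set"))
  p <- tileset$patch_size
  m <- tileset$margin
  for (t in tileset$tiles) {
    if (!identical(dim(t$patch), c(p, p))) {
      stop("tile at (", t$row0, ",", t$col0, ") is not ", p, "x", p)
    }
  }
  ro <- sort(unique(vapply(tileset$tiles, `[[`, integer(1), "row0")))
  co <- sort(unique(vapply(tileset$tiles, `[[`, integer(1), "col0")))
  rown <- ownership_intervals(ro, p, m, tileset$frame_height)
  coln <- ownership_intervals(co, p, m, tileset$frame_width)
  out <- matrix(NA_real_, tileset$frame_height, tileset$frame_width)
  for (t in tileset$tiles) {
    i <- match(t$row0, ro)
    j <- match(t$col0, co)
    rs <- rown$start[i]; re <- rown$end[i]
    cs <- coln$start[j]; ce <- coln$end[j]
    if (re <= rs || ce <= cs) next
    out[(rs + 1L):re, (cs + 1L):ce] <-
      t$patch[(rs - t$row0 + 1L):(re - t$row0),
              (cs - t$col0 + 1L):(ce - t$col0), drop = FALSE]
  }
  out[seq_len(tileset$orig_height), seq_len(tileset$orig_width),
      drop = FALSE]
}
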