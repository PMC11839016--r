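#' Contrast Limited Adaptive Histogram Equalization
#'
#' Locally equalizes image contrast on a grid of tiles with a clipping limit,
#' flattening uneven field illumination and boosting weak cell edges before
#' standardization. Intensities stay on the input bit-depth scale.
#'
#' @param img Numeric matrix of integer-scale intensities.
#' @param clip_limit Contrast clipping limit (> 0); default 2.
#' @param tile_grid Integer vector of length 2, the local-equalization grid;
#'   default `c(8, 8)`.
#' @param max_intensity Full-scale value of the input (255 for 8-bit,
#'   65535 for 16-bit). Inferred from the data when `NULL`.
#' @return Numeric matrix, same shape, intensities in
#'   `[0, max_intensity]`.
#' @export
apply_clahe <- function(img, clip_limit = 2, tile_grid = c(8L, 8L),
                        max_intensity = NULL) {
  stopifnot(is.matrix(img), clip_limit > 0, length(tile_grid) == 2)
  if (is.null(max_intensity)) {
    max_intensity <- if (max(img) > 255) 65535 else 255
  }
  x <- img / max_intensity
  # the equalizer needs each dimension to be a multiple of its grid count;
  # reflection-pad up to the next multiple and crop back afterwards
  nr <- ceiling(nrow(x) / tile_grid[1]) * tile_grid[1]
  nc <- ceiling(ncol(x) / tile_grid[2]) * tile_grid[2]
  x <- reflect_pad(x, nr, nc)
  # EBImage indexes (x, y); the grid is symmetric by default so orientation
  # only matters for asymmetric grids: nx acts along matrix rows here.
  y <- EBImage::clahe(x, nx = tile_grid[1], ny = tile_grid[2],
                      limit = clip_limit)
  y <- y[seq_len(nrow(img)), seq_len(ncol(img)), drop = FALSE]
  out <- round(pmin(pmax(as.numeric(y), 0), 1) * max_intensity)
  matrix(out, nrow = nrow(img), ncol = ncol(img))
}

#' Standardize an image to zero mean and unit variance
#'
#' Removes the global mean and scales by the global standard deviation, the
#' normalization applied to every image before it reaches a patch predictor.
#' Constant images standardize to all zeros (the standard deviation is
#' floored at 1e-8) rather than raising an error, so degenerate frames never
#' abort a batch run.
#'
#' @param img Numeric matrix of intensities.
#' @return An object of class `std_image`: a list with `pixels` (the
#'   standardized matrix), and the removed `mean` and `sd`.
#' @export
standardize <- function(img) {
  stopifnot(is.matrix(img))
  m <- mean(img)
  # population standard deviation: the closed-form contract is
  # {0, 2} -> {-1, +1} regardless of pixel count
  s <- sqrt(mean((img - m)^2))
  if (!is.finite(s) || s < 1e-8) s <- 1e-8
  structure(list(pixels = (img - m) / s, mean = m, sd = s),
            class = "std_image")
}

#' @export
print.std_image <- function(x, ...) {
  cat(sprintf("<std_image %d x %d, removed mean=%.4g sd=%.4g>\n",
              nrow(x$pixels), ncol(x$pixels), x$mean, x$sd))
  invisible(x)
}
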