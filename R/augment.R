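#' Sample a random augmentation specification
#'
#' Draws one training-time augmentation: horizontal mirroring with
#' probability 1/2, a rotation angle uniform on \[-180, 180\] degrees, an
#' isotropic rescale factor uniform on \[0.8, 1.2\], a brightness factor
#' uniform on \[0.95, 1.05\], intensity inversion with probability 1/2,
#' and the origin of the 256 x 256 training window, uniform over the frame.
#'
#' @param seed Integer seed; the same seed always yields the same spec.
#' @param frame_shape Integer vector `c(rows, cols)` of the (padded) frame.
#' @param patch_size Training window side; default 256.
#' @return A list of class `aug_spec` with fields `mirror`, `angle`,
#'   `scale`, `brightness`, `invert`, `patch_row`, `patch_col` (1-based
#'   window origin).
#' @export
sample_augmentation <- function(seed, frame_shape, patch_size = 256L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= patch_size))
  with_seed(seed, {
    spec <- list(
      mirror = stats::runif(1) < 0.5,
      angle = stats::runif(1, -180, 180),
      scale = stats::runif(1, 0.8, 1.2),
      brightness = stats::runif(1, 0.95, 1.05),
      invert = stats::runif(1) < 0.5,
      patch_row = sample.int(frame_shape[1] - patch_size + 1L, 1),
      patch_col = sample.int(frame_shape[2] - patch_size + 1L, 1)
    )
    structure(spec, class = "aug_spec")
  })
}

#' The do-nothing augmentation
#' @param patch_row,patch_col Window origin (1-based).
#' @return An `aug_spec` whose geometric and photometric parts are identity.
#' @export
identity_augmentation <- function(patch_row = 1L, patch_col = 1L) {
  structure(list(mirror = FALSE, angle = 0, scale = 1, brightness = 1,
                 invert = FALSE, patch_row = patch_row, patch_col = patch_col),
            class = "aug_spec")
}

#' Geometric warp shared by image and map
#'
#' Applies mirror, then rotation, then rescale, all about the frame center,
#' by bilinear resampling of the inverse-mapped grid. Boundary handling is
#' `"reflect"` (mirrored interior, edge not duplicated) for images and
#' `"zero"` for distance maps, whose semantic background is 0.
#' @noRd
warp_geometric <- function(x, spec, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  if (!spec$mirror && spec$angle == 0 && spec$scale == 1) return(x)
  h <- nrow(x); w <- ncol(x)
  cr <- (h + 1) / 2
  cc <- (w + 1) / 2
  th <- spec$angle * pi / 180
  # output pixel -> input pixel: undo scale, then rotation, then mirror
  gr <- rep(seq_len(h), times = w) - cr
  gc <- rep(seq_len(w), each = h) - cc
  gr <- gr / spec$scale
  gc <- gc / spec$scale
  ir <- cos(th) * gr + sin(th) * gc
  ic <- -sin(th) * gr + cos(th) * gc
  if (spec$mirror) ic <- -ic
  ir <- ir + cr
  ic <- ic + cc
  r0 <- floor(ir); c0 <- floor(ic)
  fr <- ir - r0; fc <- ic - c0
  sample_at <- function(ri, ci) {
    if (boundary == "reflect") {
      ri <- reflect_coord(ri, h)
      ci <- reflect_coord(ci, w)
      x[cbind(ri, ci)]
    } else {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- numeric(length(ri))
      v[ok] <- x[cbind(ri[ok], ci[ok])]
      v
    }
  }
  v <- (1 - fr) * (1 - fc) * sample_at(r0, c0) +
       (1 - fr) * fc * sample_at(r0, c0 + 1) +
       fr * (1 - fc) * sample_at(r0 + 1, c0) +
       fr * fc * sample_at(r0 + 1, c0 + 1)
  matrix(v, h, w)
}

#' Reflect an index vector into 1..n without duplicating the edge pixel
#' @noRd
reflect_coord <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2 * (n - 1)
  r <- (i - 1) %% period
  as.integer(ifelse(r < n, r + 1, period - r + 1))
}

#' Apply an augmentation spec to a (standardized) image
#'
#' Geometric operations (mirror, rotate, rescale) are applied with bilinear
#' interpolation and reflection padding, then brightness multiplication,
#' then inversion. On standardized (zero-mean) images inversion is negation,
#' which equals full-scale intensity inversion up to the removed affine
#' statistics.
#'
#' @param spec An `aug_spec`.
#' @param img Numeric matrix.
#' @return Numeric matrix, same shape.
#' @export
augment_image <- function(spec, img) {
  stopifnot(inherits(spec, "aug_spec"))
  out <- warp_geometric(img, spec, boundary = "reflect")
  out <- out * spec$brightness
  if (spec$invert) out <- -out
  out
}

#' Apply an augmentation spec to a distance map
#'
#' Only the geometric operations are applied — a distance map is a
#' geometric quantity, so brightness and inversion are skipped.
#' Interpolated values are clamped back into \[0, 1\] and out-of-frame
#' regions are filled with the background value 0.
#'
#' @param spec An `aug_spec`.
#' @param dmap Numeric matrix in \[0, 1\].
#' @return Numeric matrix in \[0, 1\], same shape.
#' @export
augment_map <- function(spec, dmap) {
  stopifnot(inherits(spec, "aug_spec"))
  out <- warp_geometric(dmap, spec, boundary = "zero")
  pmin(pmax(out, 0), 1)
}

#' Cut one consistently augmented training pair
#'
#' Samples an augmentation keyed by `seed`, applies it to the image and its
#' distance map with the same interpolation grid, and cuts the same
#' `patch_size` window from both. Frames smaller than `patch_size` are
#' reflection-padded (image) / zero-padded (map) first.
#'
#' @param seed Integer seed for the augmentation draw.
#' @param img Numeric matrix (standardized image).
#' @param dmap Numeric matrix in \[0, 1\], same shape as `img`.
#' @param patch_size Window side; default 256.
#' @return List with `image` and `map`, both `patch_size` square, and the
#'   `spec` used.
#' @export
sample_training_pair <- function(seed, img, dmap, patch_size = 256L) {
  stopifnot(identical(dim(img), dim(dmap)))
  if (nrow(img) < patch_size || ncol(img) < patch_size) {
    img <- reflect_pad(img, patch_size, patch_size)
    d2 <- matrix(0, max(nrow(dmap), patch_size), max(ncol(dmap), patch_size))
    d2[seq_len(nrow(dmap)), seq_len(ncol(dmap))] <- dmap
    dmap <- d2
  }
  spec <- sample_augmentation(seed, dim(img), patch_size)
  ai <- augment_image(spec, img)
  am <- augment_map(spec, dmap)
  rows <- spec$patch_row:(spec$patch_row + patch_size - 1L)
  cols <- spec$patch_col:(spec$patch_col + patch_size - 1L)
  list(image = ai[rows, cols, drop = FALSE],
       map = am[rows, cols, drop = FALSE],
       spec = spec)
}
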