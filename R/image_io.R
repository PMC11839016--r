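#' Read a grayscale microscopy image
#'
#' Reads a TIFF or PNG image as a numeric matrix of intensities on the
#' original bit-depth scale (0..255 for 8-bit, 0..65535 for 16-bit). RGB
#' images are converted to grayscale by the standard luminance weighting
#' 0.299 R + 0.587 G + 0.114 B.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file with 1 or 3 channels.
#' @return A numeric matrix (rows = image height) of class intensities.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image, no such file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                   error = function(e) stop("unreadable TIFF file: ", path))
    px <- px * 1.0
  } else if (ext == "png") {
    px <- tryCatch(png::readPNG(path, info = TRUE),
                   error = function(e) stop("unreadable PNG file: ", path))
    info <- attr(px, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    px <- px * (2^depth - 1)
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  if (length(dim(px)) == 2) {
    return(round(px))
  }
  nch <- dim(px)[3]
  if (nch == 3) {
    return(round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]))
  }
  stop("unsupported channel count (", nch, ") in ", path,
       ": expected 1 (gray) or 3 (RGB)")
}

#' Read an instance label mask
#'
#' Label masks are single-channel integer images: 0 is background, positive
#' values identify cell instances.
#'
#' @param path Path to a single-channel PNG or TIFF.
#' @return An integer matrix.
#' @export
read_label_mask <- function(path) {
  px <- read_image(path)
  if (length(dim(px)) != 2) stop("label mask must be single-channel: ", path)
  storage.mode(px) <- "integer"
  px
}

#' Write an instance label mask as 16-bit TIFF or PNG
#'
#' @param mask Integer matrix of instance labels (0 = background, < 65536).
#' @param path Output path; `.tif`/`.tiff` or `.png`.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535) stop("label mask exceeds 16-bit range")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "png") {
    png::writePNG(mask / 65535, path)
  } else {
    stop("unsupported mask format: ", path)
  }
  invisible(path)
}

#' Write a grayscale image (8-bit scale) as TIFF or PNG
#'
#' @param img Numeric matrix of intensities in 0..255.
#' @param path Output path; `.tif`/`.tiff` or `.png`.
#' @export
write_gray_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}

#' Write a distance map as 32-bit TIFF
#'
#' @param dmap Numeric matrix with values in \[0, 1\].
#' @param path Output path ending in `.tif`/`.tiff`.
#' @export
write_distance_map <- function(dmap, path) {
  tiff::writeTIFF(dmap, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}
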