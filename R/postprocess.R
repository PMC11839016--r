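#' Dual-threshold binarization of a predicted distance map
#'
#' Produces the two binary images that drive instance recovery: the
#' "binary mask" (`dmap > t_foreground`, default 0.05), telling cell from
#' background, and the "cell centers" image (`dmap > t_center`, default
#' 0.5), which should contain exactly one connected component per cell.
#' Both comparisons are strict, and the same thresholds are used across all
#' experiments — they are insensitive to the image or training set.
#'
#' @param dmap Numeric matrix in \[0, 1\].
#' @param t_foreground,t_center The two thresholds,
#'   `0 <= t_foreground < t_center <= 1`.
#' @return List with logical matrices `binary_mask` and `cell_centers`
#'   (the latter a subset of the former).
#' @export
threshold_maps <- function(dmap, t_foreground = 0.05, t_center = 0.5) {
  stopifnot(t_foreground >= 0, t_foreground < t_center, t_center <= 1)
  list(binary_mask = dmap > t_foreground,
       cell_centers = dmap > t_center)
}

#' Recover instance masks from a distance map by seeded watershed
#'
#' Seeds are the 8-connected components of the cell-centers image;
#' flooding proceeds downhill on the distance map (high values first),
#' restricted to the binary mask, until basins meet — the meeting lines are
#' the recovered cell boundaries. Every flooded foreground pixel belongs
#' to a basin; foreground components containing no seed are discarded
#' (no center, no cell). Labels are canonical 1..N.
#'
#' @param dmap Numeric matrix in \[0, 1\].
#' @param t_foreground,t_center Thresholds as in [threshold_maps()].
#' @return Integer instance label mask.
#' @export
recover_instances <- function(dmap, t_foreground = 0.05, t_center = 0.5) {
  th <- threshold_maps(dmap, t_foreground, t_center)
  seeds <- cpp_label_components(th$cell_centers, 8L)
  if (max(seeds) == 0L) {
    return(matrix(0L, nrow(dmap), ncol(dmap)))
  }
  lab <- cpp_seeded_watershed(dmap, seeds, th$binary_mask)
  canonicalize_labels(lab)
}

#' Culture-health statistics from an instance mask
#'
#' The biology-facing per-image summary: number of cells, mean cell area
#' in pixels, confluency (fraction of the frame covered by cells), and the
#' number of neighbors of each cell. Two cells are neighbors when their
#' supports come within `2 * neighbor_radius` pixels (Euclidean) of each
#' other — equivalently, dilating each by a disk of `neighbor_radius`
#' makes them meet.
#'
#' @param mask Canonical integer label mask.
#' @param neighbor_radius Disk radius in pixels for the neighbor test;
#'   default 3.
#' @return A list of class `culture_report`: `cell_count`, `mean_area`,
#'   `confluency`, `neighbors` (integer vector, one entry per cell), and
#'   `areas` (per-cell pixel counts).
#' @export
culture_statistics <- function(mask, neighbor_radius = 3L) {
  stopifnot(is.matrix(mask))
  n <- n_labels(mask)
  frame_px <- length(mask)
  if (n == 0L) {
    return(structure(list(cell_count = 0L, mean_area = 0,
                          confluency = 0, neighbors = integer(0),
                          areas = integer(0)),
                     class = "culture_report"))
  }
  areas <- tabulate(mask[mask > 0L], nbins = n)
  fg <- sum(areas)
  neighbors <- integer(n)
  if (n > 1L) {
    reach <- 2 * as.numeric(neighbor_radius)
    for (a in seq_len(n - 1L)) {
      # exact Euclidean distance from every pixel to cell a's support:
      # foreground = not-a, background = a, so distmap measures distance
      # to the nearest a-pixel (0 on a itself)
      da <- EBImage::distmap(mask != a, metric = "euclidean")
      for (b in (a + 1L):n) {
        if (min(da[mask == b]) <= reach) {
          neighbors[a] <- neighbors[a] + 1L
          neighbors[b] <- neighbors[b] + 1L
        }
      }
    }
  }
  structure(list(cell_count = n, mean_area = fg / n,
                 confluency = fg / frame_px, neighbors = neighbors,
                 areas = areas),
            class = "culture_report")
}

#' @export
print.culture_report <- function(x, ...) {
  cat(sprintf(
    "<culture_report: %d cells, mean area %.1f px, confluency %.1f%%, mean neighbors %.2f>\n",
    x$cell_count, x$mean_area, 100 * x$confluency,
    if (x$cell_count > 0) mean(x$neighbors) else 0))
  invisible(x)
}

#' Tabulate a culture report
#'
#' @param report A `culture_report`.
#' @return A one-row tibble: `cell_count`, `mean_area_px`,
#'   `confluency_pct`, `mean_neighbors`.
#' @export
tidy_culture_report <- function(report) {
  stopifnot(inherits(report, "culture_report"))
  tibble::tibble(
    cell_count = report$cell_count,
    mean_area_px = report$mean_area,
    confluency_pct = 100 * report$confluency,
    mean_neighbors = if (report$cell_count > 0) mean(report$neighbors) else 0
  )
}
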