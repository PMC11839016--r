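#' Synthetic culture configuration
#'
#' Describes one phase-contrast-like synthetic frame: convex,
#' ellipse-based cells of varying size and elongation, a configurable
#' fraction of them placed touching an existing cell (clumps), soft
#' low-contrast edges, a linear field-brightness gradient, additive noise,
#' and either bright-on-dark or dark-on-bright polarity. Defaults emulate
#' a moderately confluent label-free culture; peanut-shaped cells are
#' avoided by construction so the distance-map round trip is well posed.
#'
#' @param frame Frame shape `c(rows, cols)`; default 256 x 256.
#' @param n_cells Number of cells to attempt to place; default 25.
#' @param radius_range Semi-major axis range in pixels; default `c(6, 12)`.
#' @param eccentricity_range Axis-ratio range (1 = circle); default
#'   `c(1, 2.5)`.
#' @param clump_fraction Fraction of cells placed touching an existing
#'   cell; default 0.5.
#' @param contrast Peak cell/background intensity difference (8-bit
#'   scale); default 60.
#' @param edge_softness Gaussian boundary blur sigma in pixels; default 1.5.
#' @param background_gradient Intensity change across the frame; default 30.
#' @param noise_sd Additive Gaussian noise sigma; default 6.
#' @param inverted `FALSE` for bright cells on dark background (dark
#'   field), `TRUE` for dark cells on a bright field (phase contrast).
#' @param seed Integer seed; the generator is bit-reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(frame = c(256L, 256L), n_cells = 25L,
                         radius_range = c(6, 12),
                         eccentricity_range = c(1, 2.5),
                         clump_fraction = 0.5, contrast = 60,
                         edge_softness = 1.5, background_gradient = 30,
                         noise_sd = 6, inverted = FALSE, seed = 1L) {
  stopifnot(length(frame) == 2, all(frame >= 32), n_cells >= 0,
            radius_range[1] >= 2, diff(radius_range) >= 0,
            eccentricity_range[1] >= 1,
            clump_fraction >= 0, clump_fraction <= 1)
  structure(list(frame = as.integer(frame), n_cells = as.integer(n_cells),
                 radius_range = radius_range,
                 eccentricity_range = eccentricity_range,
                 clump_fraction = clump_fraction, contrast = contrast,
                 edge_softness = edge_softness,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd, inverted = inverted,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# pixel set of a rotated ellipse; rows/cols clipped to the frame
ellipse_pixels <- function(cr, cc, a, b, theta, h, w) {
  half <- ceiling(a) + 1L
  rs <- max(1L, floor(cr - half)):min(h, ceiling(cr + half))
  cs <- max(1L, floor(cc - half)):min(w, ceiling(cc + half))
  if (length(rs) == 0 || length(cs) == 0) return(NULL)
  rr <- rep(rs, times = length(cs)) - cr
  cc2 <- rep(cs, each = length(rs)) - cc
  u <- cos(theta) * rr + sin(theta) * cc2
  v <- -sin(theta) * rr + cos(theta) * cc2
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(NULL)
  cbind(rep(rs, times = length(cs))[inside],
        rep(cs, each = length(rs))[inside])
}

# does the candidate pixel set have a 4-connected interior pixel?
has_interior <- function(px, h, w) {
  occ <- matrix(FALSE, h, w)
  occ[px] <- TRUE
  r <- px[, 1]; c <- px[, 2]
  ok <- r > 1 & r < h & c > 1 & c < w
  if (!any(ok)) return(FALSE)
  r <- r[ok]; c <- c[ok]
  any(occ[cbind(r - 1, c)] & occ[cbind(r + 1, c)] &
        occ[cbind(r, c - 1)] & occ[cbind(r, c + 1)])
}

#' Generate one synthetic culture frame with ground truth
#'
#' Places cells sequentially: clumped cells are dropped next to an
#' existing cell and trimmed to its free pixels (touching but never
#' merged — labels stay pairwise disjoint); separated cells must keep at
#' least one background pixel between themselves and every other cell.
#' Placement retries are bounded, so dense configurations return fewer
#' cells rather than hanging. The rendered image adds soft (blurred)
#' edges, a linear background gradient, Gaussian noise, and optional
#' polarity inversion on an 8-bit intensity scale.
#'
#' @param cfg A [synth_config()].
#' @return List with `image` (numeric matrix, 0..255), `mask` (canonical
#'   integer label mask), and `n_placed` (cells actually placed).
#' @export
generate_culture <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  h <- cfg$frame[1]
  w <- cfg$frame[2]
  with_seed(cfg$seed, {
    mask <- matrix(0L, h, w)
    centers <- NULL
    placed <- 0L
    for (i in seq_len(cfg$n_cells)) {
      want_clump <- placed > 0L && stats::runif(1) < cfg$clump_fraction
      done <- FALSE
      for (try in 1:40) {
        a <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
        ecc <- stats::runif(1, cfg$eccentricity_range[1],
                            cfg$eccentricity_range[2])
        b <- a / ecc
        theta <- stats::runif(1, 0, pi)
        if (want_clump) {
          j <- sample.int(placed, 1)
          ang <- stats::runif(1, 0, 2 * pi)
          dist <- stats::runif(1, 0.75, 0.95) *
            (a + centers[j, 3])
          cr <- centers[j, 1] + dist * cos(ang)
          cc <- centers[j, 2] + dist * sin(ang)
        } else {
          cr <- stats::runif(1, 1 + a, h - a)
          cc <- stats::runif(1, 1 + a, w - a)
        }
        if (cr < 1 || cr > h || cc < 1 || cc > w) next
        px <- ellipse_pixels(cr, cc, a, b, theta, h, w)
        if (is.null(px)) next
        free <- mask[px] == 0L
        if (want_clump) {
          px <- px[free, , drop = FALSE]
          if (nrow(px) < 20L) next
          # keep the largest connected piece of the trimmed candidate
          occ <- matrix(FALSE, h, w)
          occ[px] <- TRUE
          comp <- cpp_label_components(occ, 4L)
          sizes <- tabulate(comp[comp > 0])
          big <- which.max(sizes)
          px <- which(comp == big, arr.ind = TRUE)
          if (nrow(px) < 20L || !has_interior(px, h, w)) next
          # a clump must actually touch (8-neighborhood) an existing cell
          touches <- FALSE
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
            r2 <- px[, 1] + d[1]; c2 <- px[, 2] + d[2]
            ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
            if (any(mask[cbind(r2[ok], c2[ok])] > 0L)) { touches <- TRUE; break }
          }
          if (!touches) next
        } else {
          if (!all(free)) next
          # require a clear 1-px background moat around separated cells
          moat <- FALSE
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
            r2 <- px[, 1] + d[1]; c2 <- px[, 2] + d[2]
            ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
            if (any(mask[cbind(r2[ok], c2[ok])] > 0L)) { moat <- TRUE; break }
          }
          if (moat) next
          if (!has_interior(px, h, w)) next
        }
        placed <- placed + 1L
        mask[px] <- placed
        centers <- rbind(centers, c(mean(px[, 1]), mean(px[, 2]), a))
        done <- TRUE
        break
      }
      if (!done) next
    }
    img <- render_culture(mask, cfg)
    list(image = img, mask = canonicalize_labels(mask), n_placed = placed)
  })
}

# render intensities for a placed mask (uses the current RNG stream)
render_culture <- function(mask, cfg) {
  h <- nrow(mask)
  w <- ncol(mask)
  base_level <- if (cfg$inverted) 165 else 90
  grad_dir <- stats::runif(1, 0, 2 * pi)
  gr <- outer(seq_len(h) / h - 0.5, rep(1, w)) * cos(grad_dir) +
    outer(rep(1, h), seq_len(w) / w - 0.5) * sin(grad_dir)
  field <- base_level + cfg$background_gradient * gr
  soft <- (mask > 0) * 1.0
  if (cfg$edge_softness > 0) {
    soft <- EBImage::gblur(soft, sigma = cfg$edge_softness)
  }
  sign <- if (cfg$inverted) -1 else 1
  img <- field + sign * cfg$contrast * soft
  img <- img + stats::rnorm(h * w, sd = cfg$noise_sd)
  matrix(round(pmin(pmax(img, 0), 255)), h, w)
}

#' Generate a reproducible suite of synthetic cultures
#'
#' Per-image configurations jitter confluency (through the cell count),
#' contrast, and polarity around `base_cfg`; each frame gets its own
#' derived seed, so the suite is bit-reproducible from `seed` alone.
#'
#' @param base_cfg A [synth_config()] providing the shared parameters.
#' @param n_images Number of frames; default 20.
#' @param seed Suite seed.
#' @param confluency_range Target foreground-fraction range explored by
#'   the jitter; default `c(0.1, 0.6)`.
#' @param jitter_invert Alternate polarity across the suite; default TRUE.
#' @return List of `generate_culture()` results.
#' @export
generate_suite <- function(base_cfg, n_images = 20L, seed = 1L,
                           confluency_range = c(0.1, 0.6),
                           jitter_invert = TRUE) {
  stopifnot(n_images >= 1)
  mean_area <- pi * mean(base_cfg$radius_range)^2 /
    mean(base_cfg$eccentricity_range)
  frame_px <- prod(base_cfg$frame)
  lapply(seq_len(n_images), function(i) {
    cfg_i <- base_cfg
    pars <- with_seed(derive_seed(seed, i), {
      list(conf = stats::runif(1, confluency_range[1], confluency_range[2]),
           contrast = base_cfg$contrast * stats::runif(1, 0.7, 1.3),
           inv = if (jitter_invert) stats::runif(1) < 0.5 else
             base_cfg$inverted)
    })
    cfg_i$n_cells <- max(1L, as.integer(round(pars$conf * frame_px /
                                                mean_area)))
    cfg_i$contrast <- pars$contrast
    cfg_i$inverted <- pars$inv
    cfg_i$seed <- derive_seed(seed, i, 1000L)
    out <- generate_culture(cfg_i)
    out$cfg <- cfg_i
    out
  })
}
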