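# Shared fixture builders: everything is generated in code at test time.

# a small mask with two square cells and optional touching contact
two_square_mask <- function(h = 16, w = 16, touching = FALSE) {
  m <- matrix(0L, h, w)
  m[3:7, 3:7] <- 1L
  if (touching) m[3:7, 8:12] <- 2L else m[3:7, 10:14] <- 2L
  m
}

# brute-force normalized distance map: per cell, per pixel, the minimum
# Euclidean distance to any non-cell pixel (other cells and out-of-frame
# count as non-cell), divided by the per-cell maximum
brute_distance_map <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- matrix(0, h, w)
  for (k in sort(unique(mask[mask > 0]))) {
    px <- which(mask == k, arr.ind = TRUE)
    non <- which(mask != k, arr.ind = TRUE)
    ring <- rbind(cbind(0L, 0:(w + 1L)), cbind(h + 1L, 0:(w + 1L)),
                  cbind(1:h, 0L), cbind(1:h, w + 1L))
    non <- rbind(non, ring)
    d <- numeric(nrow(px))
    for (i in seq_len(nrow(px))) {
      d[i] <- sqrt(min((non[, 1] - px[i, 1])^2 + (non[, 2] - px[i, 2])^2))
    }
    out[px] <- d / max(d)
  }
  out
}

# brute-force SEG/DET from the full overlap table, independent of
# match_cells(): enumerate every reference-prediction overlap directly
brute_scores <- function(reference, predicted,
                         w_fn = 10, w_fp = 1, w_split = 5) {
  rl <- sort(unique(reference[reference > 0]))
  pl <- sort(unique(predicted[predicted > 0]))
  seg_terms <- numeric(length(rl))
  covered <- matrix(0L, length(rl), max(length(pl), 1))
  for (i in seq_along(rl)) {
    R <- reference == rl[i]
    for (j in seq_along(pl)) {
      S <- predicted == pl[j]
      inter <- sum(R & S)
      if (inter > 0.5 * sum(R)) {
        covered[i, j] <- 1L
        seg_terms[i] <- inter / sum(R | S)
      }
    }
  }
  n_fn <- sum(rowSums(covered) == 0)
  n_fp <- if (length(pl) == 0) 0 else sum(colSums(covered) == 0)
  n_split <- if (length(pl) == 0) 0 else sum(pmax(colSums(covered) - 1, 0))
  aogm <- w_fn * n_fn + w_fp * n_fp + w_split * n_split
  aogm0 <- w_fn * length(rl)
  list(seg = mean(seg_terms), det = 1 - min(aogm, aogm0) / aogm0)
}

# random label mask built from non-overlapping rectangles (may touch)
random_rect_mask <- function(h, w, max_cells = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  n <- sample.int(max_cells, 1)
  lab <- 0L
  for (i in seq_len(n)) {
    for (try in 1:20) {
      r0 <- sample.int(h - 2L, 1)
      c0 <- sample.int(w - 2L, 1)
      r1 <- min(h, r0 + sample.int(5, 1))
      c1 <- min(w, c0 + sample.int(5, 1))
      if (all(m[r0:r1, c0:c1] == 0L)) {
        lab <- lab + 1L
        m[r0:r1, c0:c1] <- lab
        break
      }
    }
  }
  m
}

# random instance mask for encoder tests: ellipse blobs that may touch or
# be clipped by the frame
random_blob_mask <- function(h, w, n_blobs = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  for (k in seq_len(n_blobs)) {
    cr <- runif(1, 1, h)
    cc <- runif(1, 1, w)
    a <- runif(1, 2, 6)
    b <- runif(1, 2, 6)
    rr <- rep(seq_len(h), times = w)
    cc2 <- rep(seq_len(w), each = h)
    inside <- ((rr - cr) / a)^2 + ((cc2 - cc) / b)^2 <= 1
    sel <- inside & (as.vector(m) == 0L)
    m[matrix(c(rr[sel], cc2[sel]), ncol = 2)] <- k
  }
  canonicalize_labels(m)
}
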