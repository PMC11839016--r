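test_that("dual thresholds are strict and nested", {
  dm <- matrix(0, 6, 6)
  dm[2, 2] <- 0.05; dm[3, 3] <- 0.5; dm[4, 4] <- 0.6
  th <- threshold_maps(dm)
  expect_false(th$binary_mask[2, 2])   # exactly 0.05 stays background
  expect_true(th$binary_mask[3, 3])
  expect_false(th$cell_centers[3, 3])  # exactly 0.5 never seeds a center
  expect_true(th$cell_centers[4, 4])
  expect_true(all(th$binary_mask | !th$cell_centers))
  expect_error(threshold_maps(dm, 0.6, 0.5))
  # all-zero map: both empty
  th0 <- threshold_maps(matrix(0, 4, 4))
  expect_false(any(th0$binary_mask))
  expect_false(any(th0$cell_centers))
})

disk_mask <- function(h, w, centers, r) {
  m <- matrix(0L, h, w)
  rr <- rep(1:h, w); cc <- rep(1:w, each = h)
  for (i in seq_len(nrow(centers))) {
    sel <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= r^2
    m[matrix(c(rr[sel], cc[sel]), ncol = 2)] <- i
  }
  m
}

test_that("watershed recovers separated and touching cells", {
  # two disks separated by background: exact recovery
  m <- disk_mask(40, 60, rbind(c(20, 15), c(20, 45)), 8)
  lab <- recover_instances(encode_distance_map(m))
  expect_equal(max(lab), 2)
  expect_equal(seg_score(m, lab), 1)
  expect_equal(det_score(m, lab), 1)
  # one disk: single label on the full support
  m1 <- disk_mask(30, 30, rbind(c(15, 15)), 9)
  lab1 <- recover_instances(encode_distance_map(m1))
  expect_equal(max(lab1), 1)
  expect_identical(lab1 > 0, m1 > 0)
  # two touching disks (distinct labels) split along the distance valley
  m2 <- disk_mask(40, 60, rbind(c(20, 22), c(20, 37)), 8)
  expect_true(any(m2 == 1) && any(m2 == 2))
  lab2 <- recover_instances(encode_distance_map(m2))
  expect_equal(max(lab2), 2)
  jacc <- function(a, b) sum(a & b) / sum(a | b)
  j1 <- max(jacc(m2 == 1, lab2 == 1), jacc(m2 == 1, lab2 == 2))
  j2 <- max(jacc(m2 == 2, lab2 == 1), jacc(m2 == 2, lab2 == 2))
  expect_gte(j1, 0.9)
  expect_gte(j2, 0.9)
})

test_that("seedless foreground is dropped; empty maps give empty masks", {
  dm <- matrix(0, 20, 20)
  dm[5:8, 5:8] <- 0.3          # foreground blob with no center seed
  dm[14:16, 14:16] <- 0.8      # seeded blob
  lab <- recover_instances(dm)
  expect_equal(max(lab), 1)
  expect_true(all(lab[5:8, 5:8] == 0))
  expect_equal(max(recover_instances(matrix(0, 10, 10))), 0)
  # every recovered label contains at least one center pixel, support
  # stays inside the binary mask
  g <- generate_culture(synth_config(seed = 77))
  d2 <- encode_distance_map(g$mask)
  l2 <- recover_instances(d2)
  th <- threshold_maps(d2)
  expect_true(all(l2[!th$binary_mask] == 0))
  for (k in seq_len(max(l2))) {
    expect_true(any(th$cell_centers[l2 == k]))
  }
})

test_that("raising the center threshold never creates more instances", {
  # guaranteed for circular cells, whose distance maps decrease radially so
  # superlevel sets stay connected while they shrink; elongated or carved
  # cells can split their discrete ridge at high thresholds (a relative of
  # the peanut ambiguity)
  g <- generate_culture(synth_config(clump_fraction = 0,
                                     eccentricity_range = c(1, 1),
                                     seed = 13))
  d <- encode_distance_map(g$mask)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9),
                   function(t) max(recover_instances(d, 0.05, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # and for maps with peaks of unequal height, cells drop out as the
  # threshold passes their peak
  dm <- matrix(0, 30, 60)
  rr <- rep(1:30, 60); cc <- rep(1:60, each = 30)
  dm[(rr - 15)^2 + (cc - 15)^2 <= 49] <- 0.6
  dm[(rr - 15)^2 + (cc - 45)^2 <= 49] <- 0.9
  counts2 <- vapply(c(0.5, 0.7, 0.95),
                    function(t) max(recover_instances(dm, 0.05, t)),
                    numeric(1))
  expect_equal(counts2, c(2, 1, 0))
})

test_that("culture statistics match hand counts", {
  empty <- culture_statistics(matrix(0L, 100, 100))
  expect_equal(empty$cell_count, 0)
  expect_equal(empty$mean_area, 0)
  expect_equal(empty$confluency, 0)
  expect_length(empty$neighbors, 0)
  one <- matrix(0L, 100, 100); one[11:20, 31:40] <- 1L
  cs <- culture_statistics(one)
  expect_equal(cs$cell_count, 1)
  expect_equal(cs$mean_area, 100)
  expect_equal(cs$confluency, 0.01)
  expect_equal(cs$neighbors, 0L)
  # two 5x5 cells with a 2-px gap: neighbors at radius 3, not at radius 1
  two <- matrix(0L, 30, 30)
  two[10:14, 5:9] <- 1L
  two[10:14, 12:16] <- 2L
  expect_equal(culture_statistics(two, 3)$neighbors, c(1L, 1L))
  expect_equal(culture_statistics(two, 1)$neighbors, c(0L, 0L))
  # brute-force cross-check: neighbor iff min pixel distance <= 2 * radius
  set.seed(3)
  g <- generate_culture(synth_config(n_cells = 8L, seed = 55))
  for (r in c(1L, 3L)) {
    cs <- culture_statistics(g$mask, r)
    n <- cs$cell_count
    pix <- lapply(seq_len(n), function(k) which(g$mask == k, arr.ind = TRUE))
    brute <- integer(n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      dmin <- sqrt(min(outer(pix[[a]][, 1], pix[[b]][, 1], `-`)^2 +
                         outer(pix[[a]][, 2], pix[[b]][, 2], `-`)^2))
      if (dmin <= 2 * r) {
        brute[a] <- brute[a] + 1L
        brute[b] <- brute[b] + 1L
      }
    }
    expect_equal(cs$neighbors, brute)
  }
})
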