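test_that("read_image handles gray, RGB and rejects odd channel counts", {
  d <- withr::local_tempdir()
  # constant 8-bit gray PNG
  p1 <- file.path(d, "const.png")
  png::writePNG(matrix(7 / 255, 5, 4), p1)
  img <- read_image(p1)
  expect_equal(dim(img), c(5, 4))
  expect_true(all(img == 7))
  # gray RGB maps to itself under luminance weighting
  p2 <- file.path(d, "rgb.png")
  arr <- array(100 / 255, dim = c(6, 6, 3))
  png::writePNG(arr, p2)
  expect_true(all(read_image(p2) == 100))
  # 2-channel (gray + alpha) is unsupported
  p3 <- file.path(d, "ga.png")
  png::writePNG(array(0.5, dim = c(4, 4, 2)), p3)
  expect_error(read_image(p3), "unsupported channel count")
  # missing file names the path
  expect_error(read_image(file.path(d, "nope.png")), "nope.png")
})

test_that("16-bit masks round-trip through TIFF", {
  d <- withr::local_tempdir()
  m <- matrix(sample(0:999, 400, replace = TRUE), 20, 20)
  storage.mode(m) <- "integer"
  f <- file.path(d, "m.tif")
  write_label_mask(m, f)
  expect_identical(read_label_mask(f), m)
})

test_that("CLAHE preserves shape, keeps constants flat, boosts local contrast", {
  const <- matrix(120, 64, 64)
  out <- apply_clahe(const)
  expect_equal(dim(out), c(64, 64))
  expect_equal(stats::sd(out), 0) # no contrast to equalize
  # gradient field with a small dark disk: local disk/background contrast
  # (mean absolute step across the boundary) must increase
  h <- 96
  img <- matrix(rep(seq(80, 150, length.out = h), each = h), h, h)
  rr <- rep(1:h, h); cc <- rep(1:h, each = h)
  disk <- (rr - 40)^2 + (cc - 40)^2 <= 36
  img[disk] <- img[disk] - 12
  img <- round(img)
  ring <- (rr - 40)^2 + (cc - 40)^2 <= 81 & !disk
  contrast <- function(x) abs(mean(x[disk]) - mean(x[ring]))
  eq <- apply_clahe(img)
  expect_gt(contrast(eq), contrast(img))
  # low-contrast two-level image: output histogram spans at least as much
  two <- matrix(100L, 64, 64); two[, 33:64] <- 110L
  eq2 <- apply_clahe(two)
  expect_gte(diff(range(eq2)), diff(range(two)))
  # works on frames whose size is not a multiple of the tile grid
  odd <- apply_clahe(matrix(round(runif(300 * 300, 0, 255)), 300, 300))
  expect_equal(dim(odd), c(300, 300))
})

test_that("standardize hits zero mean, unit variance, and is idempotent", {
  img <- matrix(c(0, 2), 10, 10)
  s <- standardize(img)
  expect_true(all(s$pixels %in% c(-1, 1)))
  expect_equal(s$mean, 1)
  set.seed(1)
  r <- matrix(runif(300 * 200, 0, 255), 300, 200)
  s2 <- standardize(r)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_lt(abs(mean(s2$pixels)), 1e-6 * s2$sd)
  expect_lt(abs(pop_sd(s2$pixels) - 1), 1e-6)
  expect_equal(s2$mean, mean(r))
  expect_equal(s2$sd, pop_sd(r))
  twice <- standardize(s2$pixels)
  expect_equal(twice$pixels, s2$pixels, tolerance = 1e-8)
  # constant input: std floor yields all zeros, no error
  expect_true(all(standardize(matrix(5, 8, 8))$pixels == 0))
})

test_that("tile origins follow the stride-and-clamp rule", {
  expect_length(make_tiles(matrix(0, 256, 256))$tiles, 1)
  t512 <- make_tiles(matrix(0, 512, 512))
  expect_length(t512$tiles, 9)
  expect_setequal(unique(vapply(t512$tiles, `[[`, integer(1), "row0")),
                  c(0L, 192L, 256L))
  t300 <- make_tiles(matrix(0, 300, 300))
  expect_length(t300$tiles, 4)
  expect_setequal(unique(vapply(t300$tiles, `[[`, integer(1), "col0")),
                  c(0L, 44L))
  expect_error(make_tiles(matrix(0, 300, 300), patch_size = 64, margin = 32),
               "margin")
})

test_that("stitch(make_tiles(x)) is the identity for arbitrary shapes", {
  set.seed(42)
  for (dims in list(c(512, 512), c(300, 300), c(256, 256), c(270, 512),
                    c(100, 40), c(1, 1), c(3, 700))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    expect_identical(stitch(make_tiles(x)), x)
  }
})

test_that("central regions partition the frame and own conflicting pixels", {
  # count ownership by stitching tiles of distinct constants, then checking
  # every pixel carries exactly one tile's constant from the expected owner
  ts <- make_tiles(matrix(0, 512, 512))
  for (i in seq_along(ts$tiles)) {
    ts$tiles[[i]]$patch <- matrix(i, 256, 256)
  }
  out <- stitch(ts)
  expect_false(anyNA(out))
  expect_setequal(sort(unique(as.vector(out))), 1:9)
  # two tiles disagree across their 64-px overlap: the owner of each pixel
  # is decided by the central-region rule, first tile up to 224, then next
  ts2 <- make_tiles(matrix(0, 256, 448))
  ts2$tiles[[1]]$patch <- matrix(1, 256, 256)
  ts2$tiles[[2]]$patch <- matrix(2, 256, 256)
  out2 <- stitch(ts2)
  expect_true(all(out2[, 1:224] == 1))
  expect_true(all(out2[, 225:448] == 2))
  # shape contract
  ts2$tiles[[1]]$patch <- matrix(1, 10, 10)
  expect_error(stitch(ts2), "not 256x256")
})
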