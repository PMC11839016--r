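test_that("oracle predictor reproduces the encoded ground truth exactly", {
  g <- generate_culture(synth_config(frame = c(300L, 300L), seed = 21))
  target <- encode_distance_map(g$mask)
  pred <- oracle_predictor(g$mask)
  patch <- matrix(0, 256, 256)
  expect_identical(predict_patch(pred, patch, 0L, 0L), target[1:256, 1:256])
  expect_identical(predict_patch(pred, patch, 44L, 44L),
                   target[45:300, 45:300])
  expect_error(predict_patch(pred, patch, -1L, 0L), "outside")
  # full pipeline is lossless with the oracle
  expect_identical(predict_frame(pred, g$image), target)
  # all-background ground truth predicts zero everywhere
  z <- oracle_predictor(matrix(0L, 300, 300))
  expect_true(all(predict_patch(z, patch, 10L, 10L) == 0))
})

test_that("constant-zero predictor yields an all-zero frame of input shape", {
  img <- matrix(round(runif(300 * 280, 0, 255)), 300, 280)
  out <- predict_frame(constant_predictor(0), img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out == 0))
})

test_that("l2 loss is the symmetric mean squared difference", {
  a <- matrix(runif(64), 8, 8)
  expect_equal(l2_loss(a, a), 0)
  expect_equal(l2_loss(matrix(1, 4, 4), matrix(0, 4, 4)), 1)
  b <- matrix(runif(64), 8, 8)
  expect_equal(l2_loss(a, b), l2_loss(b, a))
  expect_error(l2_loss(a, matrix(0, 4, 4)), "shape mismatch")
})

test_that("learning-rate schedule ramps to base then decays linearly to 0", {
  expect_equal(lr_at_step(250, 1e-4, 250, 1000), 1e-4)
  expect_equal(lr_at_step(1000, 1e-4, 250, 1000), 0)
  expect_equal(lr_at_step(625, 1e-4, 250, 1000), 5e-5) # decay midpoint
  expect_equal(lr_at_step(125, 1e-4, 250, 1000), 5e-5) # warmup midpoint
  expect_equal(lr_at_step(0, 1e-4, 250, 1000), 0)
  expect_error(lr_at_step(10, 1e-4, 250, 250), "exceed")
})

test_that("training runs reproducibly and records the schedule it follows", {
  suite <- generate_suite(synth_config(frame = c(128L, 128L), n_cells = 8L),
                          n_images = 4, seed = 31)
  imgs <- lapply(suite, `[[`, "image")
  masks <- lapply(suite, `[[`, "mask")
  cfg <- train_config(epochs = 3, batch_size = 2, base_lr = 0.05,
                      warmup_steps = 2, seed = 5)
  fit <- train_predictor(tiny_backbone(seed = 5), imgs, masks, cfg,
                         patch_size = 64)
  expect_equal(nrow(fit$history), 2 * 3) # ceil(4/2) steps x 3 epochs
  total <- 6
  expect_equal(fit$history$lr,
               vapply(seq_len(total), lr_at_step, numeric(1),
                      base_lr = 0.05, warmup_steps = 2, total_steps = total))
  fit2 <- train_predictor(tiny_backbone(seed = 5), imgs, masks, cfg,
                          patch_size = 64)
  expect_identical(fit$history, fit2$history)
  # trained predictor still honors the sigmoid contract
  out <- predict_patch(fit$predictor, matrix(rnorm(64 * 64), 64, 64))
  expect_true(all(out > 0 & out < 1))
  expect_error(train_predictor(tiny_backbone(), list(), list(), cfg),
               "empty")
})

test_that("full-batch loss decreases near-monotonically on one image", {
  g <- generate_culture(synth_config(frame = c(128L, 128L), n_cells = 10L,
                                     seed = 41))
  cfg <- train_config(epochs = 10, batch_size = 1, base_lr = 0.05,
                      warmup_steps = 1, seed = 9)
  fit <- train_predictor(tiny_backbone(seed = 9), list(g$image),
                         list(g$mask), cfg, augment = FALSE,
                         patch_size = 128)
  drops <- diff(fit$history$loss)
  expect_lte(sum(drops > 0), 1) # allow one optimizer-noise violation
  expect_lt(fit$history$loss[10], fit$history$loss[1])
})
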