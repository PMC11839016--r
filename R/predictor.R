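#' Patch predictors
#'
#' A patch predictor maps one standardized `patch_size` x `patch_size`
#' image patch to a distance-map patch with values in \[0, 1\] (the sigmoid
#' contract). Predictors are S3 objects dispatched through
#' [predict_patch()]; the package ships two: [oracle_predictor()], which
#' returns the encoded ground-truth map and is exact (used to validate the
#' tiling/stitching path independently of any learned model), and
#' [tiny_backbone()], a small trainable convolutional network for
#' desk-scale training experiments.
#'
#' @param predictor A `patch_predictor` object.
#' @param patch Numeric matrix, the standardized image patch.
#' @param row0,col0 0-based origin of the patch within the frame (some
#'   predictors, like the oracle, are location-aware).
#' @return Numeric matrix, same shape as `patch`, values in \[0, 1\].
#' @export
predict_patch <- function(predictor, patch, row0 = 0L, col0 = 0L) {
  UseMethod("predict_patch")
}

#' Ground-truth oracle predictor
#'
#' Wraps a ground-truth label mask: prediction of the patch at `(row0,
#' col0)` is the corresponding crop of `encode_distance_map(mask)`,
#' independent of the pixel content of the patch. Out-of-mask regions
#' (reflection padding of small frames) predict background 0.
#'
#' @param mask Integer instance label mask covering the frame.
#' @return A `patch_predictor` of class `oracle_predictor`.
#' @export
oracle_predictor <- function(mask) {
  dmap <- encode_distance_map(canonicalize_labels(mask))
  structure(list(dmap = dmap), class = c("oracle_predictor", "patch_predictor"))
}

#' @export
predict_patch.oracle_predictor <- function(predictor, patch, row0 = 0L,
                                           col0 = 0L) {
  p <- nrow(patch)
  stopifnot(ncol(patch) == p)
  if (row0 < 0 || col0 < 0) stop("patch origin outside frame")
  d <- predictor$dmap
  out <- matrix(0, p, p)
  rs <- (row0 + 1L):min(row0 + p, nrow(d))
  cs <- (col0 + 1L):min(col0 + p, ncol(d))
  if (row0 + 1L <= nrow(d) && col0 + 1L <= ncol(d)) {
    out[seq_along(rs), seq_along(cs)] <- d[rs, cs, drop = FALSE]
  }
  out
}

#' Constant-value predictor (degenerate baseline)
#' @param value Constant in \[0, 1\] predicted everywhere; default 0.
#' @return A `patch_predictor`.
#' @export
constant_predictor <- function(value = 0) {
  stopifnot(value >= 0, value <= 1)
  structure(list(value = value),
            class = c("constant_predictor", "patch_predictor"))
}

#' @export
predict_patch.constant_predictor <- function(predictor, patch, row0 = 0L,
                                             col0 = 0L) {
  matrix(predictor$value, nrow(patch), ncol(patch))
}

#' Mean squared error between two map patches
#'
#' The training loss: the mean over pixels of the squared difference.
#'
#' @param pred,target Numeric matrices of identical shape.
#' @return Non-negative scalar; 0 iff the patches are identical.
#' @export
l2_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) {
    stop("l2_loss: shape mismatch (", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(target), collapse = "x"), ")")
  }
  mean((pred - target)^2)
}

#' Learning rate at a training step
#'
#' Linear warm-up from 0 to `base_lr` over the first `warmup_steps` steps,
#' then linear decay back to 0 at `total_steps`.
#'
#' @param step Step index, `0 <= step <= total_steps`.
#' @param base_lr Peak learning rate.
#' @param warmup_steps Warm-up period in steps.
#' @param total_steps Total optimization steps in the run.
#' @return The learning rate, a non-negative scalar.
#' @export
lr_at_step <- function(step, base_lr, warmup_steps, total_steps) {
  if (total_steps <= warmup_steps) {
    stop("total_steps must exceed warmup_steps")
  }
  stopifnot(step >= 0, step <= total_steps)
  if (step < warmup_steps) {
    base_lr * step / warmup_steps
  } else {
    base_lr * (total_steps - step) / (total_steps - warmup_steps)
  }
}

#' Training configuration
#'
#' Defaults follow the published fine-tuning protocol: AdamW with initial
#' learning rate 1e-4, weight decay 0.1, beta1 0.9, beta2 0.999, warm-up
#' period 250 steps with linear decay to zero, batch size 2, 40 epochs.
#'
#' @param epochs,batch_size,base_lr,weight_decay,beta1,beta2,warmup_steps
#'   Optimizer and schedule parameters.
#' @param seed Integer seed controlling initialization and augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 2L, base_lr = 1e-4,
                         weight_decay = 0.1, beta1 = 0.9, beta2 = 0.999,
                         warmup_steps = 250L, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              base_lr = base_lr, weight_decay = weight_decay,
              beta1 = beta1, beta2 = beta2,
              warmup_steps = as.integer(warmup_steps), seed = as.integer(seed))
  stopifnot(all(unlist(cfg[c("epochs", "batch_size", "base_lr",
                             "weight_decay", "beta1", "beta2")]) > 0))
  structure(cfg, class = "train_config")
}

#' Run full-frame inference with a patch predictor
#'
#' The complete inference path: CLAHE, standardization, sliding-window
#' tiling, per-patch prediction, and single-ownership stitching back to a
#' full-frame distance map.
#'
#' @param predictor A `patch_predictor`.
#' @param img Numeric matrix of raw intensities (a grayscale frame).
#' @param patch_size,margin Tiling parameters; defaults 256 and 32.
#' @param clahe_clip,clahe_grid CLAHE parameters passed to [apply_clahe()].
#' @return Numeric matrix in \[0, 1\] with the shape of `img`.
#' @export
predict_frame <- function(predictor, img, patch_size = 256L, margin = 32L,
                          clahe_clip = 2, clahe_grid = c(8L, 8L)) {
  pre <- standardize(apply_clahe(img, clahe_clip, clahe_grid))
  ts <- make_tiles(pre$pixels, patch_size, margin)
  ts$tiles <- lapply(ts$tiles, function(t) {
    t$patch <- predict_patch(predictor, t$patch, t$row0, t$col0)
    t
  })
  out <- stitch(ts)
  pmin(pmax(out, 0), 1)
}
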