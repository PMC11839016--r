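#' Tiny trainable convolutional backbone
#'
#' A small fully-convolutional encoder for desk-scale training experiments:
#' conv 5x5 (1 -> `channels`) + ReLU, conv 3x3 (`channels` -> `channels`) +
#' ReLU, conv 1x1 (`channels` -> 1) + sigmoid, all with "same" zero
#' padding, so any patch size maps to a distance-map patch of the same
#' shape with values in (0, 1). Roughly `25 c + 9 c^2 + c` weights
#' (~800 for the default 8 channels) — deliberately small enough to train
#' in seconds on a CPU while still exercising the full training loop
#' (augmentation, batching, AdamW, LR schedule).
#'
#' @param channels Hidden channel count; default 8.
#' @param seed Seed for He-scaled weight initialization.
#' @return A `patch_predictor` of class `tiny_backbone`.
#' @export
tiny_backbone <- function(channels = 8L, seed = 1L) {
  c1 <- as.integer(channels)
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(25 * c1, sd = sqrt(2 / 25)), 25, c1),
    b1 = numeric(c1),
    W2 = matrix(stats::rnorm(9 * c1 * c1, sd = sqrt(2 / (9 * c1))),
                9 * c1, c1),
    b2 = numeric(c1),
    W3 = matrix(stats::rnorm(c1, sd = sqrt(1 / c1)), c1, 1),
    b3 = 0
  ))
  structure(list(params = params, channels = c1),
            class = c("tiny_backbone", "patch_predictor"))
}

# neighborhood gather indices for "same" convolution, cached per shape
.idx_cache <- new.env(parent = emptyenv())

conv_idx <- function(h, w, k) {
  key <- paste(h, w, k, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- (k - 1L) %/% 2L
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  idx <- matrix(NA_integer_, h * w, k * k)
  o <- 1L
  for (dj in -half:half) {
    for (di in -half:half) {
      r2 <- rr + di
      c2 <- cc + dj
      ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
      v <- rep(NA_integer_, h * w)
      v[ok] <- (c2[ok] - 1L) * h + r2[ok]
      idx[, o] <- v
      o <- o + 1L
    }
  }
  .idx_cache[[key]] <- idx
  idx
}

# gather a single-channel field into im2col form (zeros outside the frame)
gather1 <- function(xv, idx) {
  out <- matrix(0, nrow(idx), ncol(idx))
  for (o in seq_len(ncol(idx))) {
    v <- idx[, o]
    ok <- !is.na(v)
    out[ok, o] <- xv[v[ok]]
  }
  out
}

# gather a multi-channel field (npix x C) into im2col blocks
gatherC <- function(a, idx) {
  C <- ncol(a)
  out <- matrix(0, nrow(idx), ncol(idx) * C)
  for (o in seq_len(ncol(idx))) {
    v <- idx[, o]
    ok <- !is.na(v)
    out[ok, ((o - 1L) * C + 1L):(o * C)] <- a[v[ok], , drop = FALSE]
  }
  out
}

# scatter-add im2col-block gradients back onto the multi-channel field
scatterC <- function(d, idx, C) {
  out <- matrix(0, nrow(idx), C)
  for (o in seq_len(ncol(idx))) {
    v <- idx[, o]
    ok <- !is.na(v)
    blk <- d[ok, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    s <- rowsum(blk, v[ok])
    rows <- as.integer(rownames(s))
    out[rows, ] <- out[rows, ] + s
  }
  out
}

backbone_forward <- function(params, x, keep = FALSE) {
  h <- nrow(x); w <- ncol(x)
  C <- ncol(params$W1)
  i5 <- conv_idx(h, w, 5L)
  i3 <- conv_idx(h, w, 3L)
  X1 <- gather1(as.numeric(x), i5)
  Z1 <- sweep(X1 %*% params$W1, 2, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  X2 <- gatherC(A1, i3)
  Z2 <- sweep(X2 %*% params$W2, 2, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  Z3 <- A2 %*% params$W3 + params$b3
  Y <- 1 / (1 + exp(-Z3))
  if (!keep) return(matrix(Y, h, w))
  list(Y = Y, Z3 = Z3, A2 = A2, Z2 = Z2, X2 = X2, A1 = A1, Z1 = Z1,
       X1 = X1, i3 = i3, h = h, w = w, C = C)
}

backbone_backward <- function(params, fw, target) {
  npix <- fw$h * fw$w
  dZ3 <- (2 / npix) * (fw$Y - as.numeric(target)) * fw$Y * (1 - fw$Y)
  dW3 <- crossprod(fw$A2, dZ3)
  db3 <- sum(dZ3)
  dA2 <- dZ3 %*% t(params$W3)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$X2, dZ2)
  db2 <- colSums(dZ2)
  dX2 <- dZ2 %*% t(params$W2)
  dA1 <- scatterC(dX2, fw$i3, fw$C)
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$X1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' @export
predict_patch.tiny_backbone <- function(predictor, patch, row0 = 0L,
                                        col0 = 0L) {
  backbone_forward(predictor$params, patch)
}

# AdamW with decoupled weight decay (decay applied to weights, not biases)
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamw_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] +
      (1 - cfg$beta2) * grads[[nm]]^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + 1e-8)
    wd <- if (substr(nm, 1, 1) == "W") cfg$weight_decay else 0
    params[[nm]] <- params[[nm]] - lr * upd - lr * wd * params[[nm]]
  }
  list(params = params, state = state)
}

#' Train a tiny backbone on paired images and label masks
#'
#' Distance maps are encoded once per image before training. Every epoch
#' each image contributes one augmented 256 x 256 patch (keyed by
#' `(seed, epoch, image)` so runs are reproducible and patches vary across
#' epochs); patches are consumed in batches of `cfg$batch_size` by AdamW
#' under the warm-up/linear-decay schedule of [lr_at_step()].
#'
#' @param predictor A `tiny_backbone` (or compatible trainable predictor).
#' @param images List of raw intensity matrices.
#' @param masks List of instance label masks, same shapes as `images`.
#' @param cfg A [train_config()].
#' @param augment Apply random augmentation (default `TRUE`); when `FALSE`
#'   the top-left 256 x 256 window of each preprocessed frame is used
#'   every epoch.
#' @param patch_size Training patch side; default 256.
#' @return List with `predictor` (trained), and `history`, a tibble with
#'   one row per optimization step: `step`, `epoch`, `lr`, `loss`.
#' @export
train_predictor <- function(predictor, images, masks, cfg,
                            augment = TRUE, patch_size = 256L) {
  stopifnot(inherits(predictor, "tiny_backbone"),
            inherits(cfg, "train_config"))
  n <- length(images)
  if (n == 0L) stop("training dataset is empty")
  stopifnot(length(masks) == n)
  dmaps <- lapply(masks, function(m) encode_distance_map(canonicalize_labels(m)))
  pimgs <- lapply(images, function(im) standardize(apply_clahe(im))$pixels)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- steps_per_epoch * cfg$epochs
  if (total_steps <= cfg$warmup_steps) {
    stop("warmup_steps (", cfg$warmup_steps,
         ") must be below total steps (", total_steps, ")")
  }
  params <- predictor$params
  state <- adamw_init(params)
  hist <- vector("list", total_steps)
  step <- 0L
  for (e in seq_len(cfg$epochs)) {
    order <- with_seed(derive_seed(cfg$seed, e, 0L), sample.int(n))
    batch <- list()
    flush <- function() {
      step <<- step + 1L
      lr <- lr_at_step(step, cfg$base_lr, cfg$warmup_steps, total_steps)
      grads <- NULL
      loss <- 0
      for (pair in batch) {
        fw <- backbone_forward(params, pair$image, keep = TRUE)
        loss <- loss + mean((fw$Y - as.numeric(pair$map))^2)
        g <- backbone_backward(params, fw, pair$map)
        grads <- if (is.null(grads)) g else
          Map(`+`, grads, g)
      }
      nb <- length(batch)
      grads <- lapply(grads, function(g) g / nb)
      loss <- loss / nb
      upd <- adamw_step(params, grads, state, lr, cfg)
      params <<- upd$params
      state <<- upd$state
      hist[[step]] <<- tibble::tibble(step = step, epoch = e,
                                      lr = lr, loss = loss)
      batch <<- list()
    }
    for (i in order) {
      pair <- if (augment) {
        sample_training_pair(derive_seed(cfg$seed, e, i),
                             pimgs[[i]], dmaps[[i]], patch_size)
      } else {
        img <- reflect_pad(pimgs[[i]], patch_size, patch_size)
        dm <- matrix(0, nrow(img), ncol(img))
        dm[seq_len(nrow(dmaps[[i]])), seq_len(ncol(dmaps[[i]]))] <- dmaps[[i]]
        list(image = img[1:patch_size, 1:patch_size],
             map = dm[1:patch_size, 1:patch_size])
      }
      batch[[length(batch) + 1L]] <- pair
      if (length(batch) == cfg$batch_size) flush()
    }
    if (length(batch) > 0L) flush()
  }
  predictor$params <- params
  list(predictor = predictor, history = do.call(rbind, hist))
}
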