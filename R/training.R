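#' On-the-fly augmentation configuration
#'
#' Augmentations are applied independently per image per epoch, drawing
#' from the current RNG stream: they add diversity for generalization and
#' deliberately do not rebalance class counts. All transforms are
#' label-preserving.
#'
#' @param horizontal_flip,vertical_flip Flip probabilities in `[0,1]`.
#' @param rotation Maximum rotation in degrees (drawn uniformly in
#'   `[-rotation, rotation]`).
#' @param jitter Color-jitter amplitude: brightness, contrast and
#'   saturation factors drawn in `1 +/- jitter`.
#' @return An `augment_config` list.
#' @export
augment_config <- function(horizontal_flip = 0.5, vertical_flip = 0.5,
                           rotation = 15, jitter = 0.2) {
  if (any(c(horizontal_flip, vertical_flip) < 0 |
            c(horizontal_flip, vertical_flip) > 1)) {
    stopf("config error: flip probabilities must lie in [0,1]")
  }
  if (rotation < 0 || jitter < 0) {
    stopf("config error: rotation and jitter amplitudes must be >= 0")
  }
  structure(list(horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 rotation = rotation, jitter = jitter),
            class = "augment_config")
}

# Bilinear rotation about the image center, clamp-to-edge sampling.
rotate_image <- function(img, angle_deg) {
  S1 <- dim(img)[1]; S2 <- dim(img)[2]
  th <- angle_deg * pi / 180
  cy <- (S1 + 1) / 2; cx <- (S2 + 1) / 2
  yy <- matrix(rep(seq_len(S1), times = S2), S1) - cy
  xx <- matrix(rep(seq_len(S2), each = S1), S1) - cx
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  y0 <- pmin(pmax(floor(sy), 1), S1); y1 <- pmin(y0 + 1, S1)
  x0 <- pmin(pmax(floor(sx), 1), S2); x1 <- pmin(x0 + 1, S2)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    p <- img[, , ch]
    out[, , ch] <- (1 - fy) * (1 - fx) * p[cbind(c(y0), c(x0))] +
      (1 - fy) * fx * p[cbind(c(y0), c(x1))] +
      fy * (1 - fx) * p[cbind(c(y1), c(x0))] +
      fy * fx * p[cbind(c(y1), c(x1))]
  }
  out
}

#' Augment a batch of images
#'
#' Draws are consumed from the current RNG stream only, so a fixed
#' `.Random.seed` reproduces the output exactly.
#'
#' @param images Array `H x W x 3 x N` (or single `H x W x 3`) in `[0,1]`.
#' @param config An [augment_config()].
#' @return Array of the same shape, intensities clamped to `[0,1]`.
#' @export
augment_batch <- function(images, config) {
  single <- length(dim(images)) == 3
  if (single) dim(images) <- c(dim(images), 1L)
  N <- dim(images)[4]
  for (n in seq_len(N)) {
    img <- images[, , , n]
    if (config$horizontal_flip > 0 &&
          stats::runif(1) < config$horizontal_flip) {
      img <- img[, dim(img)[2]:1, , drop = FALSE]
    }
    if (config$vertical_flip > 0 && stats::runif(1) < config$vertical_flip) {
      img <- img[dim(img)[1]:1, , , drop = FALSE]
    }
    if (config$rotation > 0) {
      img <- rotate_image(img, stats::runif(1, -config$rotation,
                                            config$rotation))
    }
    if (config$jitter > 0) {
      a <- config$jitter
      img <- img * stats::runif(1, 1 - a, 1 + a)                 # brightness
      m <- mean(img)
      img <- (img - m) * stats::runif(1, 1 - a, 1 + a) + m       # contrast
      gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      s <- stats::runif(1, 1 - a, 1 + a)                         # saturation
      for (ch in 1:3) img[, , ch] <- gray + s * (img[, , ch] - gray)
    }
    images[, , , n] <- clamp01(img)
  }
  if (single) dim(images) <- dim(images)[1:3]
  images
}

#' Training configuration with named presets
#'
#' Two presets are shipped. `"full"` is the full-scale protocol: 299 px
#' inputs; stage 1 trains the branch heads for 5 epochs with the backbone
#' frozen (Adam, learning rate 1e-4, epsilon 0.1); stage 2 then unfreezes
#' backbone blocks step by step, last blocks first, one block per step,
#' 20 epochs per step, learning rates descending geometrically from 1e-4
#' to 1e-6. `"desk"` is a small-compute profile for synthetic data and
#' continuous testing: 96 px inputs, a narrower backbone
#' (16-32-64-64 channels, 128/64-wide heads), 2 unfreeze steps of 8 epochs,
#' and — because the desk model trains from random initialization rather
#' than from a pretrained backbone — a larger learning rate (1e-3,
#' standard Adam epsilon).
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... Named overrides of any config field.
#' @return A `train_config` list with fields `input_size`, `batch_size`,
#'   `gamma`, `weights`, `augment`, `stage1` (epochs, lr, adam_eps),
#'   `stage2` (steps, epochs_per_step, lr_start, lr_end), `backbone`,
#'   `heads`, `seed`.
#' @export
train_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "full") {
    list(preset = "full", input_size = 299L, batch_size = 32L,
         gamma = 2, weights = level_weights(0.3),
         augment = augment_config(),
         stage1 = list(epochs = 5L, lr = 1e-4, adam_eps = 0.1),
         stage2 = list(steps = 4L, epochs_per_step = 20L,
                       lr_start = 1e-4, lr_end = 1e-6),
         backbone = backbone_spec(), heads = head_config(), seed = 1L)
  } else {
    list(preset = "desk", input_size = 96L, batch_size = 32L,
         gamma = 2, weights = level_weights(0.3),
         augment = augment_config(),
         stage1 = list(epochs = 5L, lr = 1e-3, adam_eps = 1e-8),
         stage2 = list(steps = 2L, epochs_per_step = 8L,
                       lr_start = 1e-3, lr_end = 1e-4),
         backbone = backbone_spec(channels = c(16, 32, 64, 64)),
         heads = head_config(hidden = c(128, 64)), seed = 1L)
  }
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
          !inherits(over[[nm]], c("level_weights", "augment_config",
                                  "backbone_spec", "head_config"))) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  lrs <- stage_lrs(cfg$stage2)
  if (cfg$stage2$steps > 1 && any(diff(lrs) >= 0)) {
    stopf("config error: stage-2 learning rates must be strictly decreasing")
  }
  if (cfg$stage1$epochs < 1) stopf("config error: epochs must be >= 1")
  structure(cfg, class = "train_config")
}

# Geometric interpolation between the stage-2 endpoint learning rates.
stage_lrs <- function(stage2) {
  S <- stage2$steps
  if (S == 1) return(stage2$lr_start)
  exp(seq(log(stage2$lr_start), log(stage2$lr_end), length.out = S))
}

# Epoch-by-epoch schedule implied by a train_config: stage-1 epochs at the
# frozen-backbone learning rate, then each stage-2 unfreeze step at its
# geometrically interpolated rate.
training_plan <- function(config) {
  plan <- data.frame(stage = rep(1L, config$stage1$epochs), step = 0L,
                     lr = config$stage1$lr)
  lrs <- stage_lrs(config$stage2)
  for (s in seq_len(config$stage2$steps)) {
    plan <- rbind(plan, data.frame(stage = 2L, step = s,
                                   lr = rep(lrs[s],
                                            config$stage2$epochs_per_step)))
  }
  plan
}

# Which backbone blocks train during stage-2 step s of S (last blocks
# first, the first layers unfrozen last).
unfrozen_blocks <- function(nb, s, S) {
  n_open <- ceiling(nb * s / S)
  seq(nb - n_open + 1L, nb)
}

# Recursive Adam update over the nested parameter list; `grads` leaves may
# be NULL (frozen / not computed), which leaves both the parameter and its
# moment state untouched.
adam_update <- function(params, grads, state, lr, eps, t,
                        b1 = 0.9, b2 = 0.999) {
  if (is.numeric(params)) {
    if (is.null(grads)) return(list(p = params, s = state))
    r <- adam_step_leaf(params, grads, state, lr, b1, b2, eps, t)
    return(list(p = r$p, s = r$s))
  }
  for (nm in seq_along(params)) {
    r <- adam_update(params[[nm]], grads[[nm]], state[[nm]], lr, eps, t,
                     b1, b2)
    params[[nm]] <- r$p
    state[[nm]] <- r$s
  }
  list(p = params, s = state)
}

mask_conv_grads <- function(grads, trainable_blocks) {
  for (i in seq_along(grads$conv)) {
    if (!(i %in% trainable_blocks)) grads$conv[i] <- list(NULL)
  }
  grads
}

#' Train a model with the staged fine-tuning schedule
#'
#' Stage 1 trains only the branch heads with every backbone block frozen;
#' stage 2 unfreezes backbone blocks in steps (last blocks first) at
#' geometrically decreasing learning rates. Labels are expanded upward
#' through the model's taxonomy; the multi-level focal loss
#' (`total_loss` over per-level `level_loss`) is minimized with Adam.
#'
#' @param model A `hier_model` (hierarchical or flat).
#' @param manifest Training manifest data frame.
#' @param config A [train_config()].
#' @param images Optional preloaded image array matching the manifest
#'   (loaded from `attr(manifest, "dir")` when omitted).
#' @param validation Optional list(images, manifest) evaluated (loss only)
#'   after every epoch.
#' @param checkpoint_dir Optional directory; when given, a checkpoint is
#'   saved after stage 1 (`stage1.rds`) and after every stage-2 step
#'   (`stage2_step<k>.rds`).
#' @return List with `model` (trained) and `log`: one row per epoch with
#'   stage, step, learning rate, per-level and total training loss,
#'   validation loss (or NA) and the trainable parameter groups.
#' @export
train_model <- function(model, manifest, config = train_config("desk"),
                        images = NULL, validation = NULL,
                        checkpoint_dir = NULL) {
  if (nrow(manifest) == 0) stopf("data error: empty training manifest")
  if (is.null(images)) images <- load_images(manifest)
  labels <- lapply(manifest_labels(manifest), function(ids) {
    tryCatch(expand_labels(model$taxonomy, ids),
             error = function(e) stopf("data error: %s", conditionMessage(e)))
  })
  Y <- label_matrices(model$taxonomy, labels)
  Y1t <- t(Y[[1]]); Y2t <- t(Y[[2]])
  val <- NULL
  if (!is.null(validation)) {
    vl <- label_matrices(model$taxonomy,
                         lapply(manifest_labels(validation$manifest),
                                expand_labels, tax = model$taxonomy))
    val <- list(images = validation$images, Y1t = t(vl[[1]]), Y2t = t(vl[[2]]))
  }
  N <- nrow(manifest)
  nb <- length(model$params$conv)
  w <- as.numeric(config$weights)
  gamma <- config$gamma
  state <- adam_init(model$params)
  t_step <- 0L

  plan <- training_plan(config)

  log_rows <- vector("list", nrow(plan))
  with_seed(config$seed, {
    for (e in seq_len(nrow(plan))) {
      stage <- plan$stage[e]; step <- plan$step[e]; lr <- plan$lr[e]
      trainable <- if (stage == 1L) integer(0) else {
        unfrozen_blocks(nb, step, config$stage2$steps)
      }
      stop_blk <- if (length(trainable)) min(trainable) else nb + 1L
      perm <- sample.int(N)
      batch_starts <- seq(1, N, by = config$batch_size)
      tot <- l1s <- l2s <- 0
      for (bs in batch_starts) {
        idx <- perm[bs:min(bs + config$batch_size - 1, N)]
        xb <- images[, , , idx, drop = FALSE]
        xb <- augment_batch(xb, config$augment)
        fw <- forward_internal(model, xb, keep_cache = TRUE)
        y1 <- Y1t[, idx, drop = FALSE]; y2 <- Y2t[, idx, drop = FALSE]
        l1 <- level_loss(fw$p1, y1, gamma); l2 <- level_loss(fw$p2, y2, gamma)
        dZ1 <- w[1] * level_loss_grad(fw$p1, y1, gamma) * fw$p1 * (1 - fw$p1)
        dZ2 <- w[2] * level_loss_grad(fw$p2, y2, gamma) * fw$p2 * (1 - fw$p2)
        bw <- backward_internal(model, fw, dZ1, dZ2,
                                stop_at_block = stop_blk)
        grads <- mask_conv_grads(bw$grads, trainable)
        t_step <- t_step + 1L
        upd <- adam_update(model$params, grads, state, lr,
                           config$stage1$adam_eps, t_step)
        model$params <- upd$p
        state <- upd$s
        nb_frac <- length(idx) / N
        tot <- tot + total_loss(c(l1, l2), config$weights) * nb_frac
        l1s <- l1s + l1 * nb_frac; l2s <- l2s + l2 * nb_frac
      }
      val_loss <- NA_real_
      if (!is.null(val)) {
        vf <- forward_internal(model, val$images, keep_cache = FALSE)
        val_loss <- total_loss(c(level_loss(vf$p1, val$Y1t, gamma),
                                 level_loss(vf$p2, val$Y2t, gamma)),
                               config$weights)
      }
      log_rows[[e]] <- data.frame(
        epoch = e, stage = stage, step = step, lr = lr,
        loss_total = tot, loss_l1 = l1s, loss_l2 = l2s,
        val_loss = val_loss,
        trainable = paste(c("heads", if (length(trainable))
          paste0("block", trainable)), collapse = "+"),
        stringsAsFactors = FALSE)
      if (!is.null(checkpoint_dir) &&
            (e == nrow(plan) || plan$stage[e + 1] != stage ||
               plan$step[e + 1] != step)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        fname <- if (stage == 1L) "stage1.rds" else
          sprintf("stage2_step%d.rds", step)
        save_model(model, file.path(checkpoint_dir, fname))
      }
    }
  })
  list(model = model, log = do.call(rbind, log_rows))
}
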