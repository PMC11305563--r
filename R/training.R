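# Minimal CPU training loop exercising the architecture end to end on
# synthetic data. Positive assignment is center-cell: each ground truth is
# assigned to the pyramid level whose stride best matches its box size and
# to the single cell containing its box center. The composite loss is
# distributional box regression (cross-entropy over the side-distance
# bins), binary cross-entropy for the class score, an OKS-kernel keypoint
# location term (1 - exp(-d^2 / (2 s^2 k^2)) per visible keypoint), and
# binary cross-entropy for keypoint visibility.

#' Training configuration
#'
#' Defaults follow the study's schedule: SGD with momentum 0.937 and weight
#' decay 5e-4, initial learning rate 0.01 decaying linearly to 1e-4, a
#' 3-epoch warm-up during which bias-like parameters start from 0.1,
#' batch size 32, and mosaic augmentation disabled for the final 10 epochs.
#'
#' @param epochs total training epochs.
#' @param lr0,lr_final initial and final learning rates.
#' @param warmup_epochs,warmup_bias_lr warm-up length and the bias-group
#'   starting rate.
#' @param momentum,weight_decay SGD momentum and decoupled weight decay
#'   (applied to convolution weights only).
#' @param batch_size images per optimization step.
#' @param close_mosaic_epochs final epochs with mosaic augmentation off.
#' @param mosaic enable mosaic-style 4-image composition.
#' @param mosaic_prob per-sample probability of replacing an image by a
#'   mosaic while the augmentation is active.
#' @param gains named loss weights (`cls`, `dfl`, `kpt`, `kvis`).
#' @param seed RNG seed controlling shuffling, mosaic and initialization
#'   downstream.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, lr0 = 0.01, lr_final = 1e-4,
                         warmup_epochs = 3L, warmup_bias_lr = 0.1,
                         momentum = 0.937, weight_decay = 5e-4,
                         batch_size = 32L, close_mosaic_epochs = 10L,
                         mosaic = TRUE, mosaic_prob = 0.3,
                         gains = c(cls = 0.5, dfl = 1.5, kpt = 12,
                                   kvis = 1),
                         seed = 0L) {
  if (lr_final > lr0) stop("lr_final must not exceed lr0")
  if (warmup_epochs >= epochs) stop("warmup_epochs must be below epochs")
  structure(list(epochs = as.integer(epochs), lr0 = lr0,
                 lr_final = lr_final,
                 warmup_epochs = as.integer(warmup_epochs),
                 warmup_bias_lr = warmup_bias_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 close_mosaic_epochs = as.integer(close_mosaic_epochs),
                 mosaic = isTRUE(mosaic), mosaic_prob = mosaic_prob,
                 gains = gains,
                 seed = as.integer(seed)), class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear warm-up over the first `warmup_epochs` (weight groups ramp from
#' 0, bias-like groups from `warmup_bias_lr`, both reaching `lr0`), then
#' linear decay from `lr0` to `lr_final` at the final epoch. Monotone
#' non-increasing after warm-up.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param config a [train_config()].
#' @param group `"weights"` or `"bias"`.
#' @return the learning rate for that epoch and group.
#' @export
lr_schedule <- function(epoch, config, group = c("weights", "bias")) {
  group <- match.arg(group)
  if (epoch < 0 || epoch >= config$epochs) stop("epoch out of range")
  we <- config$warmup_epochs
  if (epoch < we) {
    start <- if (group == "bias") config$warmup_bias_lr else 0
    return(start + (config$lr0 - start) * epoch / we)
  }
  span <- max(1L, config$epochs - 1L - we)
  config$lr0 + (config$lr_final - config$lr0) * (epoch - we) / span
}

# ---- target assignment (center cell) --------------------------------------

# Choose, per ground truth, the level whose stride best matches the box
# size, and the cell containing the box center.
assign_targets <- function(gts, strides, grid_hw, reg_max) {
  lapply(seq_along(gts), function(gi) {
    g <- gts[[gi]]
    side <- max(g$box[3], g$box[4])
    lev <- which.min(abs(log2(pmax(side, 1) / (4 * strides))))
    s <- strides[lev]
    hw <- grid_hw[[lev]]
    cx <- g$box[1] + g$box[3] / 2
    cy <- g$box[2] + g$box[4] / 2
    gx <- min(max(floor(cx / s), 0), hw[2] - 1)
    gy <- min(max(floor(cy / s), 0), hw[1] - 1)
    ltrb <- c((gx + 0.5) - g$box[1] / s,
              (gy + 0.5) - g$box[2] / s,
              (g$box[1] + g$box[3]) / s - (gx + 0.5),
              (g$box[2] + g$box[4]) / s - (gy + 0.5))
    ltrb <- pmin(pmax(ltrb, 0.01), reg_max - 1.01)
    list(level = lev, gx = gx, gy = gy, ltrb = ltrb, gt = g, stride = s)
  })
}

# Compute the composite loss and the gradient seeds for the raw head
# outputs of one batch. `gts_batch` is a list (per image) of lists of
# keypoint_instance.
pose_loss <- function(pred, gts_batch, gains, kcfg = oks_config()) {
  strides <- attr(pred, "strides")
  reg_max <- attr(pred, "reg_max")
  nk <- attr(pred, "num_keypoints")
  nlev <- length(pred)
  dims <- lapply(pred, function(lv) dim(node_value(lv$box)))
  grid_hw <- lapply(dims, function(d) d[2:3])
  nb <- dims[[1]][4]
  cls_g <- lapply(pred, function(lv) array(0, dim(node_value(lv$cls))))
  box_g <- lapply(pred, function(lv) array(0, dim(node_value(lv$box))))
  kpt_g <- lapply(pred, function(lv) array(0, dim(node_value(lv$kpt))))
  npos <- max(1L, sum(lengths(gts_batch)))
  loss_cls <- 0; loss_dfl <- 0; loss_kpt <- 0; loss_kvis <- 0
  ncell_total <- sum(vapply(dims, function(d) d[2] * d[3], numeric(1))) * nb
  # class BCE over every cell (positives marked below)
  cls_t <- lapply(dims, function(d) array(0, c(1, d[2], d[3], d[4])))
  per_image <- lapply(seq_len(nb), function(n) {
    assign_targets(gts_batch[[n]], strides, grid_hw, reg_max)
  })
  for (n in seq_len(nb)) {
    for (tg in per_image[[n]]) {
      cls_t[[tg$level]][1, tg$gy + 1, tg$gx + 1, n] <- 1
    }
  }
  for (l in seq_len(nlev)) {
    z <- node_value(pred[[l]]$cls)
    p <- sigmoid_(z)
    t <- cls_t[[l]]
    loss_cls <- loss_cls +
      sum(-(t * log(pmax(p, 1e-12)) + (1 - t) * log(pmax(1 - p, 1e-12))))
    cls_g[[l]] <- (p - t) / npos
  }
  loss_cls <- loss_cls / npos
  nvis_total <- 0
  for (n in seq_len(nb)) {
    for (tg in per_image[[n]]) {
      l <- tg$level; s <- tg$stride
      bx <- node_value(pred[[l]]$box)
      # distributional regression: CE between the softmax over bins and
      # the two-bin interpolation of the continuous distance
      for (side in 1:4) {
        idx <- ((side - 1) * reg_max + 1):(side * reg_max)
        zlog <- bx[idx, tg$gy + 1, tg$gx + 1, n]
        sm <- exp(zlog - max(zlog)); sm <- sm / sum(sm)
        tval <- tg$ltrb[side]
        fl <- floor(tval); wr <- tval - fl
        tdist <- numeric(reg_max)
        tdist[fl + 1] <- 1 - wr
        if (fl + 2 <= reg_max) tdist[fl + 2] <- wr
        loss_dfl <- loss_dfl + -sum(tdist * log(pmax(sm, 1e-12))) / npos
        box_g[[l]][idx, tg$gy + 1, tg$gx + 1, n] <-
          box_g[[l]][idx, tg$gy + 1, tg$gx + 1, n] + (sm - tdist) / npos
      }
      # keypoints
      kp <- node_value(pred[[l]]$kpt)[, tg$gy + 1, tg$gx + 1, n]
      gkp <- tg$gt$keypoints
      scl2 <- max(instance_scale(tg$gt), 2)^2
      vis <- gkp[, 3] > 0
      nvis_total <- nvis_total + sum(vis)
      for (j in seq_len(nk)) {
        base <- (j - 1) * 3
        zv <- kp[base + 3]
        pv <- sigmoid_(zv)
        tv <- as.numeric(vis[j])
        loss_kvis <- loss_kvis +
          (-(tv * log(max(pv, 1e-12)) +
               (1 - tv) * log(max(1 - pv, 1e-12)))) / npos
        kpt_g[[l]][base + 3, tg$gy + 1, tg$gx + 1, n] <-
          kpt_g[[l]][base + 3, tg$gy + 1, tg$gx + 1, n] + (pv - tv) / npos
        if (!vis[j]) next
        px <- (2 * kp[base + 1] + tg$gx) * s
        py <- (2 * kp[base + 2] + tg$gy) * s
        dx <- px - gkp[j, 1]; dy <- py - gkp[j, 2]
        # loss-side kernel widened (2k) so far-off predictions still carry
        # gradient, plus a small quadratic pull; evaluation OKS keeps k
        denom <- 2 * scl2 * (2 * kcfg$k[j])^2
        e <- (dx^2 + dy^2) / denom
        loss_kpt <- loss_kpt + (1 - exp(-e)) +
          0.05 * (dx^2 + dy^2) / scl2
        coef <- exp(-e) * 2 / denom + 0.05 * 2 / scl2
        kpt_g[[l]][base + 1, tg$gy + 1, tg$gx + 1, n] <-
          kpt_g[[l]][base + 1, tg$gy + 1, tg$gx + 1, n] +
          coef * dx * 2 * s
        kpt_g[[l]][base + 2, tg$gy + 1, tg$gx + 1, n] <-
          kpt_g[[l]][base + 2, tg$gy + 1, tg$gx + 1, n] +
          coef * dy * 2 * s
      }
    }
  }
  if (nvis_total > 0) {
    loss_kpt <- loss_kpt / nvis_total
    for (l in seq_len(nlev)) {
      xy_idx <- as.vector(sapply(seq_len(nk) - 1, function(j) {
        3 * j + 1:2
      }))
      kpt_g[[l]][xy_idx, , , ] <- kpt_g[[l]][xy_idx, , , ] / nvis_total
    }
  }
  total <- gains[["cls"]] * loss_cls + gains[["dfl"]] * loss_dfl +
    gains[["kpt"]] * loss_kpt + gains[["kvis"]] * loss_kvis
  seeds <- list()
  for (l in seq_len(nlev)) {
    if (is_node(pred[[l]]$cls)) {
      seeds <- c(seeds, list(
        list(node = pred[[l]]$cls, grad = gains[["cls"]] * cls_g[[l]]),
        list(node = pred[[l]]$box, grad = gains[["dfl"]] * box_g[[l]]),
        list(node = pred[[l]]$kpt,
             grad = {
               km <- kpt_xy_mask(dim(kpt_g[[l]]), nk)
               gains[["kpt"]] * kpt_g[[l]] * km +
                 gains[["kvis"]] * kpt_g[[l]] * (1 - km)
             })))
    }
  }
  list(total = total,
       breakdown = c(cls = loss_cls, dfl = loss_dfl, kpt = loss_kpt,
                     kvis = loss_kvis),
       seeds = seeds)
}

kpt_xy_mask <- function(d, nk) {
  m <- rep(c(1, 1, 0), nk)
  array(m, d)
}

# ---- mosaic ---------------------------------------------------------------

# Compose four images into one at half scale (2x2 grid), transforming the
# annotations accordingly.
mosaic_sample <- function(samples, size) {
  img <- array(0, c(size, size, 3))
  gts <- list()
  half <- size %/% 2L
  offs <- list(c(0, 0), c(0, half), c(half, 0), c(half, half))
  for (q in 1:4) {
    s <- samples[[q]]
    src <- s$image
    sh <- dim(src)[1]
    idx <- pmin(pmax(round(seq(1, sh, length.out = half)), 1L), sh)
    small <- src[idx, idx, , drop = FALSE]
    oy <- offs[[q]][1]; ox <- offs[[q]][2]
    img[(oy + 1):(oy + half), (ox + 1):(ox + half), ] <- small
    f <- half / sh
    for (g in s$gts) {
      kp <- g$keypoints
      kp[, 1] <- kp[, 1] * f + ox
      kp[, 2] <- kp[, 2] * f + oy
      gts <- c(gts, list(keypoint_instance(
        c(g$box[1] * f + ox, g$box[2] * f + oy, g$box[3] * f, g$box[4] * f),
        1, kp)))
    }
  }
  list(image = img, gts = gts)
}

# ---- optimizer ------------------------------------------------------------

sgd_step <- function(params, velocities, lr_w, lr_b, momentum, wd) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    is_weight <- length(dim(p$value)) >= 2L
    g <- p$grad
    if (is_weight && wd > 0) g <- g + wd * p$value
    key <- as.character(p$id)
    v <- velocities[[key]]
    v <- if (is.null(v)) g else momentum * v + g
    velocities[[key]] <- v
    p$value <- p$value - (if (is_weight) lr_w else lr_b) * v
  }
  invisible(NULL)
}

# ---- checkpoints -----------------------------------------------------------

collect_bn_states <- function(m) {
  out <- list()
  for (f in c("bn", "bn1", "bn3", "bnid")) {
    if (!is.null(m[[f]])) out <- c(out, list(m[[f]]))
  }
  for (ch in m$children) out <- c(out, collect_bn_states(ch))
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the configuration, all parameter values, batch-norm
#' running statistics and the fused/multibranch state; they restore onto a
#' model built from the same configuration.
#'
#' @param model a pose model.
#' @param path file path (RDS serialization).
#' @rdname checkpoint
#' @export
save_checkpoint <- function(model, path) {
  params <- module_params(model$root)
  bns <- collect_bn_states(model$root)
  saveRDS(list(cfg = model$cfg,
               reparameterized = model$reparameterized,
               values = lapply(params, function(p) p$value),
               bn = lapply(bns, function(s) {
                 list(mean = s$running_mean, var = s$running_var)
               })), path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  if (isTRUE(ck$reparameterized) && !model$reparameterized) {
    reparameterize_network(model)
  }
  params <- module_params(model$root)
  if (length(params) != length(ck$values)) {
    stop("checkpoint does not match the model architecture")
  }
  for (i in seq_along(params)) params[[i]]$value <- ck$values[[i]]
  bns <- collect_bn_states(model$root)
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- ck$bn[[i]]$mean
    bns[[i]]$running_var <- ck$bn[[i]]$var
  }
  invisible(model)
}

#' Build a model from a checkpoint file
#' @param path checkpoint path.
#' @export
model_from_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  load_checkpoint(model, path)
  model
}

# ---- evaluation wrapper ----------------------------------------------------

#' Evaluate a model on an in-memory dataset
#'
#' @param model a pose model.
#' @param data list of samples (as from [load_dataset()]).
#' @param conf_threshold,iou_threshold decoding thresholds.
#' @param kcfg an [oks_config()].
#' @param factor_tags use the samples' factor tags for stratified results?
#' @return a `pose_eval`.
#' @export
evaluate_model <- function(model, data, conf_threshold = 0.25,
                           iou_threshold = 0.5, kcfg = oks_config(),
                           factor_tags = FALSE) {
  ds <- lapply(data, function(s) {
    list(gts = s$gts,
         preds = predict_instances(model, s$image, conf_threshold,
                                   iou_threshold))
  })
  tags <- if (factor_tags) lapply(data, `[[`, "tags") else NULL
  evaluate_poses(ds, kcfg, factor_tags = tags)
}

# ---- training loop ---------------------------------------------------------

#' Train a pose model on synthetic data
#'
#' @param model a pose model in multibranch (training) topology.
#' @param data list of training samples, each `list(image, gts)` (as from
#'   [load_dataset()]).
#' @param config a [train_config()].
#' @param val_data optional validation samples; AP_0.5 is logged per epoch
#'   and the best-AP_0.5 parameters are kept.
#' @param checkpoint_path optional path; the best (or last) checkpoint is
#'   written there.
#' @param verbose print a line per epoch?
#' @return list with `log` (per-epoch data.frame), `best_ap50`,
#'   `best_epoch`; the model is left holding the final-epoch weights unless
#'   `restore_best` found a better earlier epoch.
#' @export
train_pose <- function(model, data, config = train_config(),
                       val_data = NULL, checkpoint_path = NULL,
                       verbose = FALSE) {
  stopifnot(length(data) > 0)
  if (model$reparameterized) {
    stop("state error: cannot train a reparameterized model")
  }
  set.seed(config$seed)
  set_training(model, TRUE)
  params <- module_params(model$root)
  velocities <- new.env(parent = emptyenv())
  log <- NULL
  best_ap50 <- -Inf
  best_epoch <- NA_integer_
  best_file <- if (!is.null(checkpoint_path)) checkpoint_path else NULL
  n <- length(data)
  for (epoch in seq_len(config$epochs) - 1L) {
    mosaic_on <- config$mosaic &&
      epoch < config$epochs - config$close_mosaic_epochs
    lr_w <- lr_schedule(epoch, config, "weights")
    lr_b <- lr_schedule(epoch, config, "bias")
    ord <- sample.int(n)
    epoch_loss <- 0
    bits <- c(cls = 0, dfl = 0, kpt = 0, kvis = 0)
    nsteps <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(n, start + config$batch_size - 1L)]
      batch <- lapply(idx, function(i) {
        if (mosaic_on && runif(1) < config$mosaic_prob) {
          mosaic_sample(data[sample.int(n, 4, replace = TRUE)],
                        dim(data[[i]]$image)[1])
        } else {
          data[[i]]
        }
      })
      xb <- array(0, c(3, dim(batch[[1]]$image)[1:2], length(batch)))
      for (b in seq_along(batch)) {
        xb[, , , b] <- image_to_input(batch[[b]]$image)[, , , 1]
      }
      res <- with_grad({
        pred <- forward_model(model, xb, training = TRUE)
        ls <- pose_loss(pred, lapply(batch, `[[`, "gts"), config$gains)
        cp_backward(ls$seeds)
        ls
      })
      if (!is.finite(res$total)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (components: ",
             paste(sprintf("%s=%.3g", names(res$breakdown), res$breakdown),
                   collapse = ", "), ")")
      }
      sgd_step(params, velocities, lr_w, lr_b, config$momentum,
               config$weight_decay)
      cp_zero_grad(params)
      epoch_loss <- epoch_loss + res$total
      bits <- bits + res$breakdown
      nsteps <- nsteps + 1L
    }
    ap50 <- NA_real_
    if (!is.null(val_data)) {
      set_training(model, FALSE)
      ev <- evaluate_model(model, val_data)
      ap50 <- ev$ap50
      set_training(model, TRUE)
      if (ap50 > best_ap50) {
        best_ap50 <- ap50
        best_epoch <- epoch
        if (!is.null(best_file)) save_checkpoint(model, best_file)
      }
    }
    log <- rbind(log, data.frame(
      epoch = epoch, loss = epoch_loss / nsteps,
      cls = bits[["cls"]] / nsteps, dfl = bits[["dfl"]] / nsteps,
      kpt = bits[["kpt"]] / nsteps, kvis = bits[["kvis"]] / nsteps,
      lr = lr_w, mosaic = mosaic_on, val_ap50 = ap50))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  lr %.5f  ap50 %s", epoch,
                      epoch_loss / nsteps, lr_w,
                      ifelse(is.na(ap50), "-", sprintf("%.3f", ap50))))
    }
  }
  set_training(model, FALSE)
  if (is.null(val_data) && !is.null(checkpoint_path)) {
    save_checkpoint(model, checkpoint_path)
  }
  list(log = log, best_ap50 = best_ap50, best_epoch = best_epoch)
}
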