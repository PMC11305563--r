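test_that("backbone taps follow the stride contract and reject bad sizes", {
  set.seed(1)
  bb <- build_backbone(toy_model_config())
  x <- array(rnorm(3 * 64 * 64 * 1), c(3, 64, 64, 1))
  f <- bb$forward(x, training = FALSE)
  expect_equal(dim(f$P3)[2:3], c(8L, 8L))
  expect_equal(dim(f$P4)[2:3], c(4L, 4L))
  expect_equal(dim(f$P5)[2:3], c(2L, 2L))
  bad <- array(0, c(3, 63, 63, 1))
  expect_error(bb$forward(bad, training = FALSE), "divisible by 32")
  expect_error(bb$trace(641), "divisible by 32")
  # stride arithmetic at the full input size, via the shape trace
  tr <- bb$trace(640)
  expect_equal(tr$shapes$P3[2:3], c(80, 80))
  expect_equal(tr$shapes$P4[2:3], c(40, 40))
  expect_equal(tr$shapes$P5[2:3], c(20, 20))
})

test_that("parameter counting is exact on a closed-form case", {
  m <- conv_plain(3, 16, 3)
  expect_equal(count_parameters(m), 16 * 3 * 9 + 16)
  expect_equal(count_flops(m, 640), 2 * (16 * 3 * 9) * 640^2 / 1e9,
               tolerance = 1e-12)
})

test_that("architecture statistics reproduce the printed model budgets", {
  set.seed(2)
  baseline <- build_model(baseline_config())
  expect_equal(count_parameters(baseline), 3274403)
  expect_equal(round(count_parameters(baseline) / 1e6, 2), 3.27)
  gb <- count_flops(baseline, 640)
  expect_equal(round(gb, 1), 9.1)

  with_att <- build_model(model_config(neck = "pan_baseline"))
  expect_identical(count_parameters(with_att), count_parameters(baseline))

  improved <- build_model(model_config())
  reparameterize_network(improved)
  expect_equal(round(count_parameters(improved) / 1e6, 2), 3.11)
  gi <- count_flops(improved, 640)
  expect_equal(round(gi, 1), 8.1)

  # printed deltas: -0.16 M parameters and -1.0 GFLOPs
  expect_equal(round(count_parameters(baseline) / 1e6, 2) -
                 round(count_parameters(improved) / 1e6, 2), 0.16)
  expect_equal(round(gb - gi, 1), 1.0)
})

test_that("bidirectional fusion enforces and preserves the stride contract", {
  set.seed(3)
  blk <- bifusion_block(8, 12, 6, 16)
  deep <- array(rnorm(8 * 4 * 4 * 1), c(8, 4, 4, 1))
  cur <- array(rnorm(12 * 8 * 8 * 1), c(12, 8, 8, 1))
  shal <- array(rnorm(6 * 16 * 16 * 1), c(6, 16, 16, 1))
  out <- blk$forward(deep, cur, shal, training = FALSE)
  expect_equal(dim(out), c(16L, 8L, 8L, 1L))   # current's stride kept
  expect_error(blk$forward(cur, cur, shal, FALSE), "shape error")

  # linearity: with zero inputs and zero shift terms the output is zero,
  # whatever the convolution weights are
  z <- list(array(0, dim(deep)), array(0, dim(cur)), array(0, dim(shal)))
  y1 <- blk$forward(z[[1]], z[[2]], z[[3]], FALSE)
  expect_true(all(y1 == 0))
  for (p in cattlepose:::module_params(blk)) {
    if (length(dim(p$value)) >= 2) p$value <- p$value + rnorm(length(p$value))
  }
  y2 <- blk$forward(z[[1]], z[[2]], z[[3]], FALSE)
  expect_true(all(y2 == 0))

  # channel bookkeeping: the fused concat carries 3 * out_channels
  expect_equal(blk$cv_out$cin, 3L * 16L)
  f <- bifusion(deep, cur, shal, out_channels = 16)
  expect_equal(dim(f)[1], 16L)
})

test_that("the neck needs its backbone taps", {
  cfg <- toy_model_config()
  expect_error(build_neck(cfg, c(P3 = 16L, P4 = 32L, P5 = 64L)),
               "P2 tap")
  expect_error(build_neck(cfg, c(P2 = 8L)), "P3/P4/P5")
})

test_that("head grid and field sizes follow the contract", {
  cfg <- model_config()
  set.seed(4)
  bb <- build_backbone(cfg)
  tr <- bb$trace(640)
  cells <- sum(vapply(tr$shapes[c("P3", "P4", "P5")],
                      function(s) s[2] * s[3], numeric(1)))
  expect_equal(cells, 8400)
  hd <- build_head(cfg, c(48L, 128L, 256L))
  expect_equal(hd$kpt[[1]][[3]]$cout, 48L)  # 16 keypoints x 3 values
  expect_equal(hd$box[[1]][[3]]$cout, 64L)  # 4 sides x 16 bins
})

test_that("head output shapes are invariant under neck reparameterization", {
  set.seed(5)
  model <- build_model(toy_model_config())
  x <- array(rnorm(3 * 64 * 64 * 1), c(3, 64, 64, 1))
  d0 <- lapply(forward_model(model, x), function(l) lapply(l, dim))
  reparameterize_network(model)
  d1 <- lapply(forward_model(model, x), function(l) lapply(l, dim))
  expect_identical(d0, d1)
})

make_pred <- function(levels, strides, input_hw, reg_max = 16L, nk = 16L) {
  structure(levels, strides = strides, input_hw = input_hw,
            reg_max = reg_max, num_keypoints = nk,
            class = "cp_dense_prediction")
}

empty_level <- function(h, w, reg_max = 16L, nk = 16L) {
  list(box = array(0, c(4 * reg_max, h, w, 1)),
       cls = array(-20, c(1, h, w, 1)),
       kpt = array(0, c(3 * nk, h, w, 1)))
}

# place a box/keypoint target at one cell, with sharply peaked
# distribution logits encoding the ltrb side distances
encode_target <- function(level, gx, gy, ltrb, kpts_rel, score_logit = 6,
                          reg_max = 16L) {
  for (side in 1:4) {
    fl <- floor(ltrb[side]); wr <- ltrb[side] - fl
    idx <- (side - 1) * reg_max
    level$box[idx + fl + 1, gy + 1, gx + 1, 1] <- 20 * (1 - wr)
    if (fl + 2 <= reg_max) {
      level$box[idx + fl + 2, gy + 1, gx + 1, 1] <- 20 * wr
    }
  }
  level$cls[1, gy + 1, gx + 1, 1] <- score_logit
  for (j in seq_len(nrow(kpts_rel))) {
    level$kpt[(j - 1) * 3 + 1, gy + 1, gx + 1, 1] <- kpts_rel[j, 1]
    level$kpt[(j - 1) * 3 + 2, gy + 1, gx + 1, 1] <- kpts_rel[j, 2]
    level$kpt[(j - 1) * 3 + 3, gy + 1, gx + 1, 1] <- 10
  }
  level
}

test_that("decoding inverts an encoded ground truth to within one cell", {
  lv <- empty_level(8, 8)
  # gt box: center (30, 34), size 28 x 20, on the stride-8 level
  box <- c(16, 24, 28, 20)
  gx <- 3L; gy <- 4L   # cell containing the center
  s <- 8
  ltrb <- c((gx + 0.5) - box[1] / s, (gy + 0.5) - box[2] / s,
            (box[1] + box[3]) / s - (gx + 0.5),
            (box[2] + box[4]) / s - (gy + 0.5))
  kp_abs <- cbind(seq(18, 40, length.out = 16), seq(26, 42, length.out = 16))
  kp_rel <- cbind((kp_abs[, 1] / s - gx) / 2, (kp_abs[, 2] / s - gy) / 2)
  lv <- encode_target(lv, gx, gy, ltrb, kp_rel)
  pred <- make_pred(list(lv, empty_level(4, 4), empty_level(2, 2)),
                    c(8L, 16L, 32L), c(64L, 64L))
  out <- decode(pred, conf_threshold = 0.5, iou_threshold = 0.5)
  expect_length(out, 1)
  got <- out[[1]]
  cx <- got$box[1] + got$box[3] / 2
  cy <- got$box[2] + got$box[4] / 2
  expect_lt(abs(cx - 30), s)
  expect_lt(abs(cy - 34), s)
  expect_lt(max(abs(got$keypoints[, 1] - kp_abs[, 1])), 1e-6)
  expect_lt(max(abs(got$keypoints[, 2] - kp_abs[, 2])), 1e-6)
  expect_true(all(got$keypoints[, 3] == 2))
})

test_that("decoding applies confidence gating and non-maximum suppression", {
  lv <- empty_level(8, 8)
  kp <- cbind(rep(0, 16), rep(0, 16))
  lv <- encode_target(lv, 3L, 3L, c(2, 2, 2, 2), kp, score_logit = 6)
  lv <- encode_target(lv, 4L, 3L, c(3, 2, 1.5, 2), kp, score_logit = 5)
  pred <- make_pred(list(lv, empty_level(4, 4), empty_level(2, 2)),
                    c(8L, 16L, 32L), c(64L, 64L))
  expect_length(decode(pred, conf_threshold = 1.0), 0)
  # the two cells describe (almost) the same box: one survives
  out <- decode(pred, conf_threshold = 0.5, iou_threshold = 0.5)
  expect_length(out, 1)
  # scores sorted descending when suppression is disabled
  all_out <- decode(pred, conf_threshold = 0.5, iou_threshold = 0.9999)
  expect_length(all_out, 2)
  expect_true(all_out[[1]]$score >= all_out[[2]]$score)
})

test_that("decode results survive whole-model reparameterization", {
  set.seed(6)
  model <- build_model(toy_model_config())
  randomize_bn_stats(model)
  sc <- render_scene(scene_spec(image_size = 64, seed = 3))
  p0 <- predict_instances(model, sc$image, conf_threshold = 0.01)
  reparameterize_network(model)
  p1 <- predict_instances(model, sc$image, conf_threshold = 0.01)
  expect_equal(length(p0), length(p1))
  if (length(p0)) {
    for (i in seq_along(p0)) {
      expect_lt(max(abs(p0[[i]]$keypoints[, 1:2] - p1[[i]]$keypoints[, 1:2])),
                1e-3)
      expect_lt(max(abs(p0[[i]]$box - p1[[i]]$box)), 1e-3)
    }
  }
})

test_that("model configuration validates and round-trips through YAML", {
  expect_error(model_config(depth_multiple = 0), "positive")
  expect_error(model_config(simam_stages = "P9"), "subset")
  path <- tempfile(fileext = ".yaml")
  write_model_config(model_config(), path)
  cfg <- read_model_config(path)
  expect_equal(cfg$neck_widths, model_config()$neck_widths)
  expect_equal(cfg$simam_stages, c("P3", "P4", "P5"))
  expect_equal(cfg$depth_multiple, 1 / 3, tolerance = 1e-6)
})
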