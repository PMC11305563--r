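test_that("OKS matches analytic cases", {
  gt <- make_instance()
  expect_equal(oks(gt, gt), 1.0)

  # one visible keypoint at squared distance 2 s^2 k^2 -> exp(-1)
  cfg <- oks_config()
  vis <- c(2L, rep(0L, 15))
  g1 <- make_instance(vis = vis)
  s <- sqrt(g1$box[3] * g1$box[4])
  p1 <- g1
  p1$keypoints[1, 1] <- p1$keypoints[1, 1] + sqrt(2) * s * cfg$k[1]
  expect_equal(oks(g1, p1), exp(-1), tolerance = 1e-12)

  # two visible keypoints with exponents 0 and 1 -> (1 + e^-1) / 2
  vis2 <- c(2L, 2L, rep(0L, 14))
  g2 <- make_instance(vis = vis2)
  p2 <- g2
  p2$keypoints[2, 2] <- p2$keypoints[2, 2] + sqrt(2) * s * cfg$k[2]
  expect_equal(oks(g2, p2), (1 + exp(-1)) / 2, tolerance = 1e-12)

  # no visible ground-truth keypoints is undefined
  g0 <- make_instance(vis = rep(0L, 16))
  expect_error(oks(g0, g0), "undefined OKS")
})

test_that("OKS is rigid-translation invariant and scales with the object", {
  set.seed(1)
  gt <- make_instance()
  pred <- gt
  pred$keypoints[, 1:2] <- pred$keypoints[, 1:2] + rnorm(32, sd = 4)
  base <- oks(gt, pred)
  shift <- function(inst, dx, dy) {
    inst$keypoints[, 1] <- inst$keypoints[, 1] + dx
    inst$keypoints[, 2] <- inst$keypoints[, 2] + dy
    inst$box[1:2] <- inst$box[1:2] + c(dx, dy)
    inst
  }
  expect_equal(oks(shift(gt, 31, -17), shift(pred, 31, -17)), base,
               tolerance = 1e-12)
  magnify <- function(inst, f) {
    inst$keypoints[, 1:2] <- inst$keypoints[, 1:2] * f
    inst$box <- inst$box * f
    inst
  }
  expect_equal(oks(magnify(gt, 3), magnify(pred, 3)), base,
               tolerance = 1e-12)
})

test_that("matching is greedy by confidence with input-order tie-breaks", {
  gt <- make_instance()
  perfect <- gt
  m <- match_instances(list(gt), list(perfect))
  expect_equal(m$oks, 1.0)
  expect_equal(m$gt, 1L)

  # two predictions on one ground truth: the higher-score one claims it
  worse <- gt
  worse$keypoints[, 1] <- worse$keypoints[, 1] + 3
  worse$score <- 0.9
  best <- gt
  best$score <- 0.95
  m2 <- match_instances(list(gt), list(worse, best))
  expect_equal(m2$oks[m2$pred == 2], 1.0)
  expect_equal(m2$oks[m2$pred == 1], 0)
  expect_true(is.na(m2$gt[1]))

  # permuting equal-score predictions leaves the OKS multiset unchanged
  set.seed(2)
  gts <- list(make_instance(80, 80, 60), make_instance(200, 200, 70))
  preds <- jitter_predictions(gts, pseudo_pred_config(jitter_sigma = 3),
                              seed = 4)
  for (p in seq_along(preds)) preds[[p]]$score <- 0.8
  m_a <- match_instances(gts, preds)
  m_b <- match_instances(gts, rev(preds))
  expect_equal(sort(m_a$oks), sort(m_b$oks), tolerance = 1e-12)
})

test_that("ap_at counts the detections above threshold", {
  matches <- data.frame(pred = 1:10, gt = 1:10,
                        oks = c(0.9, 0.8, 0.7, 0.6, rep(0.2, 6)),
                        score = seq(1, 0.1, length.out = 10))
  expect_equal(ap_at(matches, 0.5), 0.4)
  perfect <- data.frame(pred = 1:3, gt = 1:3, oks = 1, score = 1)
  for (t in oks_thresholds()) expect_equal(ap_at(perfect, t), 1.0)
  expect_equal(ap_at(matches[0, ], 0.5), 0)
  expect_error(ap_at(matches, 0.3), "0.5")

  # non-increasing in t for random match sets
  set.seed(3)
  for (i in 1:10) {
    mm <- data.frame(pred = 1:20, gt = 1:20, oks = runif(20), score = 1)
    aps <- vapply(oks_thresholds(), function(t) ap_at(mm, t), numeric(1))
    expect_true(all(diff(aps) <= 0))
  }
})

test_that("the evaluation protocol pools detections over ten thresholds", {
  gt <- make_instance()
  ds <- list(list(gts = list(gt), preds = list(gt)),
             list(gts = list(gt), preds = list(gt)))
  ev <- evaluate_poses(ds)
  expect_equal(ev$ap50, 1.0)
  expect_equal(ev$ap50_95, 1.0)
  expect_equal(as.numeric(names(ev$ap_by_threshold)),
               seq(0.50, 0.95, by = 0.05))
  expect_length(ev$ap_by_threshold, 10)
  expect_identical(ev$ap50_95, mean(ev$ap_by_threshold))
})

test_that("factor-stratified evaluation filters by tags", {
  gt <- make_instance()
  miss <- gt
  miss$keypoints[, 1] <- miss$keypoints[, 1] + 1e4   # OKS ~ 0
  ds <- list(list(gts = list(gt), preds = list(gt)),
             list(gts = list(gt), preds = list(miss)))
  tags <- list(c("bright light", "side view"), c("dim light", "side view"))
  ev <- evaluate_poses(ds, factor_tags = tags)
  expect_equal(unname(ev$per_factor[["bright light"]]["ap50"]), 1.0)
  expect_equal(unname(ev$per_factor[["dim light"]]["ap50"]), 0.0)
  expect_equal(unname(ev$per_factor[["side view"]]["ap50"]), 0.5)
  expect_warning(
    evaluate_poses(ds, factor_tags = tags,
                   factor_levels = c("side view", "back view")),
    "back view")
})

test_that("mean OKS under Gaussian jitter matches its closed form", {
  # E[exp(-d^2 / (2 s^2 k^2))] = 1 / (1 + tau^2 / (s^2 k^2)) for
  # independent per-axis N(0, tau^2) errors
  set.seed(4)
  gt <- make_instance(150, 150, 120)
  s <- sqrt(gt$box[3] * gt$box[4])
  k <- 0.1
  tau <- s * k            # expectation 1/2
  n <- 2000
  vals <- replicate(n, oks(gt, jitter_predictions(
    list(gt), pseudo_pred_config(jitter_sigma = tau))[[1]]))
  se <- sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals) - 0.5), 3 * se)
})

test_that("evaluation reports serialize to JSON and text", {
  gt <- make_instance()
  ev <- evaluate_poses(list(list(gts = list(gt), preds = list(gt))))
  jf <- tempfile(fileext = ".json")
  tf <- tempfile(fileext = ".txt")
  write_eval_report(ev, jf, tf)
  j <- jsonlite::read_json(jf)
  expect_equal(j$ap50, 1.0)
  expect_true(any(grepl("AP_0.5", readLines(tf), fixed = TRUE)))
})
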