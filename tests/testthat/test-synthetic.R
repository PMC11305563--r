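test_that("sampled skeletons respect the template geometry", {
  sch <- cattle_keypoint_schema()
  inst <- sample_skeleton("side", "large", "standing", 320, seed = 1)
  kp <- inst$keypoints
  # all 16 keypoints inside the box
  expect_true(all(kp[, 1] >= inst$box[1] & kp[, 1] <= inst$box[1] + inst$box[3]))
  expect_true(all(kp[, 2] >= inst$box[2] & kp[, 2] <= inst$box[2] + inst$box[4]))
  # anatomical ordering (y grows downward): thigh root above knee above hoof
  for (leg in c("right front", "left front", "right hind", "left hind")) {
    th <- kp[match(paste(leg, "thigh root"), sch), 2]
    kn <- kp[match(paste(leg, "knee"), sch), 2]
    hf <- kp[match(paste(leg, "hoof"), sch), 2]
    expect_lt(th, kn)
    expect_lt(kn, hf)
  }
  # far-side limbs are labeled-but-occluded in side view
  expect_true(all(kp[grep("^left", sch), 3] == 1))
})

test_that("view geometry controls visibility flags", {
  sch <- cattle_keypoint_schema()
  back <- sample_skeleton("back", "large", "standing", 320, seed = 2)
  expect_equal(back$keypoints[match("head top", sch), 3], 1)
  front <- sample_skeleton("front", "large", "standing", 320, seed = 3)
  expect_equal(front$keypoints[match("head top", sch), 3], 2)
  expect_true(all(front$keypoints[grep("hind", sch), 3] == 1))
})

test_that("skeleton sampling is deterministic per seed", {
  a <- sample_skeleton("side", "small", "walking", 320, seed = 9)
  b <- sample_skeleton("side", "small", "walking", 320, seed = 9)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$box, b$box)
  c <- sample_skeleton("side", "small", "walking", 320, seed = 10)
  expect_false(identical(a$keypoints, c$keypoints))
})

test_that("rendered scenes agree with their annotations", {
  sc <- render_scene(scene_spec(image_size = 320, n_instances = 3, seed = 4))
  expect_length(sc$doc$instances, 3)
  expect_equal(dim(sc$image), c(320, 320, 3))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  for (inst in sc$doc$instances) {
    expect_lte(nrow(inst$keypoints), 16)
  }
  # every visible keypoint lies on its instance's rendered foreground
  for (i in seq_along(sc$instances)) {
    kp <- sc$instances[[i]]$keypoints
    vis <- kp[, 3] == 2
    px <- pmin(pmax(ceiling(kp[vis, 1]), 1), 320)
    py <- pmin(pmax(ceiling(kp[vis, 2]), 1), 320)
    expect_true(all(sc$masks[[i]][cbind(py, px)]))
  }
})

test_that("fence occluders flip covered keypoints to occluded", {
  base <- render_scene(scene_spec(image_size = 320, seed = 5))
  kp <- base$instances[[1]]$keypoints
  sch <- cattle_keypoint_schema()
  hoof_idx <- match("right front hoof", sch)
  expect_equal(kp[hoof_idx, 3], 2)
  bar_x <- kp[hoof_idx, 1] - 4
  occ <- render_scene(scene_spec(image_size = 320, seed = 5,
                                 occluders = list(c(bar_x, 8))))
  expect_equal(occ$instances[[1]]$keypoints[hoof_idx, 3], 1)
  # occluder outside the canvas is rejected
  expect_error(render_scene(scene_spec(image_size = 320, seed = 5,
                                       occluders = list(c(318, 8)))),
               "occluder outside image")
})

test_that("dim lighting darkens the rendered scene", {
  bright <- render_scene(scene_spec(image_size = 160, seed = 6,
                                    brightness = "bright"))
  dim_sc <- render_scene(scene_spec(image_size = 160, seed = 6,
                                    brightness = "dim"))
  expect_lt(mean(dim_sc$image), 0.55 * mean(bright$image))
})

test_that("scene generation is byte-deterministic per seed", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  m1 <- generate_dataset(4, seed = 7, out_dir = d1, image_size = 96)
  m2 <- generate_dataset(4, seed = 7, out_dir = d2, image_size = 96)
  expect_identical(m1$tags, m2$tags)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(file.path(d1, m1$json[i]), warn = FALSE),
                     readLines(file.path(d2, m2$json[i]), warn = FALSE))
    expect_identical(readBin(file.path(d1, m1$image[i]), "raw", 1e6),
                     readBin(file.path(d2, m2$image[i]), "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("factor mixture proportions are honored", {
  d <- file.path(tempdir(), "mix")
  man <- generate_dataset(12, seed = 8, out_dir = d, image_size = 96,
                          mixture = list(
                            scale = c(large = 0.5, small = 0.5),
                            brightness = c(bright = 0.5, dim = 0.5),
                            view = c(side = 1),
                            occlusion = c(unobstructed = 1)))
  tags <- strsplit(man$tags, ";")
  expect_equal(sum(vapply(tags, function(t) "bright light" %in% t,
                          logical(1))), 6)
  expect_equal(sum(vapply(tags, function(t) "dim light" %in% t,
                          logical(1))), 6)
  expect_true(all(man$n_instances >= 1 & man$n_instances <= 3))
  unlink(d, recursive = TRUE)
})

test_that("pseudo predictions drive the metric protocol as designed", {
  sc <- render_scene(scene_spec(image_size = 320, seed = 11))
  gt <- sc$instances[[1]]
  # no jitter, no drops: exact reproduction
  p0 <- jitter_predictions(list(gt), pseudo_pred_config(0, 0, 0.9))
  expect_equal(oks(gt, p0[[1]]), 1.0)
  expect_equal(p0[[1]]$score, 0.9)
  expect_equal(p0[[1]]$box, gt$box)
  # dropping every keypoint leaves nothing for OKS to stand on
  pd <- jitter_predictions(list(gt), pseudo_pred_config(0, 1, 0.9), seed = 1)
  expect_true(all(pd[[1]]$keypoints[, 3] == 0))
  expect_error(oks(pd[[1]], gt), "undefined OKS")
  expect_error(pseudo_pred_config(-1), "non-negative")
  expect_error(pseudo_pred_config(0, 2), "drop_probability")
  expect_error(pseudo_pred_config(0, 0, 0), "score")
})

test_that("the generate-convert-evaluate pipeline closes exactly", {
  d <- file.path(tempdir(), "pipe")
  man <- generate_dataset(4, seed = 12, out_dir = d, image_size = 128)
  data <- load_dataset(man, d)
  ds <- lapply(data, function(s) {
    list(gts = s$gts,
         preds = jitter_predictions(s$gts, pseudo_pred_config(0, 0, 0.9)))
  })
  ev <- evaluate_poses(ds, factor_tags = lapply(data, `[[`, "tags"))
  expect_equal(ev$ap50, 1.0)
  expect_equal(ev$ap50_95, 1.0)
  # the yolo text round-trips against the json annotations
  y <- read_yolo_txt(file.path(d, man$txt[1]))
  doc <- read_labelme(file.path(d, man$json[1]))
  expect_lt(max(abs(as.matrix(labelme_to_yolo(doc)) - as.matrix(y))), 1e-6)
  unlink(d, recursive = TRUE)
})
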