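# Procedural generator of cattle-like scenes with exact ground truth.
# Instances are flat-shaded quadruped silhouettes (torso ellipse, head
# disc, thick leg strokes) over a textured background; every keypoint is
# placed by the same parametric skeleton that drives the rendering, so
# annotations are exactly consistent with the drawn geometry. The
# generator emulates the study-data variation factors -- 1-3 animals per
# image, large/small scale, bright/dim light, front/side/back view,
# fence occlusion and edge truncation -- without attempting photorealism.

#' Sample a 16-keypoint cattle skeleton
#'
#' A parameterized quadruped template (body length/height, leg segments,
#' head offset) jittered per draw. Visibility follows view geometry:
#' far-side limbs in side view, the hindquarters in front view, and head/
#' neck/forequarters in back view are labeled-but-occluded (v = 1).
#'
#' @param view one of `"side"`, `"front"`, `"back"`.
#' @param scale `"large"` (instance height 45-75% of the image) or
#'   `"small"` (10-25%).
#' @param pose `"standing"`, `"walking"` or `"lying"`.
#' @param image_size square canvas edge in pixels.
#' @param seed optional integer; when given the draw is deterministic.
#' @return a [keypoint_instance()] with score 1; attributes `facing`
#'   (+1/-1) and `geom` carry the silhouette parameters used by
#'   [render_scene()].
#' @export
sample_skeleton <- function(view = c("side", "front", "back"),
                            scale = c("large", "small"),
                            pose = c("standing", "walking", "lying"),
                            image_size = 320L, seed = NULL) {
  view <- match.arg(view)
  scale <- match.arg(scale)
  pose <- match.arg(pose)
  if (!is.null(seed)) return(local_rng(seed, sample_skeleton(
    view, scale, pose, image_size)))
  frac <- if (scale == "large") runif(1, 0.45, 0.75) else runif(1, 0.10, 0.25)
  hpx <- frac * image_size             # instance height in pixels
  # canonical side-view template, unit body length, y down, ground at 0.90
  leg <- function(x0, dx, lean) {
    rbind(c(x0, 0.40), c(x0 + dx * 0.5 + lean, 0.64),
          c(x0 + dx + lean, 0.88))    # thigh root, knee, hoof
  }
  walk <- pose == "walking"
  lie <- pose == "lying"
  sway <- if (walk) 0.06 else 0
  tmpl <- rbind(
    "head top" = c(-0.16, -0.06),
    "neck" = c(0.00, 0.08),
    "spine" = c(0.45, 0.04),
    leg(0.14, 0.02, sway),             # right front
    leg(0.20, -0.02, -sway),           # left front
    "coccyx" = c(0.94, 0.06),
    leg(0.82, 0.03, -sway),            # right hind
    leg(0.88, -0.01, sway))            # left hind
  rownames(tmpl) <- cattle_keypoint_schema()
  if (lie) {
    legrows <- grep("thigh|knee|hoof", rownames(tmpl))
    tmpl[legrows, 2] <- 0.40 + 0.18 * (tmpl[legrows, 2] - 0.40) / 0.48
    tmpl[, 2] <- tmpl[, 2] + 0.30      # body sinks toward the ground
  }
  tmpl <- tmpl + matrix(rnorm(32, sd = 0.012), ncol = 2)
  v <- rep(2L, 16)
  sch <- cattle_keypoint_schema()
  if (view == "side") {
    v[grep("^left", sch)] <- 1L        # far-side limbs self-occluded
  } else {
    squeeze <- 0.30                    # body axis along the camera depth
    tmpl[, 1] <- 0.5 + (tmpl[, 1] - 0.5) * squeeze
    if (view == "front") {
      v[c(grep("hind", sch), which(sch == "coccyx"))] <- 1L
    } else {
      v[c(which(sch %in% c("head top", "neck")), grep("front", sch))] <- 1L
    }
  }
  facing <- sample(c(-1, 1), 1)
  if (facing < 0) tmpl[, 1] <- 1 - tmpl[, 1]  # mirror horizontally
  span <- 0.96                         # template height (head top to hoof)
  L <- hpx / span
  xr <- range(tmpl[, 1])
  wpx <- (xr[2] - xr[1]) * L
  x0 <- runif(1, 0.02 * image_size, max(0.03 * image_size,
                                        image_size - wpx - 0.02 * image_size))
  ytop <- runif(1, 0.02 * image_size, max(0.03 * image_size,
                                          image_size - hpx - 0.02 * image_size))
  pts <- cbind((tmpl[, 1] - xr[1]) * L + x0, (tmpl[, 2] + 0.06) * L + ytop)
  margin <- 0.03 * hpx
  lab <- v > 0
  box <- c(min(pts[lab, 1]) - margin, min(pts[lab, 2]) - margin,
           max(pts[lab, 1]) + margin, max(pts[lab, 2]) + margin)
  inst <- keypoint_instance(c(box[1], box[2], box[3] - box[1],
                              box[4] - box[2]), 1, cbind(pts, v))
  attr(inst, "facing") <- facing
  attr(inst, "geom") <- list(L = L, view = view, pose = pose)
  inst
}

#' Specification of one synthetic scene
#'
#' @param image_size square canvas edge in pixels.
#' @param n_instances number of cattle, 1 to 3.
#' @param brightness `"bright"` or `"dim"` (dim multiplies intensities by
#'   0.35 and adds sensor-like noise).
#' @param view,scale,pose factors passed to [sample_skeleton()].
#' @param occluders list of vertical fence bars, each `c(x, width)` pixels.
#' @param truncate push one instance partially off-canvas?
#' @param seed integer seed; the whole scene is deterministic given it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 320L, n_instances = 1L,
                       brightness = c("bright", "dim"),
                       view = c("side", "front", "back"),
                       scale = c("large", "small"),
                       pose = NULL, occluders = list(), truncate = FALSE,
                       seed = 0L) {
  brightness <- match.arg(brightness)
  view <- match.arg(view)
  scale <- match.arg(scale)
  if (!n_instances %in% 1:3) stop("n_instances must be 1, 2 or 3")
  structure(list(image_size = as.integer(image_size),
                 n_instances = as.integer(n_instances),
                 brightness = brightness, view = view, scale = scale,
                 pose = pose, occluders = occluders,
                 truncate = isTRUE(truncate), seed = as.integer(seed)),
            class = "scene_spec")
}

fill_ellipse <- function(mask, cx, cy, rx, ry) {
  d <- dim(mask)
  ys <- matrix(seq_len(d[1]) - 0.5, d[1], d[2])
  xs <- matrix(seq_len(d[2]) - 0.5, d[1], d[2], byrow = TRUE)
  mask | (((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1)
}

stroke_segment <- function(mask, x1, y1, x2, y2, r) {
  d <- dim(mask)
  ys <- matrix(seq_len(d[1]) - 0.5, d[1], d[2])
  xs <- matrix(seq_len(d[2]) - 0.5, d[1], d[2], byrow = TRUE)
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- if (len2 > 0) pmin(1, pmax(0, ((xs - x1) * vx + (ys - y1) * vy) / len2)) else 0
  mask | ((xs - (x1 + t * vx))^2 + (ys - (y1 + t * vy))^2 <= r^2)
}

instance_mask <- function(inst, size) {
  kp <- inst$keypoints
  g <- attr(inst, "geom")
  L <- g$L
  mask <- matrix(FALSE, size, size)
  sch <- cattle_keypoint_schema()
  pt <- function(nm) kp[match(nm, sch), 1:2]
  neck <- pt("neck"); spine <- pt("spine"); cocc <- pt("coccyx")
  head <- pt("head top")
  body_w <- if (g$view == "side") 0.24 * L else 0.16 * L
  mask <- fill_ellipse(mask, (neck[1] + cocc[1]) / 2,
                       (neck[2] + cocc[2]) / 2 + 0.14 * L,
                       abs(cocc[1] - neck[1]) / 2 + 0.16 * L, body_w)
  mask <- fill_ellipse(mask, head[1], head[2] + 0.05 * L,
                       max(0.11 * L, 2), max(0.13 * L, 2))
  mask <- stroke_segment(mask, head[1], head[2], neck[1], neck[2] + 0.1 * L,
                         max(0.07 * L, 1.2))
  r <- max(0.045 * L, 1.2)
  for (leg in c("right front", "left front", "right hind", "left hind")) {
    th <- pt(paste(leg, "thigh root")); kn <- pt(paste(leg, "knee"))
    hf <- pt(paste(leg, "hoof"))
    mask <- stroke_segment(mask, th[1], th[2], kn[1], kn[2], r)
    mask <- stroke_segment(mask, kn[1], kn[2], hf[1], hf[2], r)
  }
  mask
}

#' Render a synthetic cattle scene
#'
#' Flat-shaded silhouettes over a textured background, with exact
#' annotations. Fence occluders overdraw the animals and flip covered
#' visible keypoints to v = 1; instances drawn later occlude keypoints of
#' earlier ones the same way; truncation clips keypoints off-canvas to
#' v = 0. Dim scenes are darkened by a factor 0.35 plus additive noise.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3 array in 0..1), `doc` (a
#'   `labelme_doc`), `masks` (per-instance foreground masks), `tags`
#'   (character factor tags of the scene).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  size <- spec$image_size
  for (oc in spec$occluders) {
    if (oc[1] < 0 || oc[1] + oc[2] > size) {
      stop("validation error: occluder outside image")
    }
  }
  local_rng(spec$seed, {
    img <- matrix(0.42, size, size) +
      outer(seq(0, 0.12, length.out = size), rep(1, size)) +
      matrix(rnorm(size * size, sd = 0.03), size, size)
    img <- array(rep(img, 3), c(size, size, 3))
    img[, , 2] <- img[, , 2] * 0.95
    img[, , 3] <- img[, , 3] * 0.80
    instances <- list()
    masks <- list()
    for (i in seq_len(spec$n_instances)) {
      pose <- if (is.null(spec$pose)) {
        sample(c("standing", "walking", "lying"), 1,
               prob = c(0.5, 0.3, 0.2))
      } else spec$pose
      inst <- sample_skeleton(spec$view, spec$scale, pose, size)
      if (spec$truncate && i == 1L) {
        shift <- 0.35 * size
        kp <- inst$keypoints
        kp[, 1] <- kp[, 1] - shift
        b <- inst$box; b[1] <- b[1] - shift
        g <- attr(inst, "geom")
        inst <- keypoint_instance(b, 1, kp)
        attr(inst, "geom") <- g
      }
      instances[[i]] <- inst
    }
    # draw in list order; later instances overdraw earlier ones
    for (i in seq_along(instances)) {
      inst <- instances[[i]]
      g <- attr(inst, "geom")
      if (is.null(g)) {
        g <- list(L = max(inst$box[3:4]) / 1.2, view = spec$view)
        attr(inst, "geom") <- g
        instances[[i]] <- inst
      }
      mask <- instance_mask(inst, size)
      shade <- runif(1, 0.18, 0.40)
      tint <- c(1, runif(1, 0.75, 0.9), runif(1, 0.55, 0.75))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- shade * tint[ch] +
          rnorm(sum(mask), sd = 0.015)
        img[, , ch] <- plane
      }
      masks[[i]] <- mask
    }
    # later-drawn instances occlude visible keypoints of earlier ones
    if (length(instances) > 1L) {
      for (i in seq_len(length(instances) - 1L)) {
        kp <- instances[[i]]$keypoints
        for (j in (i + 1L):length(instances)) {
          mj <- masks[[j]]
          px <- pmin(pmax(ceiling(kp[, 1]), 1L), size)
          py <- pmin(pmax(ceiling(kp[, 2]), 1L), size)
          cover <- mj[cbind(py, px)] & kp[, 3] == 2
          kp[cover, 3] <- 1
        }
        instances[[i]]$keypoints <- kp
      }
    }
    # fence bars overdraw everything
    for (oc in spec$occluders) {
      cols <- max(1L, ceiling(oc[1])):min(size, ceiling(oc[1] + oc[2]))
      img[, cols, ] <- 0.25
      for (i in seq_along(instances)) {
        kp <- instances[[i]]$keypoints
        hit <- kp[, 1] >= oc[1] & kp[, 1] <= oc[1] + oc[2] & kp[, 3] == 2
        kp[hit, 3] <- 1
        instances[[i]]$keypoints <- kp
        masks[[i]][, cols] <- FALSE
      }
    }
    # truncation: off-canvas keypoints are not labeled
    for (i in seq_along(instances)) {
      kp <- instances[[i]]$keypoints
      out <- kp[, 1] < 0 | kp[, 1] > size | kp[, 2] < 0 | kp[, 2] > size
      kp[out, 3] <- 0
      instances[[i]]$keypoints <- kp
    }
    if (spec$brightness == "dim") {
      img <- img * 0.35 + array(rnorm(length(img), sd = 0.02), dim(img))
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    schema <- cattle_keypoint_schema()
    doc_insts <- lapply(instances, function(inst) {
      kp <- inst$keypoints
      keep <- kp[, 3] > 0
      list(box = c(inst$box[1], inst$box[2], inst$box[1] + inst$box[3],
                   inst$box[2] + inst$box[4]),
           keypoints = data.frame(name = schema[keep], x = kp[keep, 1],
                                  y = kp[keep, 2],
                                  v = as.integer(kp[keep, 3]),
                                  stringsAsFactors = FALSE))
    })
    tags <- c(paste0(spec$scale, " scale"),
              paste0(spec$brightness, " light"),
              paste0(spec$view, " view"),
              if (length(spec$occluders) || spec$n_instances > 1L ||
                  spec$truncate) "occlusion" else "unobstructed")
    list(image = img,
         doc = labelme_doc("", size, size, 3L, doc_insts),
         instances = instances, masks = masks, tags = tags)
  })
}

#' Pseudo-predictor configuration
#'
#' @param jitter_sigma per-axis Gaussian displacement of visible keypoints
#'   (pixels).
#' @param drop_probability probability of dropping a keypoint (v to 0).
#' @param score confidence assigned to every pseudo prediction, in (0, 1].
#' @return an object of class `pseudo_pred_config`.
#' @export
pseudo_pred_config <- function(jitter_sigma = 0, drop_probability = 0,
                               score = 0.9) {
  if (jitter_sigma < 0) stop("jitter_sigma must be non-negative")
  if (drop_probability < 0 || drop_probability > 1) {
    stop("drop_probability must lie in [0, 1]")
  }
  if (score <= 0 || score > 1) stop("score must lie in (0, 1]")
  structure(list(jitter_sigma = jitter_sigma,
                 drop_probability = drop_probability, score = score),
            class = "pseudo_pred_config")
}

#' Jitter ground-truth instances into pseudo predictions
#'
#' Displaces every visible keypoint by independent per-axis Gaussian noise,
#' optionally drops keypoints, copies boxes, and assigns the configured
#' score. Used to validate the OKS/AP protocol against its closed-form
#' expectation.
#'
#' @param gts list of [keypoint_instance()].
#' @param config a [pseudo_pred_config()].
#' @param seed optional integer seed.
#' @return list of predicted [keypoint_instance()].
#' @export
jitter_predictions <- function(gts, config = pseudo_pred_config(),
                               seed = NULL) {
  if (!is.null(seed)) {
    return(local_rng(seed, jitter_predictions(gts, config)))
  }
  lapply(gts, function(g) {
    kp <- g$keypoints
    vis <- kp[, 3] > 0
    nv <- sum(vis)
    kp[vis, 1] <- kp[vis, 1] + rnorm(nv, sd = config$jitter_sigma)
    kp[vis, 2] <- kp[vis, 2] + rnorm(nv, sd = config$jitter_sigma)
    if (config$drop_probability > 0) {
      drop <- vis & runif(16) < config$drop_probability
      kp[drop, 3] <- 0
    }
    keypoint_instance(g$box, config$score, kp)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG images, Labelme-style JSON, converted YOLO-pose text records
#' and a per-image factor-tag sidecar, stratified by the requested factor
#' mixture (defaults mirror the study's condition breakdown: scale 2:1
#' large:small, light 1:1, views equal, occlusion 1:2).
#'
#' @param n_images number of scenes.
#' @param seed integer seed; output is byte-deterministic given it.
#' @param out_dir output directory (created if needed).
#' @param image_size canvas edge in pixels.
#' @param mixture named list of factor proportions with entries `scale`,
#'   `brightness`, `view`, `occlusion`.
#' @return manifest data.frame (one row per image: file paths, tags, seed),
#'   invisibly also written to `manifest.csv`.
#' @export
generate_dataset <- function(n_images, seed = 0L, out_dir,
                             image_size = 320L,
                             mixture = list(
                               scale = c(large = 2 / 3, small = 1 / 3),
                               brightness = c(bright = 0.5, dim = 0.5),
                               view = c(side = 1 / 3, front = 1 / 3,
                                        back = 1 / 3),
                               occlusion = c(occluded = 1 / 3,
                                             unobstructed = 2 / 3))) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("I/O error: cannot create ", out_dir)
  for (d in c("images", "labels_json", "labels_txt", "tags")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  assign_factor <- function(props, n) {
    counts <- floor(props * n)
    while (sum(counts) < n) {
      i <- which.max(props * n - counts)
      counts[i] <- counts[i] + 1L
    }
    rep(names(props), counts)
  }
  local_rng(seed, {
    fac <- data.frame(
      scale = sample(assign_factor(mixture$scale, n_images)),
      brightness = sample(assign_factor(mixture$brightness, n_images)),
      view = sample(assign_factor(mixture$view, n_images)),
      occl = sample(assign_factor(mixture$occlusion, n_images)),
      stringsAsFactors = FALSE)
    nins <- sample(1:3, n_images, replace = TRUE,
                   prob = c(0.78, 0.19, 0.03))
    seeds <- sample.int(.Machine$integer.max - 1L, n_images)
    rows <- lapply(seq_len(n_images), function(i) {
      occluded <- fac$occl[i] == "occluded"
      occ <- if (occluded) {
        list(c(runif(1, 0.2, 0.7) * image_size,
               max(2, 0.03 * image_size)))
      } else list()
      spec <- scene_spec(image_size = image_size,
                         n_instances = if (occluded) max(nins[i], 1L) else nins[i],
                         brightness = fac$brightness[i], view = fac$view[i],
                         scale = fac$scale[i], occluders = occ,
                         seed = seeds[i])
      sc <- render_scene(spec)
      stem <- sprintf("img_%05d", i)
      img_path <- file.path("images", paste0(stem, ".png"))
      json_path <- file.path("labels_json", paste0(stem, ".json"))
      txt_path <- file.path("labels_txt", paste0(stem, ".txt"))
      tag_path <- file.path("tags", paste0(stem, ".json"))
      png::writePNG(sc$image, file.path(out_dir, img_path))
      doc <- sc$doc
      doc$image_path <- img_path
      write_labelme(doc, file.path(out_dir, json_path))
      write_yolo_txt(labelme_to_yolo(doc), file.path(out_dir, txt_path))
      jsonlite::write_json(sc$tags, file.path(out_dir, tag_path))
      data.frame(image = img_path, json = json_path, txt = txt_path,
                 tags = paste(sc$tags, collapse = ";"),
                 n_instances = length(sc$doc$instances),
                 seed = seeds[i], stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    manifest
  })
}

#' Load a generated dataset into memory
#'
#' @param manifest manifest data.frame from [generate_dataset()].
#' @param root dataset root directory.
#' @return list with one entry per image: `image` array, `doc`, `gts`
#'   (list of [keypoint_instance()]), `tags`.
#' @export
load_dataset <- function(manifest, root) {
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(root, manifest$image[i]))
    doc <- read_labelme(file.path(root, manifest$json[i]))
    gts <- doc_to_instances(doc)
    list(image = img, doc = doc, gts = gts,
         tags = strsplit(manifest$tags[i], ";")[[1]])
  })
}

#' Convert a `labelme_doc` to a list of keypoint instances
#' @param doc a `labelme_doc`.
#' @return list of [keypoint_instance()] with score 1.
#' @export
doc_to_instances <- function(doc) {
  lapply(doc$instances, function(inst) {
    kp <- full_keypoint_frame(inst$keypoints)
    keypoint_instance(c(inst$box[1], inst$box[2],
                        inst$box[3] - inst$box[1],
                        inst$box[4] - inst$box[2]), 1,
                      cbind(kp$x, kp$y, kp$v))
  })
}
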