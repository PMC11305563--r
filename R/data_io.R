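# The 16-keypoint cattle annotation schema and conversion between
# Labelme-style JSON documents and YOLO-pose normalized text records.
# Coordinates are 0-based, pixel-continuous, origin top-left, x rightward,
# y downward; normalization divides by image width/height. A text record is
# one line per instance: class, cx, cy, w, h, then 16 triples (x, y, v) --
# 53 space-separated fields. Absent keypoints (v = 0) are written as 0 0 0.

#' The ordered 16-keypoint cattle schema
#' @return character vector of the 16 keypoint names, in canonical order.
#' @export
cattle_keypoint_schema <- function() {
  c("head top", "neck", "spine",
    "right front thigh root", "right front knee", "right front hoof",
    "left front thigh root", "left front knee", "left front hoof",
    "coccyx",
    "right hind thigh root", "right hind knee", "right hind hoof",
    "left hind thigh root", "left hind knee", "left hind hoof")
}

#' Construct a Labelme-style annotation document
#'
#' @param image_path path of the annotated image (relative to the dataset
#'   root).
#' @param width,height image size in pixels.
#' @param channels channel count (3 for RGB).
#' @param instances list; each element has `box` (x1, y1, x2, y2 corner
#'   coordinates) and `keypoints` (data.frame with columns `name`, `x`,
#'   `y`, `v`).
#' @return an object of class `labelme_doc`.
#' @export
labelme_doc <- function(image_path, width, height, channels = 3L,
                        instances = list()) {
  doc <- structure(list(image_path = image_path, width = as.numeric(width),
                        height = as.numeric(height),
                        channels = as.integer(channels),
                        instances = instances), class = "labelme_doc")
  validate_labelme(doc)
}

validate_labelme <- function(doc) {
  if (!is.finite(doc$width) || !is.finite(doc$height) ||
      doc$width <= 0 || doc$height <= 0) {
    stop("format error: image width/height missing or invalid")
  }
  schema <- cattle_keypoint_schema()
  for (i in seq_along(doc$instances)) {
    inst <- doc$instances[[i]]
    kp <- inst$keypoints
    if (nrow(kp) > 16L) {
      stop("validation error: instance ", i, " has ", nrow(kp),
           " keypoints; at most 16 allowed")
    }
    bad <- setdiff(kp$name, schema)
    if (length(bad)) {
      stop("validation error: unknown keypoint name(s) ",
           paste(sQuote(bad), collapse = ", "), "; allowed names are: ",
           paste(schema, collapse = ", "))
    }
    if (anyDuplicated(kp$name)) {
      stop("validation error: duplicate keypoint name within instance ", i)
    }
    inb <- kp$x >= 0 & kp$x <= doc$width & kp$y >= 0 & kp$y <= doc$height
    doc$instances[[i]]$truncated <- any(!inb & kp$v > 0)
  }
  doc
}

#' Read a Labelme-style JSON annotation file
#'
#' Shapes are grouped into instances by `group_id`; each instance holds one
#' `rectangle` (the bounding box) and up to 16 named `point` shapes.
#' A point's `flags$occluded` marks it labeled-but-occluded (v = 1);
#' otherwise a labeled point is visible (v = 2). Unlabeled keypoints are
#' absent (v = 0).
#'
#' @param path JSON file path.
#' @return a `labelme_doc`.
#' @export
read_labelme <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$imageWidth) || is.null(j$imageHeight)) {
    stop("format error: imageWidth/imageHeight missing in ", path)
  }
  gids <- unique(vapply(j$shapes, function(s) {
    if (is.null(s$group_id)) 1L else as.integer(s$group_id)
  }, integer(1)))
  schema <- cattle_keypoint_schema()
  instances <- lapply(sort(gids), function(g) {
    shapes <- Filter(function(s) {
      gid <- if (is.null(s$group_id)) 1L else as.integer(s$group_id)
      gid == g
    }, j$shapes)
    rects <- Filter(function(s) identical(s$shape_type, "rectangle"), shapes)
    pts <- Filter(function(s) identical(s$shape_type, "point"), shapes)
    if (length(rects) != 1L) {
      stop("validation error: instance group ", g, " needs exactly one ",
           "rectangle shape")
    }
    p <- rects[[1]]$points
    box <- c(min(p[[1]][[1]], p[[2]][[1]]), min(p[[1]][[2]], p[[2]][[2]]),
             max(p[[1]][[1]], p[[2]][[1]]), max(p[[1]][[2]], p[[2]][[2]]))
    kp <- data.frame(
      name = vapply(pts, function(s) as.character(s$label), character(1)),
      x = vapply(pts, function(s) as.numeric(s$points[[1]][[1]]), numeric(1)),
      y = vapply(pts, function(s) as.numeric(s$points[[1]][[2]]), numeric(1)),
      v = vapply(pts, function(s) {
        if (isTRUE(s$flags$occluded)) 1L else 2L
      }, integer(1)), stringsAsFactors = FALSE)
    list(box = box, keypoints = kp)
  })
  labelme_doc(if (is.null(j$imagePath)) "" else j$imagePath,
              j$imageWidth, j$imageHeight,
              if (is.null(j$imageChannels)) 3L else j$imageChannels,
              instances)
}

#' Write a `labelme_doc` as Labelme-style JSON
#' @param doc a `labelme_doc`.
#' @param path output file path.
#' @export
write_labelme <- function(doc, path) {
  doc <- validate_labelme(doc)
  shapes <- list()
  for (g in seq_along(doc$instances)) {
    inst <- doc$instances[[g]]
    shapes <- c(shapes, list(list(
      label = "cattle",
      points = list(c(inst$box[1], inst$box[2]),
                    c(inst$box[3], inst$box[4])),
      group_id = g, shape_type = "rectangle", flags = structure(list(), names = character(0)))))
    kp <- inst$keypoints
    for (r in seq_len(nrow(kp))) {
      if (kp$v[r] == 0L) next
      shapes <- c(shapes, list(list(
        label = kp$name[r], points = list(c(kp$x[r], kp$y[r])),
        group_id = g, shape_type = "point",
        flags = if (kp$v[r] == 1L) list(occluded = TRUE) else structure(list(), names = character(0)))))
    }
  }
  out <- list(version = "5.2.1", flags = structure(list(), names = character(0)), shapes = shapes,
              imagePath = doc$image_path, imageHeight = doc$height,
              imageWidth = doc$width, imageChannels = doc$channels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

full_keypoint_frame <- function(kp) {
  schema <- cattle_keypoint_schema()
  out <- data.frame(name = schema, x = 0, y = 0, v = 0L,
                    stringsAsFactors = FALSE)
  if (!is.null(kp) && nrow(kp)) {
    idx <- match(kp$name, schema)
    out$x[idx] <- kp$x
    out$y[idx] <- kp$y
    out$v[idx] <- kp$v
  }
  out
}

#' Convert a Labelme document to YOLO-pose records
#'
#' Boxes go corner to center/size form and are normalized by the image
#' size; keypoints are normalized likewise. Keypoints that are absent or
#' out of frame are encoded as the triple (0, 0, 0); labeled-but-occluded
#' points keep v = 1 and visible points v = 2.
#'
#' @param doc a `labelme_doc`.
#' @return data.frame with 53 columns (`class`, `cx`, `cy`, `w`, `h`, then
#'   `x1`, `y1`, `v1`, ..., `x16`, `y16`, `v16`), one row per instance.
#' @export
labelme_to_yolo <- function(doc) {
  doc <- validate_labelme(doc)
  W <- doc$width; H <- doc$height
  rows <- lapply(doc$instances, function(inst) {
    b <- inst$box
    # clip truncated boxes to the image so normalized values stay in [0, 1]
    b <- c(max(0, b[1]), max(0, b[2]), min(W, b[3]), min(H, b[4]))
    bw <- b[3] - b[1]; bh <- b[4] - b[2]
    if (bw <= 0 || bh <= 0) stop("validation error: zero-area bounding box")
    kp <- full_keypoint_frame(inst$keypoints)
    oob <- kp$x < 0 | kp$x > W | kp$y < 0 | kp$y > H
    kp$v[oob] <- 0L
    kp$x[kp$v == 0L] <- 0
    kp$y[kp$v == 0L] <- 0
    vals <- c(0, (b[1] + bw / 2) / W, (b[2] + bh / 2) / H, bw / W, bh / H,
              as.numeric(t(cbind(kp$x / W, kp$y / H, kp$v))))
    vals
  })
  m <- do.call(rbind, rows)
  colnames(m) <- yolo_field_names()
  as.data.frame(m)
}

yolo_field_names <- function() {
  c("class", "cx", "cy", "w", "h",
    as.vector(t(outer(seq_len(16), c("x", "y", "v"),
                      function(i, s) paste0(s, i)))))
}

#' Convert YOLO-pose records back to a Labelme document
#'
#' @param records data.frame as produced by [labelme_to_yolo()] or
#'   [read_yolo_txt()].
#' @param width,height image size in pixels used for denormalization.
#' @param image_path stored image path.
#' @return a `labelme_doc`.
#' @export
yolo_to_labelme <- function(records, width, height, image_path = "") {
  schema <- cattle_keypoint_schema()
  instances <- lapply(seq_len(nrow(records)), function(r) {
    v <- as.numeric(records[r, ])
    cx <- v[2] * width; cy <- v[3] * height
    bw <- v[4] * width; bh <- v[5] * height
    k <- matrix(v[6:53], ncol = 3, byrow = TRUE)
    keep <- k[, 3] > 0
    kp <- data.frame(name = schema[keep], x = k[keep, 1] * width,
                     y = k[keep, 2] * height, v = as.integer(k[keep, 3]),
                     stringsAsFactors = FALSE)
    list(box = c(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2),
         keypoints = kp)
  })
  labelme_doc(image_path, width, height, 3L, instances)
}

#' Write / read YOLO-pose text records
#'
#' One line per instance, 53 space-separated fields; normalized values are
#' written with six decimals.
#'
#' @param records data.frame of records.
#' @param path text file path.
#' @rdname yolo_txt
#' @export
write_yolo_txt <- function(records, path) {
  lines <- apply(records, 1, function(v) {
    paste(c(sprintf("%d", as.integer(v[1])),
            sprintf("%.6f", as.numeric(v[2:5])),
            as.vector(rbind(sprintf("%.6f", as.numeric(v[seq(6, 53, 3)])),
                            sprintf("%.6f", as.numeric(v[seq(7, 53, 3)])),
                            sprintf("%d", as.integer(v[seq(8, 53, 3)]))))),
          collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname yolo_txt
#' @export
read_yolo_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    f <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(f) != 53L) {
      stop("format error: expected 53 fields per record, got ", length(f))
    }
    f
  })
  m <- do.call(rbind, rows)
  colnames(m) <- yolo_field_names()
  as.data.frame(m)
}

#' Deterministically split a manifest into training and validation parts
#'
#' @param manifest character vector (or data.frame with an `image` column)
#'   of dataset entries.
#' @param ratio training fraction in (0, 1); the training set gets
#'   `round(n * ratio)` entries.
#' @param seed integer seed; the same seed always yields the same split.
#' @return list with `train` and `val`, disjoint and covering the manifest.
#' @export
split_dataset <- function(manifest, ratio = 0.9, seed = 0L) {
  n <- if (is.data.frame(manifest)) nrow(manifest) else length(manifest)
  if (n == 0L) stop("empty manifest")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  perm <- local_rng(seed, sample.int(n))
  ntrain <- round(n * ratio)
  take <- function(idx) {
    if (is.data.frame(manifest)) manifest[idx, , drop = FALSE]
    else manifest[idx]
  }
  list(train = take(sort(perm[seq_len(ntrain)])),
       val = take(sort(perm[setdiff(seq_len(n), seq_len(ntrain))])))
}

# Run an expression under a temporary RNG state seeded with `seed`.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
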