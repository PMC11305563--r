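# Object-keypoint-similarity (OKS) scoring and the average-precision
# protocol. OKS is the keypoint analogue of IoU: a Gaussian kernel on the
# per-keypoint pixel error d_i, normalized by the object scale s (square
# root of the ground-truth box area) and a per-keypoint decay constant k_i,
# averaged over the keypoints visible in the annotation:
#
#   OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0]
#
# AP at threshold t is the fraction of detections whose matched OKS
# reaches t; AP_0.5:0.95 averages the ten thresholds 0.50, 0.55, ..., 0.95.

#' OKS configuration
#'
#' @param k per-keypoint decay constants, length 16 (default uniform 0.1;
#'   `s * k_i` is the standard deviation of the error kernel in pixels).
#' @param scale_rule how the object scale s is derived; only
#'   `"sqrt_box_area"` is defined.
#' @return an object of class `oks_config`.
#' @export
oks_config <- function(k = rep(0.1, 16), scale_rule = "sqrt_box_area") {
  k <- rep_len(as.numeric(k), 16L)
  if (any(k <= 0)) stop("decay constants k must be positive")
  scale_rule <- match.arg(scale_rule, "sqrt_box_area")
  structure(list(k = k, scale_rule = scale_rule), class = "oks_config")
}

instance_scale <- function(inst) {
  sqrt(max(inst$box[3], 0) * max(inst$box[4], 0))
}

#' Object keypoint similarity between one ground truth and one prediction
#'
#' Only keypoints visible in the ground truth (v > 0) contribute.
#'
#' @param gt,pred [keypoint_instance()] objects.
#' @param config an [oks_config()].
#' @return OKS value in `[0, 1]`.
#' @export
oks <- function(gt, pred, config = oks_config()) {
  vis <- gt$keypoints[, 3] > 0
  if (!any(vis)) {
    stop("undefined OKS: ground truth has no visible keypoints")
  }
  s <- instance_scale(gt)
  if (s <= 0) stop("undefined OKS: ground-truth box has zero area")
  d2 <- (gt$keypoints[vis, 1] - pred$keypoints[vis, 1])^2 +
    (gt$keypoints[vis, 2] - pred$keypoints[vis, 2])^2
  mean(exp(-d2 / (2 * s^2 * config$k[vis]^2)))
}

#' Match predictions to ground truths within one image
#'
#' Predictions are processed in order of descending score (ties broken by
#' input order); each claims the still-unclaimed ground truth maximizing
#' OKS. Unmatched predictions carry OKS 0; each ground truth is matched at
#' most once.
#'
#' @param gts,preds lists of [keypoint_instance()].
#' @param config an [oks_config()].
#' @return data.frame with columns `pred`, `gt` (NA if unmatched), `oks`,
#'   `score`, one row per prediction.
#' @export
match_instances <- function(gts, preds, config = oks_config()) {
  np <- length(preds)
  out <- data.frame(pred = seq_len(np), gt = rep(NA_integer_, np),
                    oks = numeric(np),
                    score = vapply(preds, function(p) p$score, numeric(1)))
  if (np == 0L) return(out)
  claimed <- rep(FALSE, length(gts))
  ord <- order(-out$score, out$pred)
  for (j in ord) {
    free <- which(!claimed)
    if (length(free) == 0L) break
    vals <- vapply(free, function(i) oks(gts[[i]], preds[[j]], config),
                   numeric(1))
    best <- which.max(vals)
    out$gt[j] <- free[best]
    out$oks[j] <- vals[best]
    claimed[free[best]] <- TRUE
  }
  out
}

#' Detection accuracy at one OKS threshold
#'
#' The fraction of detection records whose OKS reaches `t`; 0 by convention
#' when there are no detections.
#'
#' @param matches a match table from [match_instances()] (rows from several
#'   images may be pooled).
#' @param t threshold in `[0.5, 0.95]`.
#' @return accuracy in `[0, 1]`.
#' @export
ap_at <- function(matches, t) {
  if (t < 0.5 || t > 0.95) stop("threshold must lie in [0.5, 0.95]")
  if (nrow(matches) == 0L) return(0)
  mean(matches$oks >= t)
}

#' The ten OKS thresholds of the AP protocol (0.50 to 0.95, step 0.05)
#' @return numeric vector of length 10.
#' @export
oks_thresholds <- function() seq(0.50, 0.95, by = 0.05)

#' Evaluate a dataset of ground truths and predictions
#'
#' Detections from all images are pooled; AP is computed at the ten OKS
#' thresholds 0.50 to 0.95 (step 0.05) and averaged for AP_0.5:0.95. When
#' per-image factor tags are supplied, the same protocol runs on each
#' tag-defined subset.
#'
#' @param dataset list with one entry per image, each a list with elements
#'   `gts` and `preds` (lists of [keypoint_instance()]).
#' @param config an [oks_config()].
#' @param factor_tags optional list (one character vector of tags per
#'   image); an image may carry several tags (scale, light, view,
#'   occlusion).
#' @param factor_levels optional tag universe; requested levels with no
#'   images are dropped with a warning.
#' @return an object of class `pose_eval` with `ap_by_threshold`, `ap50`,
#'   `ap50_95` and `per_factor`.
#' @export
evaluate_poses <- function(dataset, config = oks_config(),
                           factor_tags = NULL, factor_levels = NULL) {
  pool <- function(idx) {
    do.call(rbind, lapply(idx, function(i) {
      match_instances(dataset[[i]]$gts, dataset[[i]]$preds, config)
    }))
  }
  ap_block <- function(matches) {
    th <- oks_thresholds()
    ap <- vapply(th, function(t) ap_at(matches, t), numeric(1))
    names(ap) <- sprintf("%.2f", th)
    list(ap_by_threshold = ap, ap50 = ap[[1]], ap50_95 = mean(ap))
  }
  all_idx <- seq_along(dataset)
  main <- ap_block(pool(all_idx))
  per_factor <- list()
  if (!is.null(factor_tags)) {
    stopifnot(length(factor_tags) == length(dataset))
    levels <- if (is.null(factor_levels)) {
      unique(unlist(factor_tags))
    } else {
      factor_levels
    }
    for (tag in levels) {
      idx <- which(vapply(factor_tags, function(tt) tag %in% tt, logical(1)))
      if (length(idx) == 0L) {
        warning("no images carry factor tag '", tag, "'; entry omitted")
        next
      }
      b <- ap_block(pool(idx))
      per_factor[[tag]] <- c(ap50 = b$ap50, ap50_95 = b$ap50_95,
                             n_images = length(idx))
    }
  }
  structure(c(main, list(per_factor = per_factor,
                         n_images = length(dataset))),
            class = "pose_eval")
}

#' @export
print.pose_eval <- function(x, ...) {
  cat(format_eval_table(x), sep = "\n")
  invisible(x)
}

#' Plain-text table of an evaluation result
#' @param eval a `pose_eval`.
#' @return character vector of table lines.
#' @export
format_eval_table <- function(eval) {
  lines <- c(
    sprintf("Pose evaluation over %d image(s)", eval$n_images),
    sprintf("  AP_0.5      = %.4f", eval$ap50),
    sprintf("  AP_0.5:0.95 = %.4f", eval$ap50_95),
    "  per-threshold:",
    paste0("    ", paste(sprintf("%s:%.3f", names(eval$ap_by_threshold),
                                 eval$ap_by_threshold), collapse = " ")))
  if (length(eval$per_factor)) {
    lines <- c(lines, "  per-factor:")
    for (tag in names(eval$per_factor)) {
      f <- eval$per_factor[[tag]]
      lines <- c(lines, sprintf("    %-14s ap50=%.4f ap50_95=%.4f (n=%d)",
                                tag, f[["ap50"]], f[["ap50_95"]],
                                as.integer(f[["n_images"]])))
    }
  }
  lines
}

#' Write an evaluation report to JSON and/or plain text
#' @param eval a `pose_eval`.
#' @param json_path,txt_path output file paths (NULL to skip).
#' @export
write_eval_report <- function(eval, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(eval), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(txt_path)) {
    writeLines(format_eval_table(eval), txt_path)
  }
  invisible(eval)
}
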