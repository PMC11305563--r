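# Model assembly: an anchor-free single-stage pose estimator with a
# CSP-style backbone (stem, C2f stages, SPPF), an optional parameter-free
# attention operator after the C2f of the P3/P4/P5 stages, one of two neck
# networks (the reference path-aggregation neck, or the reparameterizable
# bidirectional fusion neck), and a decoupled head that predicts, per grid
# cell: a distributional box regression (4 sides x reg_max bins), a class
# score, and num_keypoints x keypoint_dims keypoint values.

make_divisible <- function(x, divisor = 8L) {
  as.integer(ceiling(x / divisor) * divisor)
}

#' Model configuration
#'
#' Width/depth multipliers follow the public n-scale convention
#' (depth 1/3, width 1/4, max 1024 channels). `neck_widths` pins the
#' internal channel widths of the bidirectional fusion neck; the committed
#' defaults are the package's reference configuration.
#'
#' @param depth_multiple,width_multiple,max_channels scaling of block
#'   repeats and channel widths.
#' @param num_keypoints,keypoint_dims keypoint field layout (16 x 3 for the
#'   cattle schema: x, y, visibility).
#' @param num_classes object classes (1: cattle).
#' @param reg_max bins of the distributional box regression.
#' @param simam_stages character subset of `c("P3","P4","P5")`: stages whose
#'   C2f output is refined by SimAM attention.
#' @param simam_omega regularization coefficient of the attention energy.
#' @param neck `"pan_baseline"` or `"efficient_rep_bipan"`.
#' @param repblock_depths integer vector of length 4: units per RepBlock
#'   (top-down P4, top-down P3, bottom-up P4, bottom-up P5).
#' @param neck_widths named list of internal channel widths of the
#'   bidirectional neck (`w4`, `w3`, `d3`, `d4`, `p3`, `p4`, `p5`).
#' @param input_size default square input resolution (must be a multiple
#'   of 32).
#' @return an object of class `pose_model_config`.
#' @export
model_config <- function(depth_multiple = 1 / 3,
                         width_multiple = 0.25,
                         max_channels = 1024L,
                         num_keypoints = 16L,
                         keypoint_dims = 3L,
                         num_classes = 1L,
                         reg_max = 16L,
                         simam_stages = c("P3", "P4", "P5"),
                         simam_omega = 1e-4,
                         neck = c("efficient_rep_bipan", "pan_baseline"),
                         repblock_depths = c(1L, 1L, 1L, 1L),
                         neck_widths = NULL,
                         input_size = 640L) {
  neck <- match.arg(neck)
  if (depth_multiple <= 0 || width_multiple <= 0) {
    stop("multipliers must be positive")
  }
  if (!all(simam_stages %in% c("P3", "P4", "P5"))) {
    stop("simam_stages must be a subset of P3/P4/P5")
  }
  if (is.null(neck_widths)) neck_widths <- reference_neck_widths()
  structure(list(
    depth_multiple = depth_multiple, width_multiple = width_multiple,
    max_channels = as.integer(max_channels),
    num_keypoints = as.integer(num_keypoints),
    keypoint_dims = as.integer(keypoint_dims),
    num_classes = as.integer(num_classes), reg_max = as.integer(reg_max),
    simam_stages = simam_stages, simam_omega = simam_omega,
    neck = neck, repblock_depths = as.integer(repblock_depths),
    neck_widths = neck_widths, input_size = as.integer(input_size)
  ), class = "pose_model_config")
}

# Committed reference widths of the bidirectional fusion neck at n-scale.
# See the methods vignette for how these were chosen (once) to give the
# deployed model its printed parameter/FLOP budget.
reference_neck_widths <- function() {
  list(w4 = 48L, w3 = 32L, d3 = 64L, d4 = 160L,
       p3 = 48L, p4 = 128L, p5 = 256L)
}

#' Baseline configuration: standard backbone, PAN neck, no attention
#' @param ... overrides passed to [model_config()].
#' @export
baseline_config <- function(...) {
  model_config(simam_stages = character(0), neck = "pan_baseline", ...)
}

#' Read / write a model configuration as YAML
#' @param path file path.
#' @rdname model_config_io
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$simam_stages <- as.character(unlist(y$simam_stages))
  do.call(model_config, y)
}

#' @param config a `pose_model_config`.
#' @rdname model_config_io
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

scaled_channels <- function(cfg) {
  base <- c(64, 128, 256, 512, 1024)
  vapply(base, function(c) {
    make_divisible(min(c, cfg$max_channels) * cfg$width_multiple, 8L)
  }, integer(1))
}

scaled_depth <- function(n, cfg) max(1L, as.integer(round(n * cfg$depth_multiple)))

container_module <- function(children) {
  m <- new_module("container")
  m$children <- children
  m
}

check_input_size <- function(h, w) {
  if (h %% 32L != 0L || w %% 32L != 0L) {
    stop("invalid input: spatial size must be divisible by 32 (got ",
         h, "x", w, ")")
  }
}

# ---- backbone --------------------------------------------------------------

#' Build the backbone feature extractor
#'
#' Stem and staged C2f blocks with a final SPPF; when a stage is listed in
#' `simam_stages`, a SimAM refinement is appended after that stage's C2f
#' output. Returns an environment with `$forward(x, training)` yielding the
#' P2/P3/P4/P5 pyramid taps.
#'
#' @param cfg a [model_config()].
#' @return backbone environment.
#' @export
build_backbone <- function(cfg) {
  ch <- scaled_channels(cfg)
  d <- vapply(c(3, 6, 6, 3), scaled_depth, integer(1), cfg = cfg)
  bb <- new.env(parent = emptyenv())
  bb$channels <- c(P2 = ch[2], P3 = ch[3], P4 = ch[4], P5 = ch[5])
  sim <- function(stage) {
    if (stage %in% cfg$simam_stages) simam_block(cfg$simam_omega) else NULL
  }
  bb$stem <- conv_block(3L, ch[1], 3L, 2L)
  bb$down2 <- conv_block(ch[1], ch[2], 3L, 2L)
  bb$c2f2 <- c2f_block(ch[2], ch[2], d[1], TRUE)
  bb$down3 <- conv_block(ch[2], ch[3], 3L, 2L)
  bb$c2f3 <- c2f_block(ch[3], ch[3], d[2], TRUE)
  bb$att3 <- sim("P3")
  bb$down4 <- conv_block(ch[3], ch[4], 3L, 2L)
  bb$c2f4 <- c2f_block(ch[4], ch[4], d[3], TRUE)
  bb$att4 <- sim("P4")
  bb$down5 <- conv_block(ch[4], ch[5], 3L, 2L)
  bb$c2f5 <- c2f_block(ch[5], ch[5], d[4], TRUE)
  bb$att5 <- sim("P5")
  bb$sppf <- sppf_block(ch[5], ch[5])
  bb$modules <- Filter(Negate(is.null), list(
    bb$stem, bb$down2, bb$c2f2, bb$down3, bb$c2f3, bb$att3, bb$down4,
    bb$c2f4, bb$att4, bb$down5, bb$c2f5, bb$att5, bb$sppf))
  bb$forward <- function(x, training) {
    d <- map_dims(node_value(x))
    check_input_size(d[2], d[3])
    y <- bb$stem$forward(x, training)
    y <- bb$c2f2$forward(bb$down2$forward(y, training), training)
    p2 <- y
    y <- bb$c2f3$forward(bb$down3$forward(y, training), training)
    if (!is.null(bb$att3)) y <- bb$att3$forward(y, training)
    p3 <- y
    y <- bb$c2f4$forward(bb$down4$forward(y, training), training)
    if (!is.null(bb$att4)) y <- bb$att4$forward(y, training)
    p4 <- y
    y <- bb$c2f5$forward(bb$down5$forward(y, training), training)
    if (!is.null(bb$att5)) y <- bb$att5$forward(y, training)
    p5 <- bb$sppf$forward(y, training)
    list(P2 = p2, P3 = p3, P4 = p4, P5 = p5)
  }
  bb$trace <- function(size) {
    check_input_size(size, size)
    shape <- c(3L, size, size)
    macs <- 0
    shapes <- list()
    step <- function(m, s) {
      t <- m$trace(s)
      macs <<- macs + t$macs
      t$shape
    }
    shape <- step(bb$stem, shape)
    shape <- step(bb$c2f2, step(bb$down2, shape))
    shapes$P2 <- shape
    shape <- step(bb$c2f3, step(bb$down3, shape))
    shapes$P3 <- shape
    shape <- step(bb$c2f4, step(bb$down4, shape))
    shapes$P4 <- shape
    shape <- step(bb$c2f5, step(bb$down5, shape))
    shapes$P5 <- step(bb$sppf, shape)
    list(shapes = shapes, macs = macs)
  }
  bb
}

# ---- bidirectional fusion unit --------------------------------------------

#' Bidirectional fusion block
#'
#' Fuses three neighbouring pyramid levels at the middle level's stride:
#' the deeper map is upsampled 2x by a learned transpose convolution, the
#' shallower map is projected and downsampled by a stride-2 convolution,
#' the current map is projected by a 1x1 convolution; the three are
#' concatenated and projected to `cout`.
#'
#' @param c_deep,c_cur,c_shallow input channel counts.
#' @param cout output channels.
#' @return a module taking `(deep, current, shallow)` maps.
#' @export
bifusion_block <- function(c_deep, c_cur, c_shallow, cout) {
  m <- new_module("bifusion_block")
  m$up <- deconv_block(c_deep, cout)
  m$cv_cur <- conv_block(c_cur, cout, 1L)
  m$cv_shal <- conv_block(c_shallow, cout, 1L)
  m$down <- conv_block(cout, cout, 3L, 2L)
  m$cv_out <- conv_block(3L * cout, cout, 1L)
  m$children <- list(m$up, m$cv_cur, m$cv_shal, m$down, m$cv_out)
  m$forward <- function(deep, current, shallow, training) {
    dd <- map_dims(node_value(deep))
    dc <- map_dims(node_value(current))
    ds <- map_dims(node_value(shallow))
    if (!(dd[2] * 2L == dc[2] && ds[2] == dc[2] * 2L)) {
      stop("shape error: bifusion needs strides (2s, s, s/2) for ",
           "(deep, current, shallow)")
    }
    u <- m$up$forward(deep, training)
    cur <- m$cv_cur$forward(current, training)
    sh <- m$down$forward(m$cv_shal$forward(shallow, training), training)
    m$cv_out$forward(op_concat(list(u, cur, sh)), training)
  }
  m$trace <- function(shape_cur) {
    s <- shape_cur[2:3]
    macs <- m$up$trace(c(m$up$cin, s %/% 2L))$macs +
      m$cv_cur$trace(shape_cur)$macs +
      m$cv_shal$trace(c(m$cv_shal$cin, s * 2L))$macs +
      m$down$trace(c(m$down$cin, s * 2L))$macs +
      m$cv_out$trace(c(m$cv_out$cin, s))$macs
    list(shape = c(m$cv_out$cout, s), macs = macs)
  }
  m
}

#' Fuse three neighbouring pyramid levels
#'
#' Convenience wrapper around [bifusion_block()]: builds (or reuses) a
#' block and applies it to the three maps, returning a map at the middle
#' input's stride.
#'
#' @param deep,current,shallow maps of dim (C, H, W, N) with strides
#'   (2s, s, s/2).
#' @param out_channels output channels.
#' @param block optional existing [bifusion_block()].
#' @param training logical.
#' @return fused map of dim (out_channels, H, W, N).
#' @export
bifusion <- function(deep, current, shallow, out_channels, block = NULL,
                     training = FALSE) {
  if (is.null(block)) {
    block <- bifusion_block(map_dims(node_value(deep))[1],
                            map_dims(node_value(current))[1],
                            map_dims(node_value(shallow))[1], out_channels)
  }
  block$forward(deep, current, shallow, training)
}

# ---- necks -----------------------------------------------------------------

#' Build the neck network
#'
#' For `pan_baseline`: the reference top-down/bottom-up path aggregation
#' with nearest-neighbour upsampling and C2f fusion blocks. For
#' `efficient_rep_bipan`: top-down bidirectional fusion (using the P3- and
#' P2-level backbone taps as the shallow inputs) followed by RepBlocks, and
#' a bottom-up path of stride-2 convolutions, concatenation with the
#' reduced maps, and RepBlocks.
#'
#' @param cfg a [model_config()].
#' @param backbone_channels named integer vector with P2/P3/P4/P5 channels.
#' @return neck environment with `$forward(feats, training)` returning a
#'   list of three maps at strides 8/16/32 and `$channels`.
#' @export
build_neck <- function(cfg, backbone_channels) {
  ch <- backbone_channels
  if (!all(c("P3", "P4", "P5") %in% names(ch))) {
    stop("configuration error: backbone taps P3/P4/P5 required")
  }
  nk <- new.env(parent = emptyenv())
  if (cfg$neck == "pan_baseline") {
    c3 <- ch[["P3"]]; c4 <- ch[["P4"]]; c5 <- ch[["P5"]]
    n <- scaled_depth(3, cfg)
    nk$td4 <- c2f_block(c5 + c4, c4, n, FALSE)
    nk$td3 <- c2f_block(c4 + c3, c3, n, FALSE)
    nk$dn3 <- conv_block(c3, c3, 3L, 2L)
    nk$bu4 <- c2f_block(c3 + c4, c4, n, FALSE)
    nk$dn4 <- conv_block(c4, c4, 3L, 2L)
    nk$bu5 <- c2f_block(c4 + c5, c5, n, FALSE)
    nk$modules <- list(nk$td4, nk$td3, nk$dn3, nk$bu4, nk$dn4, nk$bu5)
    nk$channels <- c(c3, c4, c5)
    nk$forward <- function(feats, training) {
      f4 <- nk$td4$forward(
        op_concat(list(op_upsample2(feats$P5), feats$P4)), training)
      f3 <- nk$td3$forward(
        op_concat(list(op_upsample2(f4), feats$P3)), training)
      n4 <- nk$bu4$forward(
        op_concat(list(nk$dn3$forward(f3, training), f4)), training)
      n5 <- nk$bu5$forward(
        op_concat(list(nk$dn4$forward(n4, training), feats$P5)), training)
      list(f3, n4, n5)
    }
    nk$trace <- function(shapes) {
      s3 <- shapes$P3; s4 <- shapes$P4; s5 <- shapes$P5
      macs <- 0
      t4 <- nk$td4$trace(c(s5[1] + s4[1], s4[2:3])); macs <- macs + t4$macs
      t3 <- nk$td3$trace(c(t4$shape[1] + s3[1], s3[2:3])); macs <- macs + t3$macs
      macs <- macs + nk$dn3$trace(t3$shape)$macs
      b4 <- nk$bu4$trace(c(s3[1] + t4$shape[1], s4[2:3])); macs <- macs + b4$macs
      macs <- macs + nk$dn4$trace(b4$shape)$macs
      b5 <- nk$bu5$trace(c(b4$shape[1] + s5[1], s5[2:3])); macs <- macs + b5$macs
      list(shapes = list(t3$shape, b4$shape, b5$shape), macs = macs)
    }
  } else {
    if (!"P2" %in% names(ch)) {
      stop("configuration error: the bidirectional neck needs the P2 tap")
    }
    w <- cfg$neck_widths
    dep <- cfg$repblock_depths
    nk$reduce5 <- conv_block(ch[["P5"]], w$w4, 1L)
    nk$bif4 <- bifusion_block(w$w4, ch[["P4"]], ch[["P3"]], w$w4)
    nk$rb4 <- rep_block(w$w4, w$p4, dep[1])
    nk$reduce4 <- conv_block(w$p4, w$w3, 1L)
    nk$bif3 <- bifusion_block(w$w3, ch[["P3"]], ch[["P2"]], w$w3)
    nk$rb3 <- rep_block(w$w3, w$p3, dep[2])
    nk$dn3 <- conv_block(w$p3, w$d3, 3L, 2L)
    nk$rbn4 <- rep_block(w$d3 + w$w3, w$p4, dep[3])
    nk$dn4 <- conv_block(w$p4, w$d4, 3L, 2L)
    nk$rbn5 <- rep_block(w$d4 + w$w4, w$p5, dep[4])
    nk$modules <- list(nk$reduce5, nk$bif4, nk$rb4, nk$reduce4, nk$bif3,
                       nk$rb3, nk$dn3, nk$rbn4, nk$dn4, nk$rbn5)
    nk$channels <- c(w$p3, w$p4, w$p5)
    nk$forward <- function(feats, training) {
      r5 <- nk$reduce5$forward(feats$P5, training)
      f4 <- nk$rb4$forward(
        nk$bif4$forward(r5, feats$P4, feats$P3, training), training)
      r4 <- nk$reduce4$forward(f4, training)
      f3 <- nk$rb3$forward(
        nk$bif3$forward(r4, feats$P3, feats$P2, training), training)
      n4 <- nk$rbn4$forward(
        op_concat(list(nk$dn3$forward(f3, training), r4)), training)
      n5 <- nk$rbn5$forward(
        op_concat(list(nk$dn4$forward(n4, training), r5)), training)
      list(f3, n4, n5)
    }
    nk$trace <- function(shapes) {
      macs <- 0
      step <- function(m, s) {
        t <- m$trace(s); macs <<- macs + t$macs; t$shape
      }
      r5 <- step(nk$reduce5, shapes$P5)
      f4 <- step(nk$rb4, step(nk$bif4, shapes$P4))
      r4 <- step(nk$reduce4, f4)
      f3 <- step(nk$rb3, step(nk$bif3, shapes$P3))
      d3 <- step(nk$dn3, f3)
      n4 <- step(nk$rbn4, c(d3[1] + r4[1], d3[2:3]))
      d4 <- step(nk$dn4, n4)
      n5 <- step(nk$rbn5, c(d4[1] + r5[1], d4[2:3]))
      list(shapes = list(f3, n4, n5), macs = macs)
    }
  }
  nk
}

# ---- head ------------------------------------------------------------------

#' Build the decoupled pose head
#'
#' Per pyramid level: a box branch emitting `4 * reg_max` distribution
#' logits, a class branch emitting `num_classes` logits, and a keypoint
#' branch emitting `num_keypoints * keypoint_dims` values per cell.
#'
#' @param cfg a [model_config()].
#' @param channels integer vector of the three neck output channels.
#' @return head environment.
#' @export
build_head <- function(cfg, channels) {
  nk_out <- cfg$num_keypoints * cfg$keypoint_dims
  c2 <- max(16L, channels[1] %/% 4L, 4L * cfg$reg_max)
  c3 <- max(channels[1], min(cfg$num_classes, 100L))
  c4 <- max(channels[1] %/% 4L, nk_out)
  hd <- new.env(parent = emptyenv())
  hd$channels <- channels
  branch <- function(cin, cmid, cout_) {
    list(conv_block(cin, cmid, 3L), conv_block(cmid, cmid, 3L),
         conv_plain(cmid, cout_, 1L))
  }
  hd$box <- lapply(channels, branch, cmid = c2, cout_ = 4L * cfg$reg_max)
  hd$cls <- lapply(channels, branch, cmid = c3, cout_ = cfg$num_classes)
  hd$kpt <- lapply(channels, branch, cmid = c4, cout_ = nk_out)
  hd$modules <- unlist(c(hd$box, hd$cls, hd$kpt), recursive = FALSE)
  run_branch <- function(br, x, training) {
    br[[3]]$forward(br[[2]]$forward(br[[1]]$forward(x, training), training),
                    training)
  }
  hd$forward <- function(maps, training) {
    lapply(seq_along(maps), function(i) {
      list(box = run_branch(hd$box[[i]], maps[[i]], training),
           cls = run_branch(hd$cls[[i]], maps[[i]], training),
           kpt = run_branch(hd$kpt[[i]], maps[[i]], training))
    })
  }
  hd$trace <- function(shapes) {
    macs <- 0
    for (i in seq_along(shapes)) {
      s <- shapes[[i]]
      for (br in list(hd$box[[i]], hd$cls[[i]], hd$kpt[[i]])) {
        ss <- s
        for (m in br) {
          t <- m$trace(ss); macs <- macs + t$macs; ss <- t$shape
        }
      }
    }
    list(macs = macs)
  }
  hd
}

# ---- whole model -----------------------------------------------------------

#' Assemble a pose model
#'
#' @param cfg a [model_config()].
#' @return model environment with `$backbone`, `$neck`, `$head`, a
#'   `$training` flag and the stride vector `c(8, 16, 32)`.
#' @export
build_model <- function(cfg = model_config()) {
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$backbone <- build_backbone(cfg)
  model$neck <- build_neck(cfg, model$backbone$channels)
  model$head <- build_head(cfg, model$neck$channels)
  model$strides <- c(8L, 16L, 32L)
  model$training <- FALSE
  model$reparameterized <- FALSE
  model$root <- container_module(c(model$backbone$modules,
                                   model$neck$modules, model$head$modules))
  class(model) <- "cp_pose_model"
  model
}

#' Switch a model between training and inference mode
#' @param model a pose model.
#' @param training logical.
#' @export
set_training <- function(model, training) {
  model$training <- isTRUE(training)
  invisible(model)
}

#' Run the model on a batch of images
#'
#' @param model a pose model.
#' @param x array of dim (3, H, W, N), H and W divisible by 32.
#' @param training override of the model's mode.
#' @return a `cp_dense_prediction`: per-level list of raw `box`, `cls`,
#'   `kpt` outputs with stride and input-size attributes.
#' @export
forward_model <- function(model, x, training = model$training) {
  feats <- model$backbone$forward(x, training)
  maps <- model$neck$forward(feats, training)
  out <- model$head$forward(maps, training)
  structure(out, strides = model$strides,
            input_hw = map_dims(node_value(x))[2:3],
            reg_max = model$cfg$reg_max,
            num_keypoints = model$cfg$num_keypoints,
            class = "cp_dense_prediction")
}

#' Count learnable parameters
#'
#' @param x a pose model or any single module.
#' @return exact number of learnable scalars.
#' @export
count_parameters <- function(x) {
  root <- if (inherits(x, "cp_pose_model")) x$root else x
  sum(vapply(module_params(root), function(p) length(p$value), numeric(1)))
}

#' Count floating-point operations
#'
#' One multiply-accumulate counts as two floating-point operations; the
#' count covers convolution-type layers at batch 1 for a square input, on
#' the model's current topology (fused or multibranch).
#'
#' @param x a pose model or a single module.
#' @param input_size square input edge in pixels.
#' @return total operations in GFLOPs (units of 1e9).
#' @export
count_flops <- function(x, input_size = 640L) {
  if (inherits(x, "cp_pose_model")) {
    bt <- x$backbone$trace(input_size)
    nt <- x$neck$trace(bt$shapes)
    ht <- x$head$trace(nt$shapes)
    return(2 * (bt$macs + nt$macs + ht$macs) / 1e9)
  }
  if (is.null(x$trace)) stop("unsupported layer: no trace available")
  cin <- if (!is.null(x$cin)) x$cin else stop("unsupported layer")
  2 * x$trace(c(cin, input_size, input_size))$macs / 1e9
}

# ---- decoding --------------------------------------------------------------

#' A detected or annotated cattle instance
#'
#' @param box numeric length 4: (x, y, w, h) in pixels, top-left corner.
#' @param score confidence in `[0, 1]`.
#' @param keypoints 16 x 3 matrix of (x, y, v); v in 0/1/2.
#' @return an object of class `keypoint_instance`.
#' @export
keypoint_instance <- function(box, score, keypoints) {
  keypoints <- as.matrix(keypoints)
  if (nrow(keypoints) != 16L || ncol(keypoints) != 3L) {
    stop("keypoints must be a 16 x 3 matrix")
  }
  structure(list(box = as.numeric(box), score = as.numeric(score),
                 keypoints = keypoints), class = "keypoint_instance")
}

softmax_cols <- function(m) {
  e <- exp(m - matrix(apply(m, 2, max), nrow(m), ncol(m), byrow = TRUE))
  e / matrix(colSums(e), nrow(m), ncol(m), byrow = TRUE)
}

box_iou_xyxy <- function(a, b) {
  ix <- pmax(0, pmin(a[3], b[, 3]) - pmax(a[1], b[, 1]))
  iy <- pmax(0, pmin(a[4], b[, 4]) - pmax(a[2], b[, 2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  ifelse(ua > 0, inter / ua, 0)
}

#' Decode dense predictions into instances
#'
#' Box distributions collapse to their expected side distances and map to
#' pixel boxes; keypoint offsets follow the cell-relative `x*2 + (anchor -
#' 0.5)` convention times the stride; visibility passes through a sigmoid.
#' Boxes then go through greedy non-maximum suppression.
#'
#' @param pred a `cp_dense_prediction` (batch of 1).
#' @param conf_threshold,iou_threshold thresholds in `[0, 1]`.
#' @return list of [keypoint_instance()], sorted by descending confidence.
#' @export
decode <- function(pred, conf_threshold = 0.25, iou_threshold = 0.5) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1,
            iou_threshold >= 0, iou_threshold <= 1)
  strides <- attr(pred, "strides")
  reg_max <- attr(pred, "reg_max")
  nk <- attr(pred, "num_keypoints")
  boxes <- NULL; scores <- NULL; kpts <- NULL
  for (i in seq_along(pred)) {
    lv <- pred[[i]]
    s <- strides[i]
    bx <- node_value(lv$box); cl <- node_value(lv$cls); kp <- node_value(lv$kpt)
    d <- dim(bx)
    h <- d[2]; w <- d[3]
    ncell <- h * w
    sc <- sigmoid_(apply(matrix(cl, dim(cl)[1], ncell), 2, max))
    keep <- which(sc >= conf_threshold & sc > 0)
    if (conf_threshold >= 1) keep <- integer(0)
    if (length(keep) == 0L) next
    gy <- (keep - 1L) %% h        # 0-based row
    gx <- (keep - 1L) %/% h       # 0-based col
    bm <- matrix(bx, 4L * reg_max, ncell)[, keep, drop = FALSE]
    dists <- matrix(0, 4, length(keep))
    for (side in 1:4) {
      logits <- bm[((side - 1L) * reg_max + 1L):(side * reg_max), ,
                   drop = FALSE]
      dists[side, ] <- colSums(softmax_cols(logits) * (seq_len(reg_max) - 1L))
    }
    cx <- gx + 0.5; cy <- gy + 0.5
    x1 <- (cx - dists[1, ]) * s; y1 <- (cy - dists[2, ]) * s
    x2 <- (cx + dists[3, ]) * s; y2 <- (cy + dists[4, ]) * s
    km <- matrix(kp, dim(kp)[1], ncell)[, keep, drop = FALSE]
    kx <- (km[seq(1, 3 * nk, by = 3), , drop = FALSE] * 2 +
             matrix(gx, nk, length(keep), byrow = TRUE)) * s
    ky <- (km[seq(2, 3 * nk, by = 3), , drop = FALSE] * 2 +
             matrix(gy, nk, length(keep), byrow = TRUE)) * s
    kv <- sigmoid_(km[seq(3, 3 * nk, by = 3), , drop = FALSE])
    boxes <- rbind(boxes, cbind(x1, y1, x2, y2))
    scores <- c(scores, sc[keep])
    kpts <- c(kpts, lapply(seq_along(keep), function(j) {
      cbind(kx[, j], ky[, j], ifelse(kv[, j] >= 0.5, 2, 1))
    }))
  }
  if (is.null(boxes) || nrow(boxes) == 0L) return(list())
  ord <- order(scores, decreasing = TRUE)
  keep <- logical(length(ord))
  taken <- NULL
  for (j in ord) {
    if (!is.null(taken) &&
        any(box_iou_xyxy(boxes[j, ], taken) > iou_threshold)) next
    keep[j] <- TRUE
    taken <- rbind(taken, boxes[j, , drop = FALSE])
  }
  sel <- ord[keep[ord]]
  lapply(sel, function(j) {
    b <- boxes[j, ]
    keypoint_instance(c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
                      scores[j], kpts[[j]])
  })
}

#' Detect cattle instances on one image
#'
#' @param model a pose model.
#' @param image array (H, W, 3) with values in `[0, 1]`.
#' @param conf_threshold,iou_threshold decoding thresholds.
#' @return list of [keypoint_instance()].
#' @export
predict_instances <- function(model, image, conf_threshold = 0.25,
                              iou_threshold = 0.5) {
  x <- image_to_input(image)
  pred <- forward_model(model, x, training = FALSE)
  decode(pred, conf_threshold, iou_threshold)
}

#' Convert an (H, W, 3) image to network input layout
#' @param image array (H, W, 3) or (H, W).
#' @return array (3, H, W, 1).
#' @export
image_to_input <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) image <- array(rep(image, 3), c(d, 3L))
  x <- aperm(image, c(3, 1, 2))
  dim(x) <- c(dim(x), 1L)
  x
}
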