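# Structural reparameterization. A RepVGG-style unit is trained as the sum
# of three parallel branches -- 3x3 conv + BN, 1x1 conv + BN, and (when the
# shape permits) an identity BN -- followed by a ReLU. For inference, the
# branches collapse algebraically into one 3x3 convolution with bias:
# BN folds into the preceding convolution as a per-output-channel affine
# map, a 1x1 kernel embeds into the centre tap of a 3x3 kernel, and the
# identity becomes a Dirac kernel. The fused unit is exactly forward
# equivalent (up to floating-point accumulation order).

#' Convolution kernel descriptor
#'
#' @param weights array of dim (out_channels, in_channels/groups, k, k).
#' @param stride,padding,groups convolution hyperparameters.
#' @return an object of class `conv_kernel`.
#' @export
conv_kernel <- function(weights, stride = 1L, padding = NULL, groups = 1L) {
  d <- dim(weights)
  if (is.null(d) || length(d) != 4L || d[3] != d[4]) {
    stop("weights must be a (cout, cin/groups, k, k) array")
  }
  if (!d[3] %in% c(1L, 3L)) stop("kernel size must be 1 or 3")
  if (is.null(padding)) padding <- (d[3] - 1L) %/% 2L
  structure(list(weights = weights, stride = as.integer(stride),
                 padding = as.integer(padding), groups = as.integer(groups)),
            class = "conv_kernel")
}

#' Batch-normalization parameters
#'
#' @param gamma,beta,running_mean,running_var numeric vectors of length
#'   out_channels.
#' @param eps positive stabilizer.
#' @return an object of class `bn_params`.
#' @export
bn_params <- function(gamma, beta, running_mean, running_var, eps = 1e-3) {
  n <- length(gamma)
  if (length(beta) != n || length(running_mean) != n ||
      length(running_var) != n) {
    stop("batch-norm vectors must share one length")
  }
  if (any(running_var < 0)) stop("invalid parameters: negative running variance")
  structure(list(gamma = gamma, beta = beta, running_mean = running_mean,
                 running_var = running_var, eps = eps), class = "bn_params")
}

#' Fold batch normalization into a preceding convolution
#'
#' Returns the kernel and bias of the single convolution that reproduces
#' `bn(conv(x))` in inference mode: `W' = W * gamma / sqrt(var + eps)` per
#' output channel and `b' = beta - gamma * mean / sqrt(var + eps)`.
#'
#' @param kernel a [conv_kernel()].
#' @param bn a [bn_params()] whose vectors match the kernel's out_channels.
#' @return list with elements `kernel` (a `conv_kernel`) and `bias`.
#' @export
fuse_conv_bn <- function(kernel, bn) {
  d <- dim(kernel$weights)
  if (length(bn$gamma) != d[1]) {
    stop("batch-norm length does not match out_channels")
  }
  if (any(bn$running_var < 0)) {
    stop("invalid parameters: negative running variance")
  }
  scale <- bn$gamma / sqrt(bn$running_var + bn$eps)
  w <- kernel$weights * scale  # recycles over the fastest (out-channel) dim
  bias <- bn$beta - bn$gamma * bn$running_mean / sqrt(bn$running_var + bn$eps)
  list(kernel = conv_kernel(w, kernel$stride, kernel$padding, kernel$groups),
       bias = bias)
}

#' Embed a 1x1 kernel into an equivalent 3x3 kernel
#'
#' The 1x1 weights move to the centre tap; with padding increased from 0 to
#' 1 the two convolutions are forward equivalent.
#'
#' @param kernel a 1x1 [conv_kernel()].
#' @return a 3x3 `conv_kernel`.
#' @export
embed_1x1_in_3x3 <- function(kernel) {
  d <- dim(kernel$weights)
  if (d[3] != 1L) stop("invalid argument: kernel size must be 1")
  w <- array(0, c(d[1], d[2], 3L, 3L))
  w[, , 2, 2] <- kernel$weights[, , 1, 1]
  conv_kernel(w, kernel$stride, 1L, kernel$groups)
}

#' Dirac 3x3 kernel implementing the identity map
#'
#' @param channels number of channels.
#' @param groups channel groups; channels must be divisible by groups.
#' @return a 3x3 `conv_kernel` which, applied with stride 1 and padding 1,
#'   returns its input unchanged.
#' @export
identity_as_3x3 <- function(channels, groups = 1L) {
  if (channels %% groups != 0L) {
    stop("invalid argument: channels not divisible by groups")
  }
  cg <- channels %/% groups
  w <- array(0, c(channels, cg, 3L, 3L))
  for (o in seq_len(channels)) {
    w[o, ((o - 1L) %% cg) + 1L, 2, 2] <- 1
  }
  conv_kernel(w, 1L, 1L, groups)
}

# ---- multibranch unit ------------------------------------------------------

#' Trainable multibranch (RepVGG-style) convolution unit
#'
#' Branches: 3x3 conv + BN, 1x1 conv + BN, and an identity BN when
#' `cin == cout` and `stride == 1`. Branch outputs are summed and passed
#' through a ReLU.
#'
#' @param cin,cout channel counts.
#' @param stride convolution stride.
#' @return a module.
#' @export
repvgg_unit <- function(cin, cout, stride = 1L) {
  m <- new_module("repvgg_unit")
  m$cin <- cin; m$cout <- cout; m$stride <- as.integer(stride)
  m$fused <- FALSE
  m$has_identity <- (cin == cout && stride == 1L)
  m$w3 <- cp_param(init_conv_weight(cout, cin, 3L))
  m$g3 <- cp_param(rep(1, cout)); m$b3 <- cp_param(numeric(cout))
  m$bn3 <- new_bn_state(cout)
  m$w1 <- cp_param(init_conv_weight(cout, cin, 1L))
  m$g1 <- cp_param(rep(1, cout)); m$b1 <- cp_param(numeric(cout))
  m$bn1 <- new_bn_state(cout)
  m$own <- list(w3 = m$w3, g3 = m$g3, b3 = m$b3,
                w1 = m$w1, g1 = m$g1, b1 = m$b1)
  if (m$has_identity) {
    m$gid <- cp_param(rep(1, cout)); m$bid <- cp_param(numeric(cout))
    m$bnid <- new_bn_state(cout)
    m$own <- c(m$own, list(gid = m$gid, bid = m$bid))
  }
  m$forward <- function(x, training) {
    if (m$fused) {
      return(op_relu(op_conv2d(x, m$wf, m$bf, stride = m$stride, pad = 1L)))
    }
    y3 <- op_batchnorm(op_conv2d(x, m$w3, stride = m$stride, pad = 1L),
                       m$g3, m$b3, m$bn3, training)
    y1 <- op_batchnorm(op_conv2d(x, m$w1, stride = m$stride, pad = 0L),
                       m$g1, m$b1, m$bn1, training)
    y <- op_add(y3, y1)
    if (m$has_identity) {
      yid <- op_batchnorm(x, m$gid, m$bid, m$bnid, training)
      y <- op_add(y, yid)
    }
    op_relu(y)
  }
  m$trace <- function(shape) {
    o <- conv_out_hw(shape[2], shape[3], 3L, m$stride, 1L)
    macs <- as.numeric(m$cout) * m$cin * 9 * o[1] * o[2]
    if (!m$fused) macs <- macs + as.numeric(m$cout) * m$cin * o[1] * o[2]
    list(shape = c(m$cout, o), macs = macs)
  }
  m
}

#' Fuse a multibranch unit into a single 3x3 convolution
#'
#' Sums the branch-fused 3x3 kernels and biases; the resulting unit (one
#' convolution with bias plus ReLU) is forward-equivalent to the branch sum
#' in inference mode.
#'
#' @param unit a [repvgg_unit()] with frozen statistics (inference mode).
#' @return the same module, mutated in place to its fused form.
#' @export
reparameterize_unit <- function(unit) {
  if (!inherits(unit, "repvgg_unit")) stop("not a reparameterizable unit")
  if (unit$fused) stop("state error: unit is already fused")
  f3 <- fuse_conv_bn(
    conv_kernel(unit$w3$value, unit$stride, 1L),
    bn_params(unit$g3$value, unit$b3$value,
              unit$bn3$running_mean, unit$bn3$running_var))
  f1 <- fuse_conv_bn(
    conv_kernel(unit$w1$value, unit$stride, 0L),
    bn_params(unit$g1$value, unit$b1$value,
              unit$bn1$running_mean, unit$bn1$running_var))
  w <- f3$kernel$weights + embed_1x1_in_3x3(f1$kernel)$weights
  b <- f3$bias + f1$bias
  if (unit$has_identity) {
    fid <- fuse_conv_bn(
      identity_as_3x3(unit$cout),
      bn_params(unit$gid$value, unit$bid$value,
                unit$bnid$running_mean, unit$bnid$running_var))
    w <- w + fid$kernel$weights
    b <- b + fid$bias
  }
  unit$wf <- cp_param(w)
  unit$bf <- cp_param(b)
  unit$own <- list(wf = unit$wf, bf = unit$bf)
  unit$fused <- TRUE
  invisible(unit)
}

#' Stack of reparameterizable units
#'
#' The first unit may change the channel count; the remaining `n - 1` units
#' keep it, so they carry identity branches.
#'
#' @param cin,cout channel counts.
#' @param n number of units (at least 1).
#' @return a module.
#' @export
rep_block <- function(cin, cout, n = 1L) {
  m <- new_module("rep_block")
  m$units <- c(list(repvgg_unit(cin, cout)),
               lapply(seq_len(max(0L, n - 1L)), function(i) {
                 repvgg_unit(cout, cout)
               }))
  m$children <- m$units
  m$forward <- function(x, training) {
    for (u in m$units) x <- u$forward(x, training)
    x
  }
  m$trace <- function(shape) {
    macs <- 0
    for (u in m$units) {
      t <- u$trace(shape)
      shape <- t$shape
      macs <- macs + t$macs
    }
    list(shape = shape, macs = macs)
  }
  m
}

collect_rep_units <- function(m) {
  out <- list()
  if (inherits(m, "repvgg_unit")) out <- c(out, list(m))
  for (ch in m$children) out <- c(out, collect_rep_units(ch))
  out
}

#' Reparameterize every multibranch unit of a model
#'
#' @param model an assembled pose model (see [build_model()]), in inference
#'   mode. Whole-network outputs before and after fusion agree to numerical
#'   accumulation error. A model without reparameterizable units passes
#'   through unchanged; calling twice is a state error.
#' @return the model, mutated in place.
#' @export
reparameterize_network <- function(model) {
  if (isTRUE(model$training)) {
    stop("state error: model must be in inference mode before fusing")
  }
  if (isTRUE(model$reparameterized)) {
    stop("state error: model is already reparameterized")
  }
  for (u in collect_rep_units(model$root)) {
    if (!u$fused) reparameterize_unit(u)
  }
  model$reparameterized <- TRUE
  invisible(model)
}
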