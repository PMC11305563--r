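# Network building blocks. A module is an environment with closures:
#   $forward(x, training)  -- x is an array or graph node
#   $params()              -- named list of cp_param nodes
#   $trace(shape)          -- list(shape = c(C, H, W), macs = <count>)
# plus whatever state the block needs. MAC counts cover convolution-type
# layers only (one multiply-accumulate per kernel tap per output position);
# normalization and activations are excluded from the accounting.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$own <- list()
  m$children <- list()
  class(m) <- c(type, "cp_module")
  m
}

module_params <- function(m) {
  out <- m$own
  for (ch in m$children) out <- c(out, module_params(ch))
  out
}

init_conv_weight <- function(cout, cin_g, k) {
  fan_in <- cin_g * k * k
  array(stats::rnorm(cout * cin_g * k * k, sd = sqrt(2 / fan_in)),
        c(cout, cin_g, k, k))
}

new_bn_state <- function(c) {
  s <- new.env(parent = emptyenv())
  s$running_mean <- numeric(c)
  s$running_var <- rep(1, c)
  s
}

apply_act <- function(x, act) {
  switch(act, silu = op_silu(x), relu = op_relu(x), none = x,
         stop("unknown activation: ", act))
}

# Convolution + batch norm + activation (the standard block of the family).
conv_block <- function(cin, cout, k, stride = 1L, act = "silu",
                       pad = NULL) {
  m <- new_module("conv_block")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride
  m$pad <- if (is.null(pad)) (k - 1L) %/% 2L else pad
  m$act <- act
  m$w <- cp_param(init_conv_weight(cout, cin, k))
  m$gamma <- cp_param(rep(1, cout))
  m$beta <- cp_param(numeric(cout))
  m$bn <- new_bn_state(cout)
  m$own <- list(w = m$w, gamma = m$gamma, beta = m$beta)
  m$forward <- function(x, training) {
    y <- op_conv2d(x, m$w, stride = m$stride, pad = m$pad)
    y <- op_batchnorm(y, m$gamma, m$beta, m$bn, training)
    apply_act(y, m$act)
  }
  m$trace <- function(shape) {
    o <- conv_out_hw(shape[2], shape[3], m$k, m$stride, m$pad)
    list(shape = c(m$cout, o),
         macs = as.numeric(m$cout) * m$cin * m$k^2 * o[1] * o[2])
  }
  m
}

# Plain convolution with bias, no norm, no activation (head outputs,
# fused rep units use their own block below).
conv_plain <- function(cin, cout, k, stride = 1L, pad = NULL,
                       act = "none") {
  m <- new_module("conv_plain")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride
  m$pad <- if (is.null(pad)) (k - 1L) %/% 2L else pad
  m$act <- act
  m$w <- cp_param(init_conv_weight(cout, cin, k))
  m$b <- cp_param(numeric(cout))
  m$own <- list(w = m$w, b = m$b)
  m$forward <- function(x, training) {
    apply_act(op_conv2d(x, m$w, m$b, stride = m$stride, pad = m$pad), m$act)
  }
  m$trace <- function(shape) {
    o <- conv_out_hw(shape[2], shape[3], m$k, m$stride, m$pad)
    list(shape = c(m$cout, o),
         macs = as.numeric(m$cout) * m$cin * m$k^2 * o[1] * o[2])
  }
  m
}

# Transpose convolution (kernel 2, stride 2) + BN + activation: the learned
# 2x upsampler of the bidirectional fusion unit.
deconv_block <- function(cin, cout, act = "silu") {
  m <- new_module("deconv_block")
  m$cin <- cin; m$cout <- cout; m$act <- act
  m$w <- cp_param(array(stats::rnorm(cin * cout * 4, sd = sqrt(2 / cin)),
                        c(cin, cout, 2, 2)))
  m$gamma <- cp_param(rep(1, cout))
  m$beta <- cp_param(numeric(cout))
  m$bn <- new_bn_state(cout)
  m$own <- list(w = m$w, gamma = m$gamma, beta = m$beta)
  m$forward <- function(x, training) {
    y <- op_conv_transpose2x(x, m$w)
    y <- op_batchnorm(y, m$gamma, m$beta, m$bn, training)
    apply_act(y, m$act)
  }
  m$trace <- function(shape) {
    list(shape = c(m$cout, shape[2] * 2L, shape[3] * 2L),
         macs = as.numeric(m$cin) * m$cout * 4 * shape[2] * shape[3])
  }
  m
}

# Residual bottleneck: two 3x3 conv blocks, optional identity shortcut.
bottleneck_block <- function(c, shortcut = TRUE) {
  m <- new_module("bottleneck_block")
  m$cv1 <- conv_block(c, c, 3L)
  m$cv2 <- conv_block(c, c, 3L)
  m$shortcut <- shortcut
  m$children <- list(m$cv1, m$cv2)
  m$forward <- function(x, training) {
    y <- m$cv2$forward(m$cv1$forward(x, training), training)
    if (m$shortcut) op_add(x, y) else y
  }
  m$trace <- function(shape) {
    t1 <- m$cv1$trace(shape)
    t2 <- m$cv2$trace(t1$shape)
    list(shape = t2$shape, macs = t1$macs + t2$macs)
  }
  m
}

# Cross-stage-partial block: split channels after a 1x1 expansion, run part
# through n bottlenecks, concatenate every intermediate, project with 1x1.
c2f_block <- function(cin, cout, n = 1L, shortcut = FALSE) {
  m <- new_module("c2f_block")
  c <- cout %/% 2L
  m$c <- c
  m$cv1 <- conv_block(cin, 2L * c, 1L)
  m$cv2 <- conv_block((2L + n) * c, cout, 1L)
  m$bottlenecks <- lapply(seq_len(n), function(i) bottleneck_block(c, shortcut))
  m$children <- c(list(m$cv1, m$cv2), m$bottlenecks)
  m$forward <- function(x, training) {
    y <- m$cv1$forward(x, training)
    a <- op_slice(y, seq_len(c))
    b <- op_slice(y, c + seq_len(c))
    parts <- list(a, b)
    for (bl in m$bottlenecks) {
      b <- bl$forward(b, training)
      parts <- c(parts, list(b))
    }
    m$cv2$forward(op_concat(parts), training)
  }
  m$trace <- function(shape) {
    t1 <- m$cv1$trace(shape)
    macs <- t1$macs
    bs <- c(m$c, t1$shape[2:3])
    for (bl in m$bottlenecks) {
      tb <- bl$trace(bs)
      macs <- macs + tb$macs
    }
    t2 <- m$cv2$trace(c((2L + length(m$bottlenecks)) * m$c, t1$shape[2:3]))
    list(shape = t2$shape, macs = macs + t2$macs)
  }
  m
}

# Spatial pyramid pooling (fast): serial 5x5 max pools, concatenated.
sppf_block <- function(cin, cout, k = 5L) {
  m <- new_module("sppf_block")
  ch <- cin %/% 2L
  m$k <- k
  m$cv1 <- conv_block(cin, ch, 1L)
  m$cv2 <- conv_block(ch * 4L, cout, 1L)
  m$children <- list(m$cv1, m$cv2)
  m$forward <- function(x, training) {
    y <- m$cv1$forward(x, training)
    p1 <- op_maxpool(y, m$k, 1L, (m$k - 1L) %/% 2L)
    p2 <- op_maxpool(p1, m$k, 1L, (m$k - 1L) %/% 2L)
    p3 <- op_maxpool(p2, m$k, 1L, (m$k - 1L) %/% 2L)
    m$cv2$forward(op_concat(list(y, p1, p2, p3)), training)
  }
  m$trace <- function(shape) {
    t1 <- m$cv1$trace(shape)
    t2 <- m$cv2$trace(c(4L * t1$shape[1], t1$shape[2:3]))
    list(shape = t2$shape, macs = t1$macs + t2$macs)
  }
  m
}

# Parameter-free attention inserted after backbone stages; see simam.R.
simam_block <- function(omega = 1e-4) {
  m <- new_module("simam_block")
  m$omega <- omega
  m$forward <- function(x, training) op_simam(x, m$omega)
  m$trace <- function(shape) list(shape = shape, macs = 0)
  m
}
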