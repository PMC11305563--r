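# Reverse-mode automatic differentiation over dense feature maps.
#
# Feature maps are numeric arrays with dim = c(C, H, W, N) (channel, row,
# column, sample). A computation graph node is an environment holding the
# value, its parents and a backward closure; node ids increase with creation
# order, which yields a valid topological order for the backward sweep.

.cp <- new.env(parent = emptyenv())
.cp$counter <- 0L
.cp$grad_enabled <- FALSE

new_node_id <- function() {
  .cp$counter <- .cp$counter + 1L
  .cp$counter
}

#' Enable or disable gradient recording
#'
#' While recording is disabled (the default), all tensor operations return
#' plain arrays and no graph is built, so inference costs no extra memory.
#'
#' @param enabled logical flag.
#' @return the previous setting, invisibly.
#' @export
cp_set_grad <- function(enabled) {
  old <- .cp$grad_enabled
  .cp$grad_enabled <- isTRUE(enabled)
  invisible(old)
}

#' Evaluate an expression with gradient recording switched on
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_grad <- function(expr) {
  old <- cp_set_grad(TRUE)
  on.exit(cp_set_grad(old))
  expr
}

is_node <- function(x) inherits(x, "cp_node")

#' @keywords internal
node_value <- function(x) if (is_node(x)) x$value else x

# Create a graph node. `backward` maps the output gradient to a list of
# gradients aligned with `parents` (NULL entries for non-node parents).
make_node <- function(value, parents = list(), backward = NULL,
                      trainable = FALSE) {
  e <- new.env(parent = emptyenv())
  e$id <- new_node_id()
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$trainable <- trainable
  e$grad <- NULL
  class(e) <- "cp_node"
  e
}

#' Create a trainable parameter node
#' @param value numeric array of initial values.
#' @return a `cp_node` flagged as trainable.
#' @export
cp_param <- function(value) make_node(value, trainable = TRUE)

#' Wrap a plain array as a graph leaf
#' @param value numeric array.
#' @param requires_grad record gradients for this leaf?
#' @return a `cp_node`.
#' @export
cp_tensor <- function(value, requires_grad = FALSE) {
  make_node(value, trainable = requires_grad)
}

recording <- function(...) {
  .cp$grad_enabled && any(vapply(list(...), is_node, logical(1)))
}

#' Backward sweep from one or more seed gradients
#'
#' Accumulates gradients into every reachable trainable node's `$grad`
#' field (added to any gradient already present, so calls can accumulate
#' over a batch).
#'
#' @param seeds list of `list(node = <cp_node>, grad = <array>)` entries.
#' @export
cp_backward <- function(seeds) {
  grads <- new.env(parent = emptyenv())
  nodes <- new.env(parent = emptyenv())
  pending <- integer(0)
  add_grad <- function(node, g) {
    key <- as.character(node$id)
    if (is.null(grads[[key]])) {
      grads[[key]] <- g
      nodes[[key]] <- node
      pending[length(pending) + 1L] <<- node$id
    } else {
      grads[[key]] <- grads[[key]] + g
    }
  }
  for (s in seeds) add_grad(s$node, s$grad)
  # Pop in descending id order: a node's parents were created before it,
  # so every gradient into a node has arrived by the time it is popped.
  while (length(pending)) {
    i <- which.max(pending)
    key <- as.character(pending[i])
    pending <- pending[-i]
    node <- nodes[[key]]
    g <- grads[[key]]
    rm(list = key, envir = grads)
    if (node$trainable) {
      node$grad <- if (is.null(node$grad)) g else node$grad + g
    }
    if (is.null(node$backward)) next
    pgs <- node$backward(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is_node(p) && !is.null(pgs[[j]])) add_grad(p, pgs[[j]])
    }
  }
  invisible(NULL)
}

#' Reset stored gradients on a list of parameters
#' @param params list of `cp_node` parameters.
#' @export
cp_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

map_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) {
    stop("feature maps must be 4-d arrays (C, H, W, N)")
  }
  d
}

cmat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

# ---- convolution -----------------------------------------------------------

conv_out_hw <- function(h, w, k, stride, pad) {
  c((h + 2 * pad - k) %/% stride + 1L, (w + 2 * pad - k) %/% stride + 1L)
}

conv2d_forward <- function(xv, wv, bv, stride, pad, groups) {
  d <- map_dims(xv)
  kd <- dim(wv)
  cout <- kd[1]; cing <- kd[2]; k <- kd[3]
  if (d[1] != cing * groups) stop("input channels do not match kernel")
  o <- conv_out_hw(d[2], d[3], k, stride, pad)
  if (groups == 1L) {
    patches <- cpp_im2col(xv, d[1], d[2], d[3], d[4], k, stride, pad)
    y <- matrix(wv, cout, cing * k * k) %*% patches
  } else {
    cg_out <- cout %/% groups
    patches <- vector("list", groups)
    y <- matrix(0, cout, o[1] * o[2] * d[4])
    for (g in seq_len(groups)) {
      xs <- xv[((g - 1) * cing + 1):(g * cing), , , , drop = FALSE]
      patches[[g]] <- cpp_im2col(xs, cing, d[2], d[3], d[4], k, stride, pad)
      wg <- wv[((g - 1) * cg_out + 1):(g * cg_out), , , , drop = FALSE]
      y[((g - 1) * cg_out + 1):(g * cg_out), ] <-
        matrix(wg, cg_out, cing * k * k) %*% patches[[g]]
    }
  }
  if (!is.null(bv)) y <- y + bv
  dim(y) <- c(cout, o[1], o[2], d[4])
  list(y = y, patches = if (groups == 1L) patches else NULL)
}

#' 2-d convolution
#'
#' @param x input map, array or node, dim (C, H, W, N).
#' @param w kernel, array or node, dim (Cout, Cin/groups, k, k).
#' @param b optional bias vector of length Cout.
#' @param stride,pad integer stride and zero padding.
#' @param groups channel groups; gradients are only supported for groups = 1.
#' @return output map (array or node).
#' @export
op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xv <- node_value(x); wv <- node_value(w); bv <- node_value(b)
  res <- conv2d_forward(xv, wv, bv, stride, pad, groups)
  if (!recording(x, w, b)) return(res$y)
  if (groups != 1L) stop("gradients unsupported for grouped convolution")
  d <- dim(xv); kd <- dim(wv)
  cout <- kd[1]; k <- kd[3]
  patches <- res$patches
  make_node(res$y, parents = list(x, w, b), backward = function(g) {
    gm <- cmat(g)
    dw <- NULL; dx <- NULL; db <- NULL
    if (is_node(w)) {
      dw <- gm %*% t(patches)
      dim(dw) <- kd
    }
    if (is_node(x)) {
      dcols <- t(matrix(wv, cout, kd[2] * k * k)) %*% gm
      dx <- cpp_col2im(dcols, d[1], d[2], d[3], d[4], k, stride, pad)
      dim(dx) <- d
    }
    if (!is.null(b) && is_node(b)) db <- rowSums(gm)
    list(dx, dw, db)
  })
}

#' Learned 2x upsampling (transpose convolution, kernel 2, stride 2)
#'
#' @param x input map, dim (Cin, H, W, N).
#' @param w kernel array, dim (Cin, Cout, 2, 2).
#' @param b optional bias length Cout.
#' @return map of dim (Cout, 2H, 2W, N).
#' @export
op_conv_transpose2x <- function(x, w, b = NULL) {
  xv <- node_value(x); wv <- node_value(w); bv <- node_value(b)
  d <- map_dims(xv)
  cin <- dim(wv)[1]; cout <- dim(wv)[2]
  if (d[1] != cin) stop("input channels do not match kernel")
  wm <- matrix(aperm(wv, c(2, 3, 4, 1)), cout * 4, cin)
  y4 <- wm %*% cmat(xv)
  dim(y4) <- c(cout, 2, 2, d[2], d[3], d[4])
  y <- aperm(y4, c(1, 2, 4, 3, 5, 6))
  dim(y) <- c(cout, 2 * d[2], 2 * d[3], d[4])
  if (!is.null(bv)) y <- y + as.numeric(bv)[slot_channel(dim(y))]
  if (!recording(x, w, b)) return(y)
  make_node(y, parents = list(x, w, b), backward = function(g) {
    dg <- g
    dim(dg) <- c(cout, 2, d[2], 2, d[3], d[4])
    dg <- aperm(dg, c(1, 2, 4, 3, 5, 6))
    dim(dg) <- c(cout * 4, d[2] * d[3] * d[4])
    dx <- NULL; dw <- NULL; db <- NULL
    if (is_node(x)) {
      dx <- t(wm) %*% dg
      dim(dx) <- d
    }
    if (is_node(w)) {
      dwm <- dg %*% t(cmat(xv))
      dim(dwm) <- c(cout, 2, 2, cin)
      dw <- aperm(dwm, c(4, 1, 2, 3))
    }
    if (!is.null(b) && is_node(b)) db <- rowSums(matrix(g, cout))
    list(dx, dw, db)
  })
}

# channel index helper: recycles a per-channel vector over an array
slot_channel <- function(d) rep_len(seq_len(d[1]), prod(d))

# ---- batch normalization ---------------------------------------------------

#' Batch normalization over (H, W, N) per channel
#'
#' In training mode batch statistics (population variance) are used and the
#' supplied module environment's running statistics are updated in place; in
#' inference mode the running statistics are used.
#'
#' @param x input map.
#' @param gamma,beta scale/shift parameter nodes (length C).
#' @param state environment with `running_mean`, `running_var` vectors.
#' @param training logical.
#' @param eps,momentum numeric stabilizer and running-average momentum.
#' @return normalized map.
#' @export
op_batchnorm <- function(x, gamma, beta, state, training,
                         eps = 1e-3, momentum = 0.03) {
  xv <- node_value(x)
  gv <- as.numeric(node_value(gamma)); bv <- as.numeric(node_value(beta))
  d <- map_dims(xv)
  m <- cmat(xv)
  if (training) {
    mu <- rowMeans(m)
    v <- rowMeans(m * m) - mu * mu
    v[v < 0] <- 0
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * istd
  y <- gv * xhat + bv
  dim(y) <- d
  if (!recording(x, gamma, beta)) return(y)
  make_node(y, parents = list(x, gamma, beta), backward = function(g) {
    gm <- matrix(g, d[1])
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dx <- NULL
    if (is_node(x)) {
      dxhat <- gm * gv
      if (training) {
        dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
      } else {
        dx <- istd * dxhat
      }
      dim(dx) <- d
    }
    list(dx, dgamma, dbeta)
  })
}

# ---- elementwise -----------------------------------------------------------

sigmoid_ <- function(x) 1 / (1 + exp(-x))

elementwise_op <- function(x, fn, dfn) {
  xv <- node_value(x)
  y <- fn(xv)
  if (!recording(x)) return(y)
  make_node(y, parents = list(x), backward = function(g) list(g * dfn(xv, y)))
}

#' SiLU activation x * sigmoid(x)
#' @param x input map or node.
#' @export
op_silu <- function(x) {
  elementwise_op(x, function(v) v * sigmoid_(v), function(v, y) {
    s <- sigmoid_(v)
    s * (1 + v * (1 - s))
  })
}

#' ReLU activation
#' @param x input map or node.
#' @export
op_relu <- function(x) {
  elementwise_op(x, function(v) pmax(v, 0), function(v, y) (v > 0) * 1)
}

#' Sigmoid activation
#' @param x input map or node.
#' @export
op_sigmoid <- function(x) {
  elementwise_op(x, sigmoid_, function(v, y) y * (1 - y))
}

#' Elementwise sum of two maps of identical shape
#' @param x,y maps or nodes.
#' @export
op_add <- function(x, y) {
  xv <- node_value(x); yv <- node_value(y)
  out <- xv + yv
  if (!recording(x, y)) return(out)
  make_node(out, parents = list(x, y), backward = function(g) list(g, g))
}

# ---- shape ops -------------------------------------------------------------

#' Concatenate maps along the channel dimension
#' @param xs list of maps/nodes with equal (H, W, N).
#' @export
op_concat <- function(xs) {
  vals <- lapply(xs, node_value)
  dims <- lapply(vals, map_dims)
  base <- dims[[1]][-1]
  for (dd in dims) {
    if (!all(dd[-1] == base)) stop("concat: spatial/batch dims differ")
  }
  cs <- vapply(dims, `[`, integer(1), 1L)
  total <- sum(cs)
  out <- array(0, c(total, base))
  at <- 0L
  for (i in seq_along(vals)) {
    out[(at + 1):(at + cs[i]), , , ] <- vals[[i]]
    at <- at + cs[i]
  }
  if (!.cp$grad_enabled || !any(vapply(xs, is_node, logical(1)))) return(out)
  make_node(out, parents = xs, backward = function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      if (is_node(xs[[i]])) {
        res[[i]] <- g[(at + 1):(at + cs[i]), , , , drop = FALSE]
      }
      at <- at + cs[i]
    }
    res
  })
}

#' Take a subset of channels
#' @param x map or node.
#' @param idx integer channel indices.
#' @export
op_slice <- function(x, idx) {
  xv <- node_value(x)
  d <- map_dims(xv)
  y <- xv[idx, , , , drop = FALSE]
  if (!recording(x)) return(y)
  make_node(y, parents = list(x), backward = function(g) {
    dx <- array(0, d)
    dx[idx, , , ] <- g
    list(dx)
  })
}

#' Nearest-neighbour 2x upsampling
#' @param x map or node.
#' @export
op_upsample2 <- function(x) {
  xv <- node_value(x)
  d <- map_dims(xv)
  y <- xv[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), ,
          drop = FALSE]
  if (!recording(x)) return(y)
  make_node(y, parents = list(x), backward = function(g) {
    dim(g) <- c(d[1], 2, d[2], 2, d[3], d[4])
    dx <- g[, 1, , 1, , , drop = FALSE] + g[, 2, , 1, , , drop = FALSE] +
      g[, 1, , 2, , , drop = FALSE] + g[, 2, , 2, , , drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

#' Max pooling
#' @param x map or node.
#' @param k,stride,pad pooling window, stride and padding.
#' @export
op_maxpool <- function(x, k, stride = 1L, pad = 0L) {
  xv <- node_value(x)
  d <- map_dims(xv)
  o <- conv_out_hw(d[2], d[3], k, stride, pad)
  res <- cpp_maxpool(xv, d[1], d[2], d[3], d[4], k, stride, pad)
  y <- res$value
  dim(y) <- c(d[1], o[1], o[2], d[4])
  if (!recording(x)) return(y)
  arg <- res$argmax
  make_node(y, parents = list(x), backward = function(g) {
    dx <- numeric(prod(d))
    acc <- rowsum(as.numeric(g), arg)
    dx[as.integer(rownames(acc))] <- acc
    dim(dx) <- d
    list(dx)
  })
}
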