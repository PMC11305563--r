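# SimAM: parameter-free 3-d attention. Every neuron t of a channel is
# scored by a closed-form energy derived from its separability from the
# other neurons of the same channel:
#
#   1/e_t = (t - mu)^2 / (4 * (var + omega)) + 1/2
#
# where mu and var are the channel mean and population variance over the
# M = H*W spatial positions (the target neuron included, which is the
# pooled O(M) form of the energy minimization). Features are refined by
# x * sigmoid(1/e_t); the operator holds no learnable parameters.

#' SimAM configuration
#'
#' @param omega positive regularization coefficient of the energy
#'   denominator; default `1e-4`.
#' @return an object of class `simam_config`.
#' @export
simam_config <- function(omega = 1e-4) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0) {
    stop("omega must be a single positive number")
  }
  structure(list(omega = omega), class = "simam_config")
}

as_activation_map <- function(map) {
  if (is.matrix(map)) map <- array(map, c(1L, dim(map)))
  d <- dim(map)
  if (is.null(d) || length(d) != 3L) {
    stop("an activation map must be a 3-d array (channels, height, width)")
  }
  if (!all(is.finite(map))) stop("activation map contains non-finite values")
  if (d[2] * d[3] < 2L) {
    stop("degenerate activation map: a channel needs at least 2 neurons ",
         "for its variance to be defined")
  }
  map
}

#' Per-channel mean and population variance
#'
#' @param map 3-d activation array (channels, height, width).
#' @param channel_index which channel to summarize.
#' @return list with `mean` and `variance` (population form, divisor M).
#' @export
channel_statistics <- function(map, channel_index) {
  map <- as_activation_map(map)
  d <- dim(map)
  if (channel_index < 1L || channel_index > d[1]) {
    stop("channel_index out of range")
  }
  v <- as.numeric(map[channel_index, , ])
  mu <- mean(v)
  list(mean = mu, variance = mean((v - mu)^2))
}

simam_importance_values <- function(map, omega) {
  d <- dim(map)
  m <- matrix(map, d[1], d[2] * d[3])
  mu <- rowMeans(m)
  va <- rowMeans(m * m) - mu * mu
  imp <- (m - mu)^2 / (4 * (va + omega)) + 0.5
  dim(imp) <- d
  imp
}

#' SimAM neuron importance (1 / e_t)
#'
#' @param map 3-d activation array.
#' @param config a [simam_config()].
#' @return array of the same shape; every value is at least 1/2.
#' @export
simam_importance <- function(map, config = simam_config()) {
  map <- as_activation_map(map)
  simam_importance_values(map, config$omega)
}

#' Refine an activation map with SimAM attention
#'
#' Multiplies the map elementwise with `sigmoid(importance)`. The sigmoid
#' bounds the scaling weights in `[sigmoid(1/2), 1)` without changing the
#' relative ordering of neuron importances.
#'
#' @param map 3-d activation array.
#' @param config a [simam_config()].
#' @return refined array, same shape as the input.
#' @export
simam_refine <- function(map, config = simam_config()) {
  map <- as_activation_map(map)
  map * sigmoid_(simam_importance_values(map, config$omega))
}

# Batched autodiff version operating on (C, H, W, N) maps. The gradient is
# derived from y_i = x_i * sigmoid(imp_i) with imp_i = u_i^2 / D + 1/2,
# u = x - mu, D = 4 * (var + omega):
#   dimp_i/dx_j = 2 u_i (delta_ij - 1/M) / D - 8 u_i^2 u_j / (M D^2)
#' SimAM attention over a batched feature map (autodiff op)
#' @param x map or node with dim (C, H, W, N); H*W must be at least 2.
#' @param omega regularization coefficient.
#' @export
op_simam <- function(x, omega = 1e-4) {
  xv <- node_value(x)
  d <- map_dims(xv)
  M <- d[2] * d[3]
  if (M < 2L) {
    stop("degenerate activation map: a channel needs at least 2 neurons ",
         "for its variance to be defined")
  }
  xm <- array(xv, c(d[1], M, d[4]))
  y <- array(0, d)
  ym <- array(y, c(d[1], M, d[4]))
  store <- vector("list", d[4])
  for (n in seq_len(d[4])) {
    m <- xm[, , n, drop = TRUE]
    dim(m) <- c(d[1], M)
    mu <- rowMeans(m)
    va <- rowMeans(m * m) - mu * mu
    u <- m - mu
    D <- 4 * (va + omega)
    imp <- u * u / D + 0.5
    s <- sigmoid_(imp)
    ym[, , n] <- m * s
    store[[n]] <- list(u = u, D = D, s = s)
  }
  dim(ym) <- d
  if (!recording(x)) return(ym)
  make_node(ym, parents = list(x), backward = function(g) {
    gm <- array(g, c(d[1], M, d[4]))
    dx <- array(0, c(d[1], M, d[4]))
    for (n in seq_len(d[4])) {
      st <- store[[n]]
      gn <- gm[, , n, drop = TRUE]
      dim(gn) <- c(d[1], M)
      m <- xm[, , n, drop = TRUE]
      dim(m) <- c(d[1], M)
      cc <- gn * m * st$s * (1 - st$s)
      cu_mean <- rowMeans(cc * st$u)
      cuu_mean <- rowMeans(cc * st$u * st$u)
      dx[, , n] <- st$s * gn +
        (2 / st$D) * (cc * st$u - cu_mean) -
        (8 * st$u / (st$D^2)) * cuu_mean
    }
    dim(dx) <- d
    list(dx)
  })
}
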