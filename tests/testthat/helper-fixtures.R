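# Shared fixtures: tiny model configurations, numeric gradients, naive
# oracles, and small annotation documents built in code.

toy_model_config <- function(...) {
  model_config(width_multiple = 0.125,
               neck_widths = list(w4 = 16L, w3 = 16L, d3 = 16L, d4 = 24L,
                                  p3 = 16L, p4 = 24L, p5 = 32L),
               input_size = 64L, ...)
}

toy_baseline_config <- function(...) {
  baseline_config(width_multiple = 0.125, input_size = 64L, ...)
}

# central-difference gradient of a scalar-valued function of an array
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# naive per-neuron SimAM importance: loops over every neuron, computing the
# channel statistics and the closed-form energy independently
simam_loop_oracle <- function(map, omega) {
  d <- dim(map)
  out <- array(0, d)
  for (c in seq_len(d[1])) {
    vals <- as.numeric(map[c, , ])
    mu <- mean(vals)
    va <- mean((vals - mu)^2)
    k <- 1
    for (w in seq_len(d[3])) {
      for (h in seq_len(d[2])) {
        t <- map[c, h, w]
        out[c, h, w] <- (t - mu)^2 / (4 * (va + omega)) + 0.5
        k <- k + 1
      }
    }
  }
  out
}

# O(M^2) exclude-target variant: statistics over the other M-1 neurons
simam_exclude_oracle <- function(map, omega) {
  d <- dim(map)
  out <- array(0, d)
  for (c in seq_len(d[1])) {
    vals <- as.numeric(map[c, , ])
    for (i in seq_along(vals)) {
      rest <- vals[-i]
      mu <- mean(rest)
      va <- mean((rest - mu)^2)
      out[c, , ][i] <- (vals[i] - mu)^2 / (4 * (va + omega)) + 0.5
    }
  }
  out
}

# a fully-visible instance with a simple geometric layout
make_instance <- function(cx = 100, cy = 100, size = 80, score = 1,
                          vis = rep(2L, 16)) {
  ang <- seq(0, 2 * pi, length.out = 17)[1:16]
  kp <- cbind(cx + 0.3 * size * cos(ang), cy + 0.3 * size * sin(ang), vis)
  keypoint_instance(c(cx - size / 2, cy - size / 2, size, size), score, kp)
}

make_labelme_doc <- function(width = 100, height = 100) {
  schema <- cattle_keypoint_schema()
  kp <- data.frame(name = schema,
                   x = seq(12, 55, length.out = 16),
                   y = seq(15, 58, length.out = 16),
                   v = c(rep(2L, 12), rep(1L, 4)),
                   stringsAsFactors = FALSE)
  labelme_doc("img.png", width, height, 3L,
              list(list(box = c(10, 10, 60, 60), keypoints = kp)))
}

# randomize a model's batch-norm running statistics, emulating a model
# whose statistics were frozen after training
randomize_bn_stats <- function(model) {
  for (s in cattlepose:::collect_bn_states(model$root)) {
    n <- length(s$running_mean)
    s$running_mean <- rnorm(n, sd = 0.3)
    s$running_var <- runif(n, 0.5, 1.5)
  }
  invisible(model)
}
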