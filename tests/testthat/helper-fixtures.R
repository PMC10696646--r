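# Shared fixtures, all generated in code.

# a plain record with annotations at given 0-based indices
make_test_record <- function(n_samples, ann_idx = integer(), symbols = NULL,
                             fs = 360, record_id = "test") {
  sig <- sin(2 * pi * seq_len(n_samples) / 97) * 0.1
  sig[ann_idx + 1L] <- 1  # spike at each annotated sample
  if (is.null(symbols)) symbols <- rep("N", length(ann_idx))
  ann <- data.frame(sample_index = as.integer(ann_idx), symbol = symbols,
                    raw_symbol = symbols)
  ecg_record(record_id, matrix(sig, nrow = 1), fs, annotations = ann)
}

# independent per-pixel brute-force image conversion: loops over every pixel
# and tests the quantization predicate directly
brute_force_image <- function(samples, min_limit, max_limit, h) {
  d <- max_limit - min_limit
  grid <- matrix(0L, nrow = h, ncol = length(samples))
  for (cc in seq_along(samples)) {
    r <- floor((samples[cc] - min_limit) / d * h)
    if (r < 0) r <- 0
    if (r > h - 1) r <- h - 1
    for (rr in 0:(h - 1)) grid[rr + 1L, cc] <- if (rr == r) 255L else 0L
  }
  grid
}

# a tiny network (8 x 6 input) exercising every layer type, for fast
# training-mechanics and gradient tests
tiny_net <- function(seed = 1L, with_bn = FALSE) {
  layers <- list(
    ecgbeats:::layer_conv(2L, c(3L, 3L), 1L))
  if (with_bn) layers <- c(layers, list(ecgbeats:::layer_bnorm(2L, "channel")))
  layers <- c(layers, list(
    ecgbeats:::layer_pool(),
    ecgbeats:::layer_flatten(),
    ecgbeats:::layer_dense(4L * 3L * 2L, 6L, "relu")))
  if (with_bn) layers <- c(layers, list(ecgbeats:::layer_bnorm(6L, "unit")))
  layers <- c(layers, list(ecgbeats:::layer_dense(6L, 15L, "softmax")))
  ecgbeats:::new_cnn("tiny", c(6L, 8L), layers, seed)
}

# two trivially separable 8 x 6 image classes: lit band at the top (class 0)
# vs at the bottom (class 1)
tiny_dataset <- function(n_per_class = 12, seed = 1L) {
  set.seed(seed)
  mk <- function(top) {
    g <- matrix(0L, nrow = 8, ncol = 6)
    rows <- if (top) 1:2 else 7:8
    for (cc in 1:6) g[sample(rows, 1), cc] <- 255L
    beat_image(g, c(0, 1))
  }
  images <- c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
              lapply(seq_len(n_per_class), function(i) mk(FALSE)))
  list(images = images, y = rep(c(0L, 1L), each = n_per_class))
}
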