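# closed-form parameter count for a conv/dense stack, independent of the
# package's own bookkeeping
conv_params <- function(k, cin, cout) k * k * cin * cout + cout
dense_params <- function(din, dout) din * dout + dout

test_that("proposed architecture matches its declared layer stack", {
  m <- build_proposed()
  types <- vapply(m$layers, function(l) l$type, character(1))
  expect_identical(types, c("conv", "pool", "conv", "pool", "conv", "pool",
                            "flatten", "dense", "dense", "dense", "dense"))
  expect_identical(m$input_shape, c(180L, 64L, 1L))
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_identical(vapply(convs, function(l) l$cout, integer(1)), c(8L, 16L, 32L))
  expect_identical(lapply(convs, function(l) l$k[1]), list(6L, 5L, 4L))
  dense <- Filter(function(l) l$type == "dense", m$layers)
  expect_identical(vapply(dense, function(l) l$dout, integer(1)),
                   c(512L, 256L, 128L, 15L))
  expect_identical(dense[[4]]$activation, "softmax")

  # independent hand calculation: same-padded convs, 2x2/2 pools
  # 64x180 -> 32x90 -> 16x45 -> 8x22; flatten 8*22*32 = 5632
  expected <- conv_params(6, 1, 8) + conv_params(5, 8, 16) +
    conv_params(4, 16, 32) + dense_params(5632, 512) +
    dense_params(512, 256) + dense_params(256, 128) + dense_params(128, 15)
  expect_identical(ecgbeats:::count_params(m$layers), expected)
})

test_that("baseline architecture matches its declared layer stack", {
  m <- build_baseline()
  types <- vapply(m$layers, function(l) l$type, character(1))
  expect_identical(types, c("conv", "bnorm", "conv", "bnorm", "pool",
                            "conv", "bnorm", "conv", "bnorm", "pool",
                            "conv", "bnorm", "conv", "bnorm", "pool",
                            "flatten", "dense", "bnorm", "noop", "dense"))
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_identical(vapply(convs, function(l) l$cout, integer(1)),
                   c(8L, 8L, 16L, 16L, 32L, 32L))
  expect_identical(m$input_shape, c(128L, 128L, 1L))
  expect_identical(m$layers[[20]]$dout, 15L)
  expect_identical(m$layers[[20]]$activation, "softmax")

  # hand count; batch norm contributes 2 trainable parameters per feature
  # 128x128 -> 64 -> 32 -> 16; flatten 16*16*32 = 8192
  expected <- conv_params(3, 1, 8) + conv_params(3, 8, 8) +
    conv_params(3, 8, 16) + conv_params(3, 16, 16) +
    conv_params(3, 16, 32) + conv_params(3, 32, 32) +
    dense_params(8192, 512) + dense_params(512, 15) +
    2 * (8 + 8 + 16 + 16 + 32 + 32 + 512)
  expect_identical(ecgbeats:::count_params(m$layers), expected)
})

test_that("untrained networks emit normalized 15-class distributions", {
  set.seed(3)
  for (m in list(build_proposed(seed = 2), build_baseline(seed = 2))) {
    w <- m$input_shape[1]; h <- m$input_shape[2]
    img <- signal_to_image(runif(w), 0, 1, h)
    p <- predict(m, img)
    expect_length(p$distribution, 15)
    expect_equal(sum(p$distribution), 1, tolerance = 1e-6)
    expect_true(all(p$distribution >= 0))
    expect_equal(p$confidence, unname(max(p$distribution)))
    expect_identical(p$label, class_labels()[p$class_index + 1])
  }
})

test_that("analytic gradients match numeric differentiation on a tiny net", {
  for (with_bn in c(FALSE, TRUE)) {
    m <- tiny_net(seed = 5, with_bn = with_bn)
    # move biases off zero: dark image patches otherwise give pre-activations
    # of exactly 0, where the ReLU kink makes finite differences one-sided
    set.seed(55)
    for (i in seq_along(m$layers))
      if (!is.null(m$layers[[i]]$b))
        m$layers[[i]]$b <- rnorm(length(m$layers[[i]]$b), sd = 0.3)
    ds <- tiny_dataset(n_per_class = 3, seed = 5)
    x <- ecgbeats:::images_to_array(ds$images, m$input_shape)
    y <- ds$y
    nb <- length(y)
    loss_of <- function(layers) {
      probs <- ecgbeats:::nn_forward(layers, x, training = TRUE)$out
      -mean(log(probs[cbind(seq_len(nb), y + 1L)]))
    }
    fw <- ecgbeats:::nn_forward(m$layers, x, training = TRUE)
    onehot <- matrix(0, nb, 15)
    onehot[cbind(seq_len(nb), y + 1L)] <- 1
    grads <- ecgbeats:::nn_backward(m$layers, fw$caches, (fw$out - onehot) / nb)
    eps <- 1e-5
    set.seed(6)
    for (i in seq_along(m$layers)) {
      g <- grads[[i]]
      if (is.null(g)) next
      for (fld in names(g)) {
        park <- switch(fld, W = "W", b = "b", gamma = "gamma", beta = "beta")
        vals <- m$layers[[i]][[park]]
        for (j in sample(seq_along(vals), min(4, length(vals)))) {
          lp <- m$layers; lp[[i]][[park]][j] <- vals[j] + eps
          lm <- m$layers; lm[[i]][[park]][j] <- vals[j] - eps
          num <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
          expect_equal(as.numeric(g[[fld]][j]), num, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("training is a no-op at zero epochs and deterministic under a seed", {
  m <- tiny_net(seed = 1)
  ds <- tiny_dataset()
  expect_identical(train_cnn(m, ds, epochs = 0), m)

  m1 <- train_cnn(m, ds, epochs = 3, batch_size = 8, seed = 9)
  m2 <- train_cnn(m, ds, epochs = 3, batch_size = 8, seed = 9)
  expect_equal(m1$log$loss, m2$log$loss, tolerance = 0)
  expect_equal(coef(m1), coef(m2), tolerance = 0)
})

test_that("training loss decreases on a separable set for most seeds", {
  ds <- tiny_dataset(n_per_class = 16, seed = 2)
  ok <- 0L
  for (s in 1:5) {
    m <- train_cnn(tiny_net(seed = s), ds, epochs = 5, batch_size = 8,
                   seed = s, lr = 1e-2)
    if (m$log$loss[5] < m$log$loss[1]) ok <- ok + 1L
  }
  expect_gte(ok, 4L)  # >= 90% of runs in spirit; 4/5 with this seed set
})

test_that("a tiny separable problem is learned to high held-out accuracy", {
  train <- tiny_dataset(n_per_class = 16, seed = 3)
  test <- tiny_dataset(n_per_class = 8, seed = 4)
  m <- train_cnn(tiny_net(seed = 1), train, epochs = 10, batch_size = 8,
                 seed = 1, lr = 1e-2)
  ev <- evaluate_model(m, test)
  expect_gte(ev$metrics$accuracy, 0.95)
})

test_that("geometry mismatches are rejected before any computation", {
  m <- build_proposed()
  img <- signal_to_image(runif(128), 0, 1, 128)  # baseline geometry
  expect_error(predict(m, img), "geometry")
  expect_error(train_cnn(m, list(images = list(img), y = 0L), epochs = 1),
               "geometry")
})

test_that("batch prediction preserves input order", {
  m <- tiny_net(seed = 2)
  ds <- tiny_dataset(n_per_class = 5, seed = 8)
  batch <- predict(m, ds$images)
  expect_length(batch, 10)
  singles <- lapply(ds$images, function(im) predict(m, im))
  for (k in seq_along(batch))
    expect_equal(batch[[k]]$distribution, singles[[k]]$distribution)
})

test_that("models survive a save/load round trip", {
  ds <- tiny_dataset(n_per_class = 6, seed = 1)
  m <- train_cnn(tiny_net(seed = 1), ds, epochs = 2, batch_size = 8, seed = 2)
  # tiny_net is not a named architecture, so exercise save/load on proposed
  mp <- build_proposed(seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(mp, path)
  mp2 <- load_model(path)
  img <- signal_to_image(runif(180, 0, 1), 0, 1, 64)
  expect_equal(predict(mp2, img)$distribution, predict(mp, img)$distribution)
})
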