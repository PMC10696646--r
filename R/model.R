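# The two beat classifiers: a compact three-block CNN (the "proposed"
# architecture) and a deeper batch-normalized reference ("baseline"), both
# ending in a 15-way softmax over the grouped beat vocabulary.

new_cnn <- function(architecture_id, input_shape, layers, seed) {
  layers <- init_params(layers, seed)
  shapes <- trace_shapes(layers, input_shape)
  structure(list(architecture_id = architecture_id,
                 input_shape = c(input_shape, 1L),
                 label_vocabulary = class_labels(),
                 layers = layers, layer_shapes = shapes,
                 training_meta = list(epochs = 0L, batch_size = NA_integer_,
                                      seed = seed, trained = FALSE),
                 log = data.frame(epoch = integer(), loss = numeric(),
                                  accuracy = numeric())),
            class = "ecg_cnn")
}

#' Build the compact 2D CNN beat classifier
#'
#' Architecture on a 180 x 64 single-channel input: three convolution /
#' max-pool blocks with 8, 16 and 32 filters of size 6x6, 5x5 and 4x4 (ReLU,
#' "same" padding, 2x2 pooling), then dense layers of 512, 256 and 128 ReLU
#' units and a 15-way softmax. The small filter counts keep the network cheap
#' enough for streaming classification on modest hardware.
#'
#' @param seed Integer seed for the weight initialization.
#' @return An `ecg_cnn` object (untrained; its softmax output is already a
#'   valid probability distribution).
#' @export
build_proposed <- function(seed = 1L) {
  layers <- list(
    layer_conv(8L, c(6L, 6L), 1L), layer_pool(),
    layer_conv(16L, c(5L, 5L), 8L), layer_pool(),
    layer_conv(32L, c(4L, 4L), 16L), layer_pool(),
    layer_flatten(),
    layer_dense(8L * 22L * 32L, 512L, "relu"),
    layer_dense(512L, 256L, "relu"),
    layer_dense(256L, 128L, "relu"),
    layer_dense(128L, 15L, "softmax"))
  new_cnn("proposed", c(180L, 64L), layers, seed)
}

#' Build the baseline 2D CNN beat classifier
#'
#' A reduced VGG-style reference on a 128 x 128 input: three blocks of two
#' batch-normalized 3x3 convolutions (8, 16, 32 filters) each followed by
#' 2x2 max pooling, then a 512-unit dense layer with batch normalization and
#' a 15-way softmax. The architecture table this follows lists a max-pooling
#' step after the flat dense/batch-norm pair; pooling is undefined on a flat
#' vector, so that step is represented as an explicit flagged no-op layer.
#'
#' @param seed Integer seed for the weight initialization.
#' @return An `ecg_cnn` object.
#' @export
build_baseline <- function(seed = 1L) {
  layers <- list(
    layer_conv(8L, c(3L, 3L), 1L), layer_bnorm(8L, "channel"),
    layer_conv(8L, c(3L, 3L), 8L), layer_bnorm(8L, "channel"), layer_pool(),
    layer_conv(16L, c(3L, 3L), 8L), layer_bnorm(16L, "channel"),
    layer_conv(16L, c(3L, 3L), 16L), layer_bnorm(16L, "channel"), layer_pool(),
    layer_conv(32L, c(3L, 3L), 16L), layer_bnorm(32L, "channel"),
    layer_conv(32L, c(3L, 3L), 32L), layer_bnorm(32L, "channel"), layer_pool(),
    layer_flatten(),
    layer_dense(16L * 16L * 32L, 512L, "relu"), layer_bnorm(512L, "unit"),
    layer_noop("max-pool on a flat vector: undefined, kept as a no-op"),
    layer_dense(512L, 15L, "softmax"))
  new_cnn("baseline", c(128L, 128L), layers, seed)
}

# stack a list of beat_image objects into an (h, w, 1, N) array, checking
# geometry against the model input shape (w, h, 1)
images_to_array <- function(images, input_shape) {
  if (inherits(images, "beat_image")) images <- list(images)
  w <- input_shape[1]; h <- input_shape[2]
  x <- array(0, dim = c(h, w, 1L, length(images)))
  for (k in seq_along(images)) {
    g <- images[[k]]$grid
    if (nrow(g) != h || ncol(g) != w)
      stop(sprintf("image geometry %d x %d does not match model input %d x %d (width x height)",
                   ncol(g), nrow(g), w, h))
    x[, , 1L, k] <- g / 255
  }
  x
}

#' Train a beat classifier
#'
#' Minimizes categorical cross-entropy with Adam (learning rate `lr`) over
#' mini-batches, shuffling each epoch with the given seed. Weights are those
#' already present in `model` (from its builder seed); `epochs = 0` returns
#' the model unchanged. All randomness flows through R's RNG, so the same
#' seed, data and initial model reproduce the same fit to floating-point
#' determinism of the BLAS in use.
#'
#' @param model An `ecg_cnn` from [build_proposed()] or [build_baseline()].
#' @param train_set List with `images` (list of [beat_image()]) and `y`
#'   (0-based integer class indices), e.g. `build_dataset(...)$train`.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size (default 512).
#' @param seed Integer seed for epoch shuffling.
#' @param lr Adam learning rate.
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained `ecg_cnn`; `$log` holds one row per epoch with
#'   training loss and accuracy.
#' @export
train_cnn <- function(model, train_set, epochs, batch_size = 512L, seed = 1L,
                      lr = 1e-3, verbose = FALSE) {
  stopifnot(inherits(model, "ecg_cnn"))
  if (length(train_set$images) == 0) stop("empty training set")
  if (epochs == 0) return(model)
  x_all <- images_to_array(train_set$images, model$input_shape)
  y_all <- as.integer(train_set$y)
  nclass <- length(model$label_vocabulary)
  if (any(y_all < 0 | y_all >= nclass)) stop("class index out of range")
  nobs <- length(y_all)
  layers <- model$layers
  state <- adam_init(layers)
  set.seed(seed)
  t_step <- 0L
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (ep in seq_len(epochs)) {
    perm <- sample.int(nobs)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, nobs, by = batch_size)) {
      ix <- perm[start:min(start + batch_size - 1L, nobs)]
      xb <- x_all[, , , ix, drop = FALSE]
      yb <- y_all[ix]
      fw <- nn_forward(layers, xb, training = TRUE)
      probs <- fw$out
      nb <- length(ix)
      onehot <- matrix(0, nb, nclass)
      onehot[cbind(seq_len(nb), yb + 1L)] <- 1
      p_true <- probs[cbind(seq_len(nb), yb + 1L)]
      ep_loss <- ep_loss + sum(-log(pmax(p_true, 1e-12)))
      ep_correct <- ep_correct + sum(max.col(probs) == yb + 1L)
      dout <- (probs - onehot) / nb
      grads <- nn_backward(layers, fw$caches, dout)
      layers <- bn_update_running(layers, fw$caches)
      t_step <- t_step + 1L
      upd <- adam_update(layers, grads, state, lr, t_step)
      layers <- upd$layers; state <- upd$state
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nobs,
                                 accuracy = ep_correct / nobs))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, accuracy %.4f",
                      ep, ep_loss / nobs, ep_correct / nobs))
  }
  model$layers <- layers
  model$training_meta <- list(epochs = epochs, batch_size = batch_size,
                              seed = seed, trained = TRUE)
  model$log <- log
  model
}

# inference-mode class probabilities, one row per image
predict_probs <- function(model, images) {
  x <- images_to_array(images, model$input_shape)
  nn_forward(model$layers, x, training = FALSE)$out
}

#' Classify beat images
#'
#' @param object An `ecg_cnn`.
#' @param newdata A single [beat_image()] or a list of them (geometry must
#'   match the model input shape).
#' @param ... Unused.
#' @return For a single image, a `beat_prediction`: a list with `class_index`
#'   (0-based per [class_labels()]), `label`, `confidence` (the maximum
#'   softmax probability) and `distribution` (all 15 probabilities). For a
#'   list of images, a list of `beat_prediction`s in input order.
#' @export
predict.ecg_cnn <- function(object, newdata, ...) {
  single <- inherits(newdata, "beat_image")
  probs <- predict_probs(object, newdata)
  labels <- object$label_vocabulary
  preds <- lapply(seq_len(nrow(probs)), function(k) {
    p <- probs[k, ]
    j <- which.max(p)
    structure(list(class_index = j - 1L, label = labels[j],
                   confidence = p[j],
                   distribution = stats::setNames(p, labels)),
              class = "beat_prediction")
  })
  if (single) preds[[1]] else preds
}

#' @export
print.beat_prediction <- function(x, ...) {
  cat(sprintf("<beat_prediction> %s (class %d), confidence %.2f%%\n",
              x$label, x$class_index, 100 * x$confidence))
  invisible(x)
}

#' @export
print.ecg_cnn <- function(x, ...) {
  cat(sprintf("<ecg_cnn '%s'>  input (%d, %d, 1), %s parameters, %s\n",
              x$architecture_id, x$input_shape[1], x$input_shape[2],
              format(count_params(x$layers), big.mark = ","),
              if (x$training_meta$trained)
                sprintf("trained %d epoch(s)", x$training_meta$epochs)
              else "untrained"))
  invisible(x)
}

#' Summarize a classifier architecture
#'
#' @param object An `ecg_cnn`.
#' @param ... Unused.
#' @return Data frame with one row per layer: type, output shape, trainable
#'   parameter count. Printed with a total.
#' @export
summary.ecg_cnn <- function(object, ...) {
  rows <- lapply(seq_along(object$layers), function(i) {
    ly <- object$layers[[i]]
    shp <- object$layer_shapes[[i]]
    shp_txt <- if (length(shp) == 3)
      sprintf("(%d, %d, %d)", shp[2], shp[1], shp[3]) else sprintf("(%d)", shp)
    np <- count_params(object$layers[i])
    lab <- switch(ly$type,
                  conv = sprintf("conv %dx%d, %d filters, relu",
                                 ly$k[1], ly$k[2], ly$cout),
                  pool = "maxpool 2x2",
                  bnorm = "batchnorm",
                  flatten = "flatten",
                  dense = sprintf("dense %d, %s", ly$dout, ly$activation),
                  noop = paste("no-op:", ly$note))
    data.frame(layer = lab, output_shape = shp_txt, params = np)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- count_params(object$layers)
  attr(out, "architecture_id") <- object$architecture_id
  class(out) <- c("summary.ecg_cnn", "data.frame")
  out
}

#' @export
print.summary.ecg_cnn <- function(x, ...) {
  cat(sprintf("Architecture '%s'\n", attr(x, "architecture_id")))
  print.data.frame(x)
  cat(sprintf("Total trainable parameters: %s\n",
              format(attr(x, "total_params"), big.mark = ",")))
  invisible(x)
}

#' Extract classifier weights
#'
#' @param object An `ecg_cnn`.
#' @param ... Unused.
#' @return Named list of weight/bias (and batch-norm scale/shift) arrays.
#' @export
coef.ecg_cnn <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$layers)) {
    ly <- object$layers[[i]]
    nm <- sprintf("layer%02d_%s", i, ly$type)
    if (ly$type %in% c("conv", "dense"))
      out[[nm]] <- list(W = ly$W, b = ly$b)
    else if (ly$type == "bnorm")
      out[[nm]] <- list(gamma = ly$gamma, beta = ly$beta,
                        running_mean = ly$rmean, running_var = ly$rvar)
  }
  out
}

#' Evaluate a classifier on a labelled image set
#'
#' @param model A trained `ecg_cnn`.
#' @param test_set List with `images` and 0-based `y`, e.g.
#'   `build_dataset(...)$test`.
#' @return List with the [confusion()] matrix and the four summary metrics
#'   from [summarize_metrics()].
#' @export
evaluate_model <- function(model, test_set) {
  probs <- predict_probs(model, test_set$images)
  labels <- model$label_vocabulary
  pred <- labels[max.col(probs)]
  truth <- labels[test_set$y + 1L]
  cm <- confusion(truth, pred)
  list(confusion = cm, metrics = summarize_metrics(cm))
}

#' Save / load a classifier as plain text (JSON)
#'
#' Serializes the architecture and all parameters with full numeric
#' precision.
#'
#' @param model An `ecg_cnn`.
#' @param path File path.
#' @return `save_model`: the path, invisibly. `load_model`: the `ecg_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ecg_cnn"))
  payload <- list(architecture_id = model$architecture_id,
                  builder_seed = model$training_meta$seed,
                  training_meta = model$training_meta,
                  log = model$log,
                  layers = lapply(model$layers, function(ly) {
                    ly$W <- if (!is.null(ly$W)) list(dim = dim(ly$W),
                                                     data = as.numeric(ly$W))
                    ly
                  }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- if (p$architecture_id == "proposed")
    build_proposed(seed = p$builder_seed) else build_baseline(seed = p$builder_seed)
  for (i in seq_along(model$layers)) {
    src <- p$layers[[i]]
    if (!is.null(src$W)) {
      dm <- unlist(src$W$dim)
      model$layers[[i]]$W <- matrix(unlist(src$W$data), dm[1], dm[2])
    }
    for (f in c("b", "gamma", "beta", "rmean", "rvar"))
      if (!is.null(src[[f]]))
        model$layers[[i]][[f]] <- as.numeric(unlist(src[[f]]))
  }
  model$training_meta <- lapply(p$training_meta, function(v)
    if (is.list(v)) unlist(v) else v)
  if (length(p$log))
    model$log <- do.call(rbind, lapply(p$log, as.data.frame))
  model
}
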