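# Internal neural-network engine: layer forward/backward passes and Adam.
#
# A network is a list of layer specs. Spatial tensors are column-major arrays
# with dim (h, w, c, batch); after `flatten` activations are (batch x units)
# matrices. Convolutions use "same" padding (pad_before = floor((k-1)/2));
# pooling is 2x2 stride 2, valid. Convolution/pooling kernels live in
# compiled code (im2col + BLAS); dense and batch-norm layers are plain
# matrix algebra here.

layer_conv <- function(cout, k, cin) {
  list(type = "conv", k = as.integer(k), cin = cin, cout = cout,
       W = NULL, b = NULL, activation = "relu")
}
layer_pool <- function() list(type = "pool")
layer_bnorm <- function(dim, over) {
  list(type = "bnorm", dim = dim, over = over, gamma = rep(1, dim),
       beta = rep(0, dim), rmean = rep(0, dim), rvar = rep(1, dim),
       momentum = 0.9, eps = 1e-5)
}
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(din, dout, activation) {
  list(type = "dense", din = din, dout = dout, W = NULL, b = NULL,
       activation = activation)
}
layer_noop <- function(note) list(type = "noop", note = note)

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# initialize weights in place; He normal for ReLU layers, Glorot for softmax
init_params <- function(layers, seed) {
  set.seed(seed)
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      fan_in <- prod(ly$k) * ly$cin
      ly$W <- matrix(rnorm(fan_in * ly$cout, sd = sqrt(2 / fan_in)),
                     nrow = fan_in, ncol = ly$cout)
      ly$b <- rep(0, ly$cout)
    } else if (ly$type == "dense") {
      sd <- if (ly$activation == "softmax")
        sqrt(2 / (ly$din + ly$dout)) else sqrt(2 / ly$din)
      ly$W <- matrix(rnorm(ly$din * ly$dout, sd = sd), ly$din, ly$dout)
      ly$b <- rep(0, ly$dout)
    }
    layers[[i]] <- ly
  }
  layers
}

# trace shapes through the stack; input_shape is c(w, h) of the image.
# returns list of per-layer output shapes (spatial: c(h, w, c); flat: units)
trace_shapes <- function(layers, input_shape) {
  shp <- c(input_shape[2], input_shape[1], 1)  # (h, w, c)
  flat <- FALSE
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      stopifnot(!flat, ly$cin == shp[3])
      shp[3] <- ly$cout
    } else if (ly$type == "pool") {
      stopifnot(!flat)
      shp[1:2] <- shp[1:2] %/% 2L
    } else if (ly$type == "flatten") {
      shp <- prod(shp); flat <- TRUE
    } else if (ly$type == "dense") {
      stopifnot(flat, ly$din == shp)
      shp <- ly$dout
    } else if (ly$type == "bnorm") {
      expect <- if (flat) shp else shp[3]
      stopifnot(ly$dim == expect)
    }
    out[[i]] <- shp
  }
  out
}

count_params <- function(layers) {
  sum(vapply(layers, function(ly) {
    switch(ly$type,
           conv = length(ly$W) + length(ly$b),
           dense = length(ly$W) + length(ly$b),
           bnorm = 2L * ly$dim,  # trainable gamma/beta only
           0L)
  }, numeric(1)))
}

bn_channel_stats <- function(x) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (h*w*n) x c
  list(mat = xm, d = d)
}

bn_unflatten <- function(xm, d) {
  aperm(array(xm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

# forward pass; training=TRUE uses batch statistics in bnorm layers and
# returns caches for backprop
nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      pre <- .cnn_conv_forward(x, ly$W, ly$b, ly$k[1], ly$k[2])
      out <- relu(pre)
      caches[[i]] <- list(x = x, pre = pre)
      x <- out
    } else if (ly$type == "pool") {
      fw <- .cnn_maxpool_forward(x)
      caches[[i]] <- list(argmax = fw$argmax, in_dim = dim(x))
      x <- fw$out
    } else if (ly$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(in_dim = d)
      x <- t(matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
    } else if (ly$type == "dense") {
      pre <- sweep(x %*% ly$W, 2, ly$b, "+")
      out <- switch(ly$activation,
                    relu = relu(pre),
                    softmax = softmax_rows(pre),
                    linear = pre)
      caches[[i]] <- list(x = x, pre = pre)
      x <- out
    } else if (ly$type == "bnorm") {
      spatial <- ly$over == "channel"
      if (spatial) { st <- bn_channel_stats(x); xm <- st$mat } else xm <- x
      if (training) {
        mu <- colMeans(xm)
        va <- colMeans(sweep(xm, 2, mu)^2)
      } else {
        mu <- ly$rmean; va <- ly$rvar
      }
      xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(va + ly$eps), "/")
      ym <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      caches[[i]] <- list(xhat = xhat, mu = mu, va = va, xm = xm,
                          spatial = spatial, in_dim = if (spatial) st$d else NULL)
      x <- if (spatial) bn_unflatten(ym, st$d) else ym
    }
    # noop: pass through
  }
  list(out = x, caches = caches)
}

# backward pass from dout (gradient of loss wrt final layer OUTPUT for
# linear/softmax-with-CE convention: for the softmax output layer pass
# (probs - onehot)/N as dout and it is treated as d(pre)).
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      cache <- caches[[i]]
      dpre <- if (ly$activation == "relu") dout * (cache$pre > 0)
              else dout  # softmax+CE or linear: dout already wrt pre
      grads[[i]] <- list(W = crossprod(cache$x, dpre), b = colSums(dpre))
      dout <- tcrossprod(dpre, ly$W)
    } else if (ly$type == "flatten") {
      d <- caches[[i]]$in_dim
      dout <- array(t(dout), dim = d)
    } else if (ly$type == "pool") {
      cache <- caches[[i]]
      dout <- .cnn_maxpool_backward(dout, cache$argmax,
                                    as.integer(cache$in_dim))
    } else if (ly$type == "conv") {
      cache <- caches[[i]]
      dpre <- dout * (cache$pre > 0)
      bw <- .cnn_conv_backward(cache$x, ly$W, dpre, ly$k[1], ly$k[2])
      grads[[i]] <- list(W = bw$dw, b = bw$db)
      dout <- bw$dx
    } else if (ly$type == "bnorm") {
      cache <- caches[[i]]
      dm <- if (cache$spatial) bn_channel_stats(dout)$mat else dout
      m <- nrow(dm)
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      dxhat <- sweep(dm, 2, ly$gamma, "*")
      istd <- 1 / sqrt(cache$va + ly$eps)
      xc <- sweep(cache$xm, 2, cache$mu)
      dvar <- colSums(dxhat * xc) * (-0.5) * istd^3
      dmu <- colSums(sweep(dxhat, 2, -istd, "*")) +
        dvar * colMeans(-2 * xc)
      dxm <- sweep(dxhat, 2, istd, "*") +
        sweep(xc, 2, 2 * dvar / m, "*") +
        matrix(dmu / m, nrow = m, ncol = length(dmu), byrow = TRUE)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dout <- if (cache$spatial) bn_unflatten(dxm, cache$in_dim) else dxm
    }
  }
  grads
}

# update batch-norm running statistics after a training-mode forward pass
bn_update_running <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bnorm" && !is.null(caches[[i]])) {
      ly <- layers[[i]]
      ly$rmean <- ly$momentum * ly$rmean + (1 - ly$momentum) * caches[[i]]$mu
      ly$rvar <- ly$momentum * ly$rvar + (1 - ly$momentum) * caches[[i]]$va
      layers[[i]] <- ly
    }
  }
  layers
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type %in% c("conv", "dense"))
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    else if (ly$type == "bnorm")
      list(mg = ly$gamma * 0, vg = ly$gamma * 0,
           mb = ly$beta * 0, vb = ly$beta * 0)
    else NULL
  })
}

adam_step <- function(val, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(val = val - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_update <- function(layers, grads, state, lr, t) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]; g <- grads[[i]]; s <- state[[i]]
    if (is.null(g) || is.null(s)) next
    if (ly$type %in% c("conv", "dense")) {
      uW <- adam_step(ly$W, g$W, s$mW, s$vW, lr, t)
      ub <- adam_step(ly$b, g$b, s$mb, s$vb, lr, t)
      ly$W <- uW$val; s$mW <- uW$m; s$vW <- uW$v
      ly$b <- ub$val; s$mb <- ub$m; s$vb <- ub$v
    } else if (ly$type == "bnorm") {
      ug <- adam_step(ly$gamma, g$gamma, s$mg, s$vg, lr, t)
      ub <- adam_step(ly$beta, g$beta, s$mb, s$vb, lr, t)
      ly$gamma <- ug$val; s$mg <- ug$m; s$vg <- ug$v
      ly$beta <- ub$val; s$mb <- ub$m; s$vb <- ub$v
    }
    layers[[i]] <- ly; state[[i]] <- s
  }
  list(layers = layers, state = state)
}
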