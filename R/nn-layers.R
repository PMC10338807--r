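## Minimal neural-network engine: typed layer objects with explicit
## forward/backward passes. Feature maps are numeric arrays with dims
## (X, Y, Z, C, N); fully-connected activations are (features x N)
## matrices. Everything is double precision and deterministic given the
## R RNG state (dropout is the only stochastic op).

new_layer <- function(type, params = list(), buffers = list(), cfg = list()) {
  structure(list(type = type, params = params, buffers = buffers, cfg = cfg),
            class = "msnet_layer")
}

is_layer <- function(x) inherits(x, "msnet_layer")

layer_conv3d <- function(kernel, in_ch, out_ch, stride = 1L,
                         pad = kernel %/% 2L, groups = 1L, bias = FALSE) {
  if (in_ch %% groups != 0L || out_ch %% groups != 0L)
    stopf("conv3d: groups %d must divide in (%d) and out (%d) channels",
          groups, in_ch, out_ch)
  params <- list(W = array(0, c(kernel, kernel, kernel, in_ch %/% groups,
                                out_ch)))
  if (bias) params$b <- numeric(out_ch)
  new_layer("conv3d", params,
            cfg = list(kernel = kernel, in_ch = in_ch, out_ch = out_ch,
                       stride = as.integer(stride), pad = as.integer(pad),
                       groups = as.integer(groups), bias = bias))
}

layer_fc <- function(in_dim, out_dim, bias = TRUE) {
  params <- list(W = matrix(0, out_dim, in_dim))
  if (bias) params$b <- numeric(out_dim)
  new_layer("fc", params, cfg = list(in_dim = in_dim, out_dim = out_dim,
                                     bias = bias))
}

layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("bn",
            params = list(gamma = rep(1, channels), beta = rep(0, channels)),
            buffers = list(running_mean = rep(0, channels),
                           running_var = rep(1, channels)),
            cfg = list(channels = channels, momentum = momentum, eps = eps))
}

layer_relu <- function() new_layer("relu")

layer_dropout <- function(p = 0.5) new_layer("dropout", cfg = list(p = p))

## ---- forward -------------------------------------------------------------

## BN shape info: feature maps are (X,Y,Z,C,N) with S = X*Y*Z spatial
## elements per channel; FC activations (C x N) have S = 1. The C++
## kernels index channels as (i / S) %% C, which matches both layouts.
bn_shape <- function(x) {
  d <- dim(x)
  if (length(d) == 5L) list(S = prod(d[1:3]), C = d[4], N = d[5], d = d)
  else list(S = 1L, C = nrow(x), N = ncol(x), d = d)
}

## layer_forward returns list(y, cache, layer); `layer` is returned because
## batch-norm updates its running statistics during training.
layer_forward <- function(layer, x, training = FALSE, keep = TRUE) {
  switch(layer$type,
    conv3d = {
      cf <- layer$cfg
      b <- if (cf$bias) layer$params$b else numeric(0)
      y <- conv3d_fw(x, layer$params$W, b, cf$stride, cf$pad, cf$groups)
      list(y = y, cache = if (keep) list(x = x) else NULL, layer = layer)
    },
    fc = {
      y <- layer$params$W %*% x
      if (layer$cfg$bias) y <- y + layer$params$b
      list(y = y, cache = if (keep) list(x = x) else NULL, layer = layer)
    },
    bn = {
      cf <- layer$cfg
      sh <- bn_shape(x)
      if (training) {
        st <- bn_stats(x, sh$S, sh$C, sh$N)
        mu <- st$mean
        v <- st$var
        mtot <- sh$S * sh$N
        layer$buffers$running_mean <-
          (1 - cf$momentum) * layer$buffers$running_mean + cf$momentum * mu
        ## unbiased variance in the running estimate (framework convention)
        vu <- if (mtot > 1) v * mtot / (mtot - 1) else v
        layer$buffers$running_var <-
          (1 - cf$momentum) * layer$buffers$running_var + cf$momentum * vu
      } else {
        mu <- layer$buffers$running_mean
        v <- layer$buffers$running_var
      }
      inv <- 1 / sqrt(v + cf$eps)
      r <- bn_apply(x, mu, inv, layer$params$gamma, layer$params$beta,
                    sh$S, sh$C, sh$N, want_xhat = keep)
      y <- r$y
      dim(y) <- sh$d
      cache <- if (keep) list(xhat = r$xhat, inv = inv, shape = sh$d,
                              C = sh$C, N = sh$N, S = sh$S,
                              training = training)
      list(y = y, cache = cache, layer = layer)
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = if (keep) list(mask = mask), layer = layer)
    },
    dropout = {
      if (!training || layer$cfg$p <= 0) {
        list(y = x, cache = if (keep) list(mask = NULL), layer = layer)
      } else {
        keepp <- 1 - layer$cfg$p
        mask <- (array(runif(length(x)), dim(x) %||% length(x)) < keepp) / keepp
        list(y = x * mask, cache = if (keep) list(mask = mask), layer = layer)
      }
    },
    stopf("unknown layer type '%s'", layer$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## layer_backward returns list(gx, grads); grads mirrors layer$params.
## need_gx = FALSE skips the input gradient (first layer of the network).
layer_backward <- function(layer, cache, gy, need_gx = TRUE) {
  switch(layer$type,
    conv3d = {
      cf <- layer$cfg
      r <- conv3d_bw(cache$x, layer$params$W, gy, cf$stride, cf$pad,
                     cf$groups, cf$bias, need_gx)
      grads <- list(W = r$gw)
      if (cf$bias) grads$b <- r$gb
      list(gx = r$gx, grads = grads)
    },
    fc = {
      gx <- crossprod(layer$params$W, gy)
      grads <- list(W = tcrossprod(gy, cache$x))
      if (layer$cfg$bias) grads$b <- rowSums(gy)
      list(gx = gx, grads = grads)
    },
    bn = {
      S <- cache$S; C <- cache$C; N <- cache$N
      sums <- bn_bw_sums(gy, cache$xhat, S, C, N)
      mtot <- S * N
      gx <- bn_bw_gx(gy, cache$xhat, layer$params$gamma, cache$inv,
                     sums$dbeta / mtot, sums$dgamma / mtot, S, C, N,
                     cache$training)
      dim(gx) <- cache$shape
      list(gx = gx, grads = list(gamma = sums$dgamma, beta = sums$dbeta))
    },
    relu = list(gx = gy * cache$mask, grads = list()),
    dropout = {
      gx <- if (is.null(cache$mask)) gy else gy * cache$mask
      list(gx = gx, grads = list())
    },
    stopf("unknown layer type '%s'", layer$type))
}

## ---- sequences -----------------------------------------------------------

seq_forward <- function(layers, x, training = FALSE, keep = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training, keep)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, gy, need_input_grad = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], gy,
                        need_gx = need_input_grad || i > 1L)
    gy <- r$gx
    grads[[i]] <- r$grads
  }
  list(gx = gy, grads = grads)
}

## ---- parameter-tree utilities --------------------------------------------

## Model components are nested lists whose leaves are msnet_layer objects.
## These walkers keep gradients/velocities in trees of identical shape.

tree_map_layers <- function(node, f) {
  if (is_layer(node)) return(f(node))
  if (is.list(node)) return(lapply(node, tree_map_layers, f = f))
  node
}

tree_collect <- function(node, f, acc = list()) {
  if (is_layer(node)) return(c(acc, list(f(node))))
  if (is.list(node)) for (ch in node) acc <- tree_collect(ch, f, acc)
  acc
}

count_params <- function(node) {
  sum(unlist(tree_collect(node, function(l)
    sum(vapply(l$params, length, numeric(1))))))
}

## Glorot-uniform initialisation; fans follow the framework convention
## (conv: k^3 * channels-per-group).
xavier_fill <- function(layer) {
  if (layer$type == "conv3d") {
    cf <- layer$cfg
    k3 <- cf$kernel^3
    fan_in <- k3 * cf$in_ch / cf$groups
    fan_out <- k3 * cf$out_ch / cf$groups
    a <- sqrt(6 / (fan_in + fan_out))
    layer$params$W[] <- runif(length(layer$params$W), -a, a)
    if (cf$bias) layer$params$b[] <- 0
  } else if (layer$type == "fc") {
    a <- sqrt(6 / (layer$cfg$in_dim + layer$cfg$out_dim))
    layer$params$W[] <- runif(length(layer$params$W), -a, a)
    if (layer$cfg$bias) layer$params$b[] <- 0
  } else if (layer$type == "bn") {
    layer$params$gamma[] <- 1
    layer$params$beta[] <- 0
    layer$buffers$running_mean[] <- 0
    layer$buffers$running_var[] <- 1
  }
  layer
}

## SGD with momentum over parallel (model, grads, velocity) trees.
## Gradient subtrees are matched to model subtrees by name where names
## exist (the model may carry extra non-parameter elements such as
## configs); NULL gradient subtrees leave the module untouched (frozen).
sgd_step <- function(node, grads, vel, lr, momentum) {
  if (is.null(grads)) return(list(node = node, vel = vel))
  if (is_layer(node)) {
    if (is.null(vel)) vel <- lapply(node$params, function(p) p * 0)
    for (nm in names(node$params)) {
      if (is.null(grads[[nm]])) next
      gv <- grads[[nm]]
      dim(gv) <- dim(node$params[[nm]])
      vel[[nm]] <- momentum * vel[[nm]] - lr * gv
      node$params[[nm]] <- node$params[[nm]] + vel[[nm]]
    }
    return(list(node = node, vel = vel))
  }
  keys <- if (!is.null(names(grads)) && all(names(grads) %in% names(node)))
    names(grads) else seq_along(grads)
  if (is.null(vel)) {
    vel <- vector("list", length(grads))
    if (is.character(keys)) names(vel) <- keys
  }
  for (k in keys) {
    if (is.null(grads[[k]])) next
    r <- sgd_step(node[[k]], grads[[k]], vel[[k]], lr, momentum)
    node[[k]] <- r$node
    vel[[k]] <- r$vel
  }
  list(node = node, vel = vel)
}

## Element-wise sum of two gradient trees of identical shape.
grad_tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(a)) out[[i]] <- grad_tree_add(a[[i]], b[[i]])
  out
}
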