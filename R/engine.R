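# Minimal CPU neural-network engine backing the RCCGNet implementation.
# Layers are plain lists carrying their parameters; forward passes return
# caches that the matching backward passes consume.  Batches are
# (H, W, C, N) arrays up to global average pooling and (features, N)
# matrices afterwards.

.BN_EPS <- 1e-3      # batch-norm epsilon
.BN_MOMENTUM <- 0.9  # running-statistics momentum

.glorot <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dims)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.bn_new <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C))
}

# ---- layer constructors ----------------------------------------------------

nn_conv <- function(name, k, cin, cout, bn = TRUE, act = "relu",
                    bias = FALSE) {
  if (!k %in% c(1L, 3L)) stop("conv kernel size must be 1 or 3")
  if (cin < 1L || cout < 1L) stop("conv channel counts must be positive")
  params <- list(W = .glorot(c(k, k, cin, cout), k * k * cin, k * k * cout))
  if (bias) params$b <- rep(0, cout)
  if (bn) params <- c(params, .bn_new(cout))
  list(type = "conv", name = name, k = k, cin = cin, cout = cout,
       bn = bn, act = act, bias = bias, params = params,
       state = if (bn) list(rmean = rep(0, cout), rvar = rep(1, cout)))
}

# channel gate: batch norm (spatial) -> global average pool -> 1x1 conv
# -> sigmoid.  The normalization sits on the gating branch's spatial
# input, where batch statistics are taken over H*W*N values per channel;
# normalizing after pooling would batch-normalize per-sample summary
# statistics, which generalizes poorly at inference.
nn_gate <- function(name, C) {
  params <- c(list(W = .glorot(c(C, C), C, C), b = rep(0, C)), .bn_new(C))
  list(type = "gate", name = name, C = C, params = params,
       state = list(rmean = rep(0, C), rvar = rep(1, C)))
}

nn_pool <- function(name) list(type = "pool", name = name, params = list())

nn_gap <- function(name) list(type = "gap", name = name, params = list())

nn_dense <- function(name, nin, nout, act = "none") {
  list(type = "dense", name = name, nin = nin, nout = nout, act = act,
       params = list(W = .glorot(c(nin, nout), nin, nout), b = rep(0, nout)))
}

nn_scr <- function(name, C, sharing = TRUE, gating = TRUE,
                   strict_gate = FALSE) {
  if (C %% 2L != 0L)
    stop("SCR block requires an even channel count, got ", C)
  sub <- list(
    conv1 = nn_conv("conv1", 3L, C, C),
    conv_x = nn_conv("conv_x", 3L, C, C),
    conv_y = nn_conv("conv_y", 3L, C, C)
  )
  if (gating) {
    sub$gate_x <- nn_gate("gate_x", C)
    sub$gate_y <- nn_gate("gate_y", C)
  }
  list(type = "scr", name = name, C = C, sharing = sharing, gating = gating,
       strict_gate = strict_gate, sub = sub, params = list())
}

# ---- forward/backward ------------------------------------------------------

.conv_fwd <- function(layer, x, training, use_float) {
  z <- cpp_conv_fwd(x, layer$params$W, use_float)
  if (layer$bias) {
    d <- dim(z)
    z <- z + rep(layer$params$b, each = prod(d[1:2]))  # recycles over N
  }
  cache <- list(x = x)
  if (layer$bn) {
    bn <- cpp_bn_fwd(z, layer$params$gamma, layer$params$beta, .BN_EPS,
                     training, layer$state$rmean, layer$state$rvar,
                     relu = layer$act == "relu")
    cache$z <- z
    cache$mean <- bn$mean
    cache$var <- bn$var
    out <- bn$out
    if (training) {
      m <- .BN_MOMENTUM
      layer$state$rmean <- m * layer$state$rmean + (1 - m) * bn$mean
      layer$state$rvar <- m * layer$state$rvar + (1 - m) * bn$var
    }
    if (layer$act == "sigmoid") out <- .sigmoid(out)
  } else {
    out <- z
    if (layer$act == "relu") out <- .relu(out)
    else if (layer$act == "sigmoid") out <- .sigmoid(out)
  }
  cache$out <- out
  list(out = out, cache = cache, layer = layer)
}

.conv_bwd <- function(layer, cache, dout, use_float) {
  if (layer$act == "relu") dout <- cpp_relu_bwd(dout, cache$out)
  else if (layer$act == "sigmoid")
    dout <- dout * cache$out * (1 - cache$out)
  grads <- list()
  if (layer$bn) {
    bb <- cpp_bn_bwd(cache$z, dout, layer$params$gamma, cache$mean,
                     cache$var, .BN_EPS)
    dz <- bb$dx
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
  } else dz <- dout
  if (layer$bias) {
    d <- dim(dz)
    grads$b <- rowSums(matrix(colSums(matrix(dz, prod(d[1:2]))),
                              d[3L], d[4L]))
  }
  cb <- cpp_conv_bwd(cache$x, layer$params$W, dz, use_float)
  grads$W <- cb$dw
  list(dx = cb$dx, grads = grads)
}

.gate_fwd <- function(layer, x, training) {
  d <- dim(x)
  hw <- prod(d[1:2])
  bn <- cpp_bn_fwd(x, layer$params$gamma, layer$params$beta, .BN_EPS,
                   training, layer$state$rmean, layer$state$rvar)
  if (training) {
    m <- .BN_MOMENTUM
    layer$state$rmean <- m * layer$state$rmean + (1 - m) * bn$mean
    layer$state$rvar <- m * layer$state$rvar + (1 - m) * bn$var
  }
  p <- matrix(colMeans(matrix(bn$out, hw)), d[3L], d[4L])  # C x N pooled
  u <- crossprod(layer$params$W, p) + layer$params$b       # 1x1 conv + bias
  s <- matrix(.sigmoid(u), d[3L], d[4L])                   # C x N scales
  out <- x * rep(s, each = hw)
  list(out = out, scale = s,
       cache = list(x = x, p = p, mean = bn$mean, var = bn$var, s = s),
       layer = layer)
}

# dout_scale: extra gradient flowing into the scale (C x N), used when the
# strict-literal block reuses the X-path scale on the Y path
.gate_bwd <- function(layer, cache, dout, dout_scale = NULL) {
  d <- dim(cache$x)
  hw <- prod(d[1:2])
  s <- cache$s
  dx <- dout * rep(s, each = hw)
  ds <- matrix(colSums(matrix(dout * cache$x, hw)), d[3L], d[4L])
  if (!is.null(dout_scale)) ds <- ds + dout_scale
  du <- ds * s * (1 - s)
  grads <- list(W = cache$p %*% t(du), b = rowSums(du))
  dp <- layer$params$W %*% du
  dxn <- array(rep(dp / hw, each = hw), d)
  bb <- cpp_bn_bwd(cache$x, dxn, layer$params$gamma, cache$mean,
                   cache$var, .BN_EPS)
  grads$gamma <- bb$dgamma
  grads$beta <- bb$dbeta
  list(dx = dx + bb$dx, grads = grads)
}

.scr_fwd <- function(layer, x, training, use_float) {
  sub <- layer$sub
  f1 <- .conv_fwd(sub$conv1, x, training, use_float)
  sub$conv1 <- f1$layer
  y <- f1$out
  if (layer$sharing) {
    sh <- share_channels(x, y)
    xc <- sh$x_concat
    yc <- sh$y_concat
  } else {
    xc <- x
    yc <- y
  }
  fx <- .conv_fwd(sub$conv_x, xc, training, use_float)
  fy <- .conv_fwd(sub$conv_y, yc, training, use_float)
  sub$conv_x <- fx$layer
  sub$conv_y <- fy$layer
  xsc <- fx$out
  ysc <- fy$out
  cache <- list(x = x, c1 = f1$cache, cx = fx$cache, cy = fy$cache)
  if (layer$gating) {
    gx <- .gate_fwd(sub$gate_x, xsc, training)
    gy <- .gate_fwd(sub$gate_y, ysc, training)
    sub$gate_x <- gx$layer
    sub$gate_y <- gy$layer
    xout <- gx$out
    if (layer$strict_gate) {
      hw <- prod(dim(ysc)[1:2])
      yout <- ysc * rep(gx$scale, each = hw)
    } else yout <- gy$out
    cache$gx <- gx$cache
    cache$gy <- gy$cache
  } else {
    xout <- xsc
    yout <- ysc
  }
  out <- cpp_add3(xout, yout, x)
  cache$out <- out
  layer$sub <- sub
  list(out = out, cache = cache, layer = layer)
}

.scr_bwd <- function(layer, cache, dout, use_float) {
  sub <- layer$sub
  grads <- list()
  dx <- dout  # residual path
  if (layer$gating) {
    if (layer$strict_gate) {
      ysc <- cache$gy$x
      hw <- prod(dim(ysc)[1:2])
      sx <- cache$gx$s
      dysc <- dout * rep(sx, each = hw)
      ds_extra <- matrix(colSums(matrix(dout * ysc, hw)),
                         dim(ysc)[3L], dim(ysc)[4L])
      bx <- .gate_bwd(sub$gate_x, cache$gx, dout, dout_scale = ds_extra)
      grads$gate_y <- lapply(sub$gate_y$params, function(p) p * 0)
    } else {
      bx <- .gate_bwd(sub$gate_x, cache$gx, dout)
      by <- .gate_bwd(sub$gate_y, cache$gy, dout)
      dysc <- by$dx
      grads$gate_y <- by$grads
    }
    dxsc <- bx$dx
    grads$gate_x <- bx$grads
  } else {
    dxsc <- dout
    dysc <- dout
  }
  bcx <- .conv_bwd(sub$conv_x, cache$cx, dxsc, use_float)
  bcy <- .conv_bwd(sub$conv_y, cache$cy, dysc, use_float)
  grads$conv_x <- bcx$grads
  grads$conv_y <- bcy$grads
  if (layer$sharing) {
    # x_concat = [x1, y2], y_concat = [y1, x2]
    sxc <- split_channels(bcx$dx)
    syc <- split_channels(bcy$dx)
    dx <- dx + concat_channels(sxc$first, syc$second)
    dy <- concat_channels(syc$first, sxc$second)
  } else {
    dx <- dx + bcx$dx
    dy <- bcy$dx
  }
  b1 <- .conv_bwd(sub$conv1, cache$c1, dy, use_float)
  grads$conv1 <- b1$grads
  dx <- dx + b1$dx
  list(dx = dx, grads = grads)
}

.pool_fwd <- function(layer, x) {
  r <- cpp_maxpool_fwd(x)
  list(out = r$out, cache = list(idx = r$idx, in_dim = dim(x)),
       layer = layer)
}

.gap_fwd <- function(layer, x) {
  d <- dim(x)
  out <- matrix(colMeans(matrix(x, prod(d[1:2]))), d[3L], d[4L])
  list(out = out, cache = list(in_dim = d), layer = layer)
}

.dense_fwd <- function(layer, x, training) {
  out <- crossprod(layer$params$W, x) + layer$params$b
  cache <- list(x = x)
  if (layer$act == "relu") out <- .relu(out)
  cache$out <- out
  list(out = out, cache = cache, layer = layer)
}

.dense_bwd <- function(layer, cache, dout) {
  if (layer$act == "relu") dout <- dout * (cache$out > 0)
  grads <- list(W = cache$x %*% t(dout), b = rowSums(dout))
  list(dx = layer$params$W %*% dout, grads = grads)
}

layer_forward <- function(layer, x, training = FALSE, use_float = TRUE) {
  switch(layer$type,
    conv = .conv_fwd(layer, x, training, use_float),
    gate = .gate_fwd(layer, x, training),
    scr = .scr_fwd(layer, x, training, use_float),
    pool = .pool_fwd(layer, x),
    gap = .gap_fwd(layer, x),
    dense = .dense_fwd(layer, x, training),
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout, use_float = TRUE) {
  switch(layer$type,
    conv = .conv_bwd(layer, cache, dout, use_float),
    gate = .gate_bwd(layer, cache, dout),
    scr = .scr_bwd(layer, cache, dout, use_float),
    pool = list(dx = cpp_maxpool_bwd(dout, cache$idx, cache$in_dim),
                grads = list()),
    gap = {
      d <- cache$in_dim
      hw <- prod(d[1:2])
      list(dx = array(rep(dout / hw, each = hw), d), grads = list())
    },
    dense = .dense_bwd(layer, cache, dout),
    stop("unknown layer type: ", layer$type))
}

# ---- parameter bookkeeping -------------------------------------------------

# flat named list of all trainable arrays, names "<layer>/<sub>/<param>"
flatten_params <- function(model) {
  out <- list()
  for (ln in names(model$layers)) {
    layer <- model$layers[[ln]]
    for (pn in names(layer$params))
      out[[paste(ln, pn, sep = "/")]] <- layer$params[[pn]]
    for (sn in names(layer$sub))
      for (pn in names(layer$sub[[sn]]$params))
        out[[paste(ln, sn, pn, sep = "/")]] <-
          layer$sub[[sn]]$params[[pn]]
  }
  out
}

set_flat_params <- function(model, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    if (length(parts) == 2L)
      model$layers[[parts[1L]]]$params[[parts[2L]]] <- flat[[nm]]
    else
      model$layers[[parts[1L]]]$sub[[parts[2L]]]$params[[parts[3L]]] <-
        flat[[nm]]
  }
  model
}

# running (non-trainable) layer state, same naming scheme as the params
flatten_states <- function(model) {
  out <- list()
  for (ln in names(model$layers)) {
    layer <- model$layers[[ln]]
    if (!is.null(layer$state)) out[[ln]] <- layer$state
    for (sn in names(layer$sub))
      if (!is.null(layer$sub[[sn]]$state))
        out[[paste(ln, sn, sep = "/")]] <- layer$sub[[sn]]$state
  }
  out
}

set_flat_states <- function(model, states) {
  for (nm in names(states)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    if (length(parts) == 1L)
      model$layers[[parts[1L]]]$state <- states[[nm]]
    else
      model$layers[[parts[1L]]]$sub[[parts[2L]]]$state <- states[[nm]]
  }
  model
}

# a full model snapshot: trainable parameters plus batch-norm running
# statistics (restoring one without the other mismatches normalization)
model_snapshot <- function(model) {
  list(params = flatten_params(model), states = flatten_states(model))
}

restore_snapshot <- function(model, snap) {
  model <- set_flat_params(model, snap$params)
  set_flat_states(model, snap$states)
}

flatten_grads <- function(model, grads) {
  out <- list()
  for (ln in names(grads)) {
    g <- grads[[ln]]
    for (pn in names(g)) {
      if (is.list(g[[pn]])) {
        for (qn in names(g[[pn]]))
          out[[paste(ln, pn, qn, sep = "/")]] <- g[[pn]][[qn]]
      } else out[[paste(ln, pn, sep = "/")]] <- g[[pn]]
    }
  }
  out
}
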