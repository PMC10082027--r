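#' Network configuration for RCCGNet
#'
#' @param input_size side length of the square RGB input, default 224.
#' @param stage_channels channel widths of the SCR stages; each must be
#'   even.  The reference network uses 16, 32 and 64 channels at its three
#'   stages, with two SCR blocks per stage.
#' @param blocks_per_stage number of SCR blocks per stage, default 2.
#' @param num_classes number of output classes (5 tumor grades by
#'   default; 8 for the breast-histology eight-class setting).
#' @param hidden_units width of the hidden fully connected layer between
#'   global average pooling and the softmax classifier.
#' @param variant `"full"` for the complete network or one of the
#'   ablations: `"cnn1_no_sharing"` (channel sharing removed),
#'   `"cnn2_no_gating"` (channel gate removed), `"cnn3_no_scr"` (each SCR
#'   block replaced by a plain conv-BN-ReLU stack of matched width).
#' @param strict_gate if `TRUE`, the Y path is rescaled by the X-path gate
#'   (the literal reading of the block equations) instead of its own gate.
#' @return an object of class `rccg_config`.
#' @export
network_config <- function(input_size = 224L,
                           stage_channels = c(16L, 32L, 64L),
                           blocks_per_stage = 2L,
                           num_classes = 5L,
                           hidden_units = 384L,
                           variant = c("full", "cnn1_no_sharing",
                                       "cnn2_no_gating", "cnn3_no_scr"),
                           strict_gate = FALSE) {
  variant <- match.arg(variant)
  if (length(stage_channels) < 1L) stop("stage_channels must be non-empty")
  if (any(stage_channels %% 2L != 0L) || any(stage_channels < 2L))
    stop("stage_channels must be even integers >= 2")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (input_size %% 2L^(length(stage_channels) - 1L) != 0L)
    stop("input_size must be divisible by 2^(number of stages - 1)")
  structure(list(input_size = as.integer(input_size),
                 stage_channels = as.integer(stage_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 num_classes = as.integer(num_classes),
                 hidden_units = as.integer(hidden_units),
                 variant = variant,
                 strict_gate = isTRUE(strict_gate)),
            class = "rccg_config")
}

#' Build the RCCGNet model
#'
#' Assembles the grading network: a 3x3 stem convolution into the first
#' stage width, then for each stage a run of SCR blocks followed (between
#' stages) by 2x2 max pooling and a 3x3 transition convolution to the next
#' width, and finally global average pooling feeding a hidden fully
#' connected layer and the softmax classifier.  All convolutions are
#' bias-free and followed by batch normalization and ReLU; the channel
#' gates use a biased 1x1 convolution with batch normalization before the
#' sigmoid.
#'
#' @param config a [network_config()].
#' @param seed optional integer seed for weight initialization (Glorot
#'   uniform); when `NULL` the current RNG state is used.
#' @param precision `"single"` to run convolution GEMMs in float32 (the
#'   default; fastest) or `"double"` for full double precision.
#' @return an object of class `rccg_model`.
#' @export
build_rccgnet <- function(config = network_config(), seed = NULL,
                          precision = c("single", "double")) {
  precision <- match.arg(precision)
  if (!inherits(config, "rccg_config")) stop("config must be a network_config()")
  if (!is.null(seed)) set.seed(seed)
  ch <- config$stage_channels
  nstage <- length(ch)
  layers <- list()
  add <- function(l) layers[[l$name]] <<- l
  add(nn_conv("stem", 3L, 3L, ch[1L]))
  for (i in seq_len(nstage)) {
    for (b in seq_len(config$blocks_per_stage)) {
      nm <- sprintf("stage%d_scr%d", i, b)
      if (config$variant == "cnn3_no_scr") {
        # matched-width plain convolution stack in place of the SCR block
        add(nn_conv(paste0(nm, "a"), 3L, ch[i], ch[i]))
        add(nn_conv(paste0(nm, "b"), 3L, ch[i], ch[i]))
      } else {
        add(nn_scr(nm, ch[i],
                   sharing = config$variant != "cnn1_no_sharing",
                   gating = config$variant != "cnn2_no_gating",
                   strict_gate = config$strict_gate))
      }
    }
    if (i < nstage) {
      add(nn_pool(sprintf("pool%d", i)))
      add(nn_conv(sprintf("trans%d", i), 3L, ch[i], ch[i + 1L]))
    }
  }
  add(nn_gap("gap"))
  add(nn_dense("fc1", ch[nstage], config$hidden_units, act = "relu"))
  add(nn_dense("fc2", config$hidden_units, config$num_classes, act = "none"))
  structure(list(layers = layers, config = config,
                 use_float = precision == "single"),
            class = "rccg_model")
}

#' Build an ablation variant of RCCGNet
#'
#' Convenience wrapper over [build_rccgnet()] for the three ablations:
#' `cnn1_no_sharing` drops the cross-layer channel exchange (the two paths
#' process the raw input and convolved maps directly), `cnn2_no_gating`
#' removes the channel gates, and `cnn3_no_scr` replaces every SCR block
#' with a plain conv-BN-ReLU stack of matched width.
#'
#' @param config a [network_config()] whose `variant` is not `"full"`.
#' @param ... passed to [build_rccgnet()].
#' @return an `rccg_model`.
#' @export
build_ablation_variant <- function(config, ...) {
  if (config$variant == "full")
    stop("build_ablation_variant: config$variant must name an ablation")
  build_rccgnet(config, ...)
}

# full forward pass; returns logits plus per-layer caches (and, with
# record = TRUE, the output of every layer by name)
net_forward <- function(model, x, training = FALSE, record = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- vector("list", length(model$layers))
  names(caches) <- names(model$layers)
  outs <- if (record) caches
  for (ln in names(model$layers)) {
    r <- layer_forward(model$layers[[ln]], x, training, model$use_float)
    model$layers[[ln]] <- r$layer
    caches[[ln]] <- r$cache
    x <- r$out
    if (record) outs[[ln]] <- x
  }
  list(logits = x, caches = caches, model = model, outputs = outs)
}

# backward pass from d(loss)/d(logits); stop_at returns the gradient with
# respect to the *output* of the named layer (used by Grad-CAM)
net_backward <- function(model, caches, dlogits, stop_at = NULL) {
  grads <- list()
  d <- dlogits
  for (ln in rev(names(model$layers))) {
    if (!is.null(stop_at) && ln == stop_at)
      return(list(grads = grads, d_stop = d))
    r <- layer_backward(model$layers[[ln]], caches[[ln]], d,
                        model$use_float)
    grads[[ln]] <- r$grads
    d <- r$dx
  }
  list(grads = grads, d_input = d)
}

#' Class probabilities for a batch of patches
#'
#' Runs the network in inference mode (batch-norm uses running statistics)
#' and applies softmax to the logits.
#'
#' @param model an `rccg_model`.
#' @param x an `H x W x 3 x N` batch (or a single `H x W x 3` patch).
#' @param batch_size forward-pass micro-batch size.
#' @return an `N x num_classes` matrix of probabilities.
#' @export
predict_proba <- function(model, x, batch_size = 16L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4L]
  out <- matrix(NA_real_, n, model$config$num_classes)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    logits <- net_forward(model, x[, , , s:e, drop = FALSE])$logits
    out[s:e, ] <- t(apply(logits, 2L, softmax))
  }
  out
}

#' @rdname predict_proba
#' @param ... passed to `predict_proba`.
#' @return `predict_classes`: integer vector of 0-based class labels.
#' @export
predict_classes <- function(model, x, ...) {
  max.col(predict_proba(model, x, ...)) - 1L
}

# ---- functional single-map wrappers ---------------------------------------

#' Convolution, batch normalization and ReLU on a single feature map
#'
#' Functional form of the network's basic composite operation, useful for
#' inspecting the block mathematics with explicit weights.  Padding is
#' "same"; stride is 1.
#'
#' @param x `H x W x C` feature map.
#' @param kernel `k x k x C x Cout` weight array (k = 1 or 3).
#' @param bias optional length-`Cout` bias.
#' @param bn optional list with elements `gamma`, `beta`, `mean`, `var`:
#'   batch normalization applied with the given (fixed) statistics.
#'   `NULL` skips normalization.
#' @param activation one of `"relu"`, `"sigmoid"`, `"none"`.
#' @return the transformed `H x W x Cout` feature map.
#' @export
conv_bn_relu <- function(x, kernel, bias = NULL, bn = NULL,
                         activation = c("relu", "sigmoid", "none")) {
  activation <- match.arg(activation)
  feature_map(x)
  d <- dim(x)
  kd <- dim(kernel)
  if (kd[3L] != d[3L])
    stop("channel mismatch: input has ", d[3L], " channels, kernel expects ",
         kd[3L])
  x4 <- x
  dim(x4) <- c(d, 1L)
  z <- cpp_conv_fwd(x4, kernel, FALSE)
  if (!is.null(bias)) z <- z + rep(bias, each = prod(d[1:2]))
  if (!is.null(bn)) {
    r <- cpp_bn_fwd(z, bn$gamma, bn$beta, .BN_EPS, FALSE, bn$mean, bn$var)
    z <- r$out
  }
  out <- switch(activation, relu = .relu(z), sigmoid = .sigmoid(z), z)
  array(out, c(d[1:2], kd[4L]))
}

#' Channel gating by pooled global statistics
#'
#' Scales every channel of `z` by `sigmoid(W' gap(z) + b)`, the
#' squeeze-style attention used inside the SCR block (`gap` is global
#' average pooling; when batch-norm parameters are supplied the gating
#' branch normalizes the map before pooling).  Because the scale lies in
#' (0, 1), gating never increases the magnitude of any activation.
#'
#' @param z `H x W x C` feature map.
#' @param W `C x C` weight matrix of the 1x1 convolution.
#' @param b length-`C` bias.
#' @param bn optional fixed batch-norm statistics as in [conv_bn_relu()],
#'   applied to the gating branch's copy of `z` before pooling.
#' @return list with the gated map (`out`) and the per-channel `scale`.
#' @export
gate_channels <- function(z, W, b = rep(0, dim(z)[3L]), bn = NULL) {
  feature_map(z)
  d <- dim(z)
  if (!all(dim(W) == d[3L])) stop("gate weights must be C x C")
  zb <- z
  if (!is.null(bn)) {
    zb <- sweep(z, 3L, bn$mean)
    zb <- sweep(zb, 3L, bn$gamma / sqrt(bn$var + .BN_EPS), `*`)
    zb <- sweep(zb, 3L, bn$beta, `+`)
  }
  p <- colMeans(matrix(zb, prod(d[1:2])))
  u <- drop(crossprod(W, p)) + b
  s <- .sigmoid(u)
  list(out = z * rep(s, each = prod(d[1:2])), scale = s)
}

#' Apply one SCR block to a single feature map
#'
#' Functional wrapper running a (possibly hand-parameterized) SCR block in
#' inference mode.  Create the block with [scr_layer()] and modify its
#' parameter arrays directly to study the block's behaviour.
#'
#' @param x `H x W x C` feature map with `C` equal to the block width.
#' @param block an SCR block created by [scr_layer()].
#' @return the `H x W x C` block output.
#' @export
scr_block <- function(x, block) {
  feature_map(x)
  d <- dim(x)
  if (d[3L] != block$C)
    stop("input has ", d[3L], " channels but the block expects ", block$C)
  x4 <- x
  dim(x4) <- c(d, 1L)
  out <- .scr_fwd(block, x4, training = FALSE, use_float = FALSE)$out
  array(out, d)
}

#' Create a standalone SCR block
#'
#' @param channels even channel count `C`.
#' @param sharing,gating enable the cross-layer channel exchange and the
#'   channel gates.
#' @param strict_gate reuse the X-path gate on the Y path (literal
#'   equation form) instead of the symmetric per-path gates.
#' @param seed optional RNG seed for weight initialization.
#' @return an SCR block usable with [scr_block()].
#' @export
scr_layer <- function(channels, sharing = TRUE, gating = TRUE,
                      strict_gate = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nn_scr("scr", as.integer(channels), sharing, gating, strict_gate)
}

#' @export
print.rccg_model <- function(x, ...) {
  cat(sprintf("RCCGNet model (variant: %s)\n", x$config$variant))
  cat(sprintf("  input %dx%dx3, stages [%s] x%d, %d classes\n",
              x$config$input_size, x$config$input_size,
              paste(x$config$stage_channels, collapse = ", "),
              x$config$blocks_per_stage, x$config$num_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
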