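# Model complexity accounting: trainable parameters and forward-pass
# FLOPs.  Conventions (documented in the methods vignette): one
# multiply-accumulate counts as 2 FLOPs, so a convolution contributes
# 2*Hout*Wout*Cout*Cin*k^2 and a dense layer 2*in*out (+out for its
# bias); batch normalization costs 2 per element, activations and pooling
# 1 per element.

.count_layer_params <- function(layer) {
  n <- sum(vapply(layer$params, length, integer(1)))
  for (s in layer$sub) n <- n + .count_layer_params(s)
  n
}

#' Count trainable parameters
#'
#' Sums the lengths of every trainable array in the model: convolution and
#' dense weights, biases, and batch-norm scale/shift.  Running batch-norm
#' statistics are not trainable and are excluded.
#'
#' @param model an `rccg_model`.
#' @return integer parameter count (365,077 for the default network,
#'   i.e. 0.3651 M).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, .count_layer_params, numeric(1)))
}

.conv_flops <- function(layer, h, w) {
  f <- 2 * h * w * layer$cout * layer$cin * layer$k^2
  e <- h * w * layer$cout
  if (isTRUE(layer$bias)) f <- f + e
  if (layer$bn) f <- f + 2 * e
  if (layer$act != "none") f <- f + e
  f
}

.gate_flops <- function(C, h, w) {
  # branch BN + pool + 1x1 conv (bias) + sigmoid + broadcast multiply
  2 * h * w * C + h * w * C + (2 * C^2 + C) + C + h * w * C
}

.layer_flops <- function(layer, h, w) {
  switch(layer$type,
    conv = .conv_flops(layer, h, w),
    scr = {
      C <- layer$C
      f <- .conv_flops(layer$sub$conv1, h, w) +
        .conv_flops(layer$sub$conv_x, h, w) +
        .conv_flops(layer$sub$conv_y, h, w)
      if (layer$gating) f <- f + 2 * .gate_flops(C, h, w)
      f + 2 * h * w * C  # three-term residual sum
    },
    dense = 2 * layer$nin * layer$nout + layer$nout +
      if (layer$act != "none") layer$nout else 0,
    0)
}

# channels leaving a layer, given the channels entering it
layer_out_channels <- function(layer, cin) {
  switch(layer$type,
    conv = layer$cout,
    scr = layer$C,
    dense = layer$nout,
    cin)
}

#' Count forward-pass FLOPs
#'
#' Walks the network at the given input size, accumulating floating-point
#' operations for one forward pass of a single image under the
#' 2-FLOPs-per-multiply-accumulate convention (see the conventions at the
#' top of this file).  The softmax itself contributes `3 * num_classes`.
#'
#' @param model an `rccg_model`.
#' @param input_size input side length; defaults to the model's configured
#'   size.  The default 224 network costs about 4.48e9 FLOPs (4.48 G).
#' @return total FLOPs (numeric).
#' @export
count_flops <- function(model, input_size = model$config$input_size) {
  h <- w <- input_size
  cin <- 3L
  total <- 0
  for (layer in model$layers) {
    if (layer$type == "pool") {
      total <- total + (h / 2) * (w / 2) * cin
      h <- h / 2
      w <- w / 2
      next
    }
    if (layer$type == "gap") {
      total <- total + h * w * cin
      next
    }
    total <- total + .layer_flops(layer, h, w)
    cin <- layer_out_channels(layer, cin)
  }
  total + 3 * model$config$num_classes  # softmax
}

#' Layer-by-layer model summary
#'
#' @param model an `rccg_model`.
#' @param input_size input side length used to report output shapes.
#' @return a data frame with one row per layer: name, type, output shape,
#'   and trainable parameter count.
#' @export
model_summary <- function(model, input_size = model$config$input_size) {
  h <- w <- input_size
  cin <- 3L
  rows <- lapply(model$layers, function(layer) {
    if (layer$type == "pool") {
      h <<- h / 2
      w <<- w / 2
    }
    cin <<- layer_out_channels(layer, cin)
    shape <- if (layer$type %in% c("gap", "dense"))
      sprintf("(%d)", cin)
    else sprintf("(%d, %d, %d)", h, w, cin)
    data.frame(layer = layer$name, type = layer$type,
               output_shape = shape,
               parameters = .count_layer_params(layer))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Complexity report
#'
#' @param model an `rccg_model`.
#' @param input_size input side length for the FLOP count.
#' @param path optional file path; when given, the report is also written
#'   as JSON.
#' @return list with `parameters`, `flops` and `input_size`.
#' @export
complexity_report <- function(model, input_size = model$config$input_size,
                              path = NULL) {
  rep <- list(parameters = count_parameters(model),
              flops = count_flops(model, input_size),
              input_size = as.integer(input_size))
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  rep
}
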