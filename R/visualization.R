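# Grad-CAM activation maps, intermediate feature extraction, overlay
# rendering, learning curves and box-plot summaries.

# name of the deepest SCR block (or, for the no-SCR ablation, the deepest
# stage convolution)
.default_cam_layer <- function(model) {
  types <- vapply(model$layers, `[[`, "", "type")
  scr <- names(model$layers)[types == "scr"]
  if (length(scr) > 0L) return(scr[length(scr)])
  conv <- names(model$layers)[types == "conv"]
  conv[length(conv)]
}

#' Gradient-weighted class activation map (Grad-CAM)
#'
#' Backpropagates the (pre-softmax) score of `target_class` to the chosen
#' convolutional layer, global-average-pools the gradient per channel to
#' obtain channel weights, and forms `ReLU(sum_c w_c A_c)`.  The map is
#' bilinearly upsampled to the input size and min-max normalized to
#' `[0, 1]`; an all-zero map stays all-zero.
#'
#' @param model an `rccg_model`.
#' @param patch normalized `H x W x 3` input patch.
#' @param layer_id layer name (see [model_summary()]); default is the
#'   deepest SCR block, where class evidence is most localized.
#' @param target_class 0-based class whose evidence is mapped; default is
#'   the model's prediction.
#' @return list of class `rccg_activation_map` with fields `heatmap`
#'   (input-sized, in `[0, 1]`), `raw` (layer-sized, pre-normalization),
#'   `target_class` and `source_layer`.
#' @export
grad_cam <- function(model, patch, layer_id = NULL, target_class = NULL) {
  if (is.null(layer_id)) layer_id <- .default_cam_layer(model)
  if (!layer_id %in% names(model$layers))
    stop("unknown layer: ", layer_id)
  fw <- net_forward(model, patch, training = FALSE, record = TRUE)
  logits <- drop(fw$logits)
  if (is.null(target_class)) target_class <- which.max(logits) - 1L
  K <- length(logits)
  if (target_class < 0L || target_class >= K)
    stop("target_class out of range")
  donehot <- matrix(0, K, 1L)
  donehot[target_class + 1L, 1L] <- 1
  bw <- net_backward(fw$model, fw$caches, donehot, stop_at = layer_id)
  A <- fw$outputs[[layer_id]]
  dA <- bw$d_stop
  d <- dim(A)
  hw <- prod(d[1:2])
  alpha <- colMeans(matrix(dA, hw))              # pooled gradient, per channel
  raw <- matrix(matrix(A, hw) %*% alpha, d[1L], d[2L])
  raw <- .relu(raw)
  insz <- dim(patch)[1:2]
  up <- cpp_resize_bilinear(array(raw, c(d[1:2], 1L)), insz[1L], insz[2L])
  up <- array(up, insz)
  if (max(up) > 0) up <- (up - min(up)) / (max(up) - min(up))
  structure(list(heatmap = up, raw = raw,
                 target_class = as.integer(target_class),
                 source_layer = layer_id),
            class = "rccg_activation_map")
}

#' Channel slices of a stage's output feature map
#'
#' @param model an `rccg_model`.
#' @param patch normalized `H x W x 3` input patch.
#' @param stage_index stage number (1-based); the output of the stage's
#'   last block is returned, one single-channel map per configured
#'   channel (16/32/64 maps for the three default stages).
#' @return list of `H x W` matrices.
#' @export
intermediate_features <- function(model, patch, stage_index) {
  nstage <- length(model$config$stage_channels)
  if (stage_index < 1L || stage_index > nstage)
    stop("stage_index must be in 1..", nstage)
  b <- model$config$blocks_per_stage
  nm <- sprintf("stage%d_scr%d", stage_index, b)
  if (model$config$variant == "cnn3_no_scr") nm <- paste0(nm, "b")
  fw <- net_forward(model, patch, training = FALSE, record = TRUE)
  A <- fw$outputs[[nm]]
  d <- dim(A)
  lapply(seq_len(d[3L]), function(c) A[, , c, 1L])
}

#' Render a three-band activation overlay
#'
#' Colors the patch by activation strength: red for the highest band,
#' orange for the middle band and light blue for the lowest, leaving
#' zero-activation pixels untouched.  Default band edges are the tertiles
#' of the nonzero heatmap mass.
#'
#' @param patch display-range `H x W x 3` image in `[0, 1]`.
#' @param map an `rccg_activation_map` (or a normalized `H x W` matrix).
#' @param bands two increasing thresholds in (0, 1] splitting the nonzero
#'   activations into low/medium/high.
#' @param alpha blending weight of the color bands.
#' @return `H x W x 3` RGB array.
#' @export
render_overlay <- function(patch, map, bands = NULL, alpha = 0.45) {
  hm <- if (inherits(map, "rccg_activation_map")) map$heatmap else map
  if (!all(dim(hm) == dim(patch)[1:2]))
    stop("heatmap and patch sizes differ")
  if (is.null(bands)) {
    nz <- hm[hm > 0]
    if (length(nz) == 0L) return(patch)
    bands <- as.numeric(quantile(nz, c(1 / 3, 2 / 3)))
  }
  cols <- rbind(low = c(0.55, 0.80, 1.00),
                mid = c(1.00, 0.60, 0.10),
                high = c(1.00, 0.10, 0.10))
  out <- patch
  band <- matrix(0L, nrow(hm), ncol(hm))
  band[hm > 0] <- 1L                 # (0, b1): low
  band[hm >= bands[1L]] <- 2L        # [b1, b2): medium
  band[hm >= bands[2L]] <- 3L        # [b2, 1]: high

  for (b in 1:3) {
    sel <- band == b
    if (!any(sel)) next
    for (ch in 1:3)
      out[, , ch][sel] <- (1 - alpha) * patch[, , ch][sel] +
        alpha * cols[b, ch]
  }
  out
}

#' Five-number summary
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles computed by linear interpolation — the numbers a box plot
#' displays.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector `(min, q1, median, q3, max)`.
#' @export
five_number_summary <- function(values) {
  if (length(values) == 0L) stop("five_number_summary: empty input")
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Learning curves from a training history
#'
#' @param history the `history` data frame of a [train_model()] state.
#' @param metric `"accuracy"` or `"loss"`.
#' @return a ggplot object (requires the `ggplot2` package).
#' @export
plot_learning_curves <- function(history, metric = c("accuracy", "loss")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_learning_curves requires the ggplot2 package")
  cols <- if (metric == "accuracy") c("accuracy", "val_accuracy")
          else c("loss", "val_loss")
  df <- rbind(
    data.frame(epoch = history$epoch, value = history[[cols[1L]]],
               series = "training"),
    data.frame(epoch = history$epoch, value = history[[cols[2L]]],
               series = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = metric, x = "epoch") +
    ggplot2::theme_minimal()
}
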