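#' Gradient-weighted class activation maps
#'
#' `grad_cam()` computes the classic map: the gradient of the target-class
#' score with respect to a convolutional layer's activations is averaged
#' over space to give per-channel weights; the rectified weighted channel sum
#' is min-max normalized to [0,1]. `grad_cam_pp()` computes the ++ variant:
#' per-location weights `alpha = g^2 / (2 g^2 + sum_spatial(A * g^3))`
#' (zero-division guarded) replace the spatial mean, and channel weights are
#' `sum(alpha * relu(g))`, which sharpens maps when several regions
#' contribute. By default the gradient is taken from the pre-softmax score
#' of the target class on the merged output (standard CAM practice); set
#' `from = "prob"` to differentiate the softmax probability instead. For
#' classifier-level fusion models, per-branch maps are computed against the
#' merged prediction, so they show each backbone's contribution to the final
#' call.
#'
#' @param model A `fusion_model` or `fusion_fit`.
#' @param image H x W x C input image (preprocessed scale, [0,1]).
#' @param class_index Target class index (1-based).
#' @param layer Name of the convolutional layer to visualize; defaults to
#'   the model's last branch layer. Must emit a 4-D map.
#' @param from `"logit"` (default) or `"prob"`.
#' @return An object of class `saliency_map`: `heatmap` (layer-resolution
#'   matrix in [0,1]), `weights` (per-channel), `branch`, `class_index`,
#'   `method` and `all_zero` flag (no positive evidence).
#' @export
grad_cam <- function(model, image, class_index, layer = NULL,
                     from = c("logit", "prob")) {
  cam_core(model, image, class_index, layer, match.arg(from), pp = FALSE)
}

#' @rdname grad_cam
#' @export
grad_cam_pp <- function(model, image, class_index, layer = NULL,
                        from = c("logit", "prob")) {
  cam_core(model, image, class_index, layer, match.arg(from), pp = TRUE)
}

cam_core <- function(model, image, class_index, layer, from, pp) {
  if (inherits(model, "fusion_fit")) model <- model$model
  stopifnot(inherits(model, "fusion_model"))
  g <- model$graph
  if (is.null(layer))
    layer <- model$branch_layers[length(model$branch_layers)]
  if (!layer %in% g$order) stop("layer not in model graph: ", layer)
  if (length(nn_shape(g, layer)) != 3L)
    stop("saliency target must be a 4-D feature map: ", layer)
  n_classes <- model$config$n_classes
  if (class_index < 1L || class_index > n_classes)
    stop("class_index out of range")

  res <- cam_gradients(model, image, class_index, layer, from)
  A <- res$A; gr <- res$G
  d <- dim(A)

  if (!pp) {
    w <- colMeans(matrix(gr, d[1] * d[2], d[3]))
  } else {
    g2 <- gr^2
    ag3 <- matrix(A * gr^3, d[1] * d[2], d[3])
    denom <- 2 * g2 + rep(colSums(ag3), each = d[1] * d[2])
    alpha <- ifelse(abs(denom) < 1e-12, 0, g2 / denom)
    w <- colSums(matrix(alpha * pmax(gr, 0), d[1] * d[2], d[3]))
  }
  map <- matrix(matrix(A, d[1] * d[2], d[3]) %*% w, d[1], d[2])
  map <- pmax(map, 0)
  mx <- max(map); mn <- min(map)
  all_zero <- mx <= 0
  if (!all_zero) map <- if (mx > mn) (map - mn) / (mx - mn)
                        else matrix(1, nrow(map), ncol(map))
  branch <- names(model$branch_layers)[model$branch_layers == layer]
  structure(list(heatmap = map, weights = w,
                 branch = if (length(branch)) branch else layer,
                 class_index = class_index,
                 method = if (pp) "grad_cam_pp" else "grad_cam",
                 all_zero = all_zero),
            class = "saliency_map")
}

# forward + backward for one image; returns the layer activation (3-D) and
# the gradient of the target score w.r.t. it (3-D)
cam_gradients <- function(model, image, class_index, layer, from) {
  g <- model$graph
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  fw <- nn_forward(g, image, need_grads = TRUE)
  merged_probs <- model$outputs[length(model$outputs)]
  merged_logits <- model$logits[length(model$logits)]
  target_node <- if (from == "logit") merged_logits else merged_probs
  seed <- matrix(0, model$config$n_classes, 1L)
  seed[class_index, 1] <- 1
  bk <- nn_backward(g, fw, stats::setNames(list(seed), target_node))
  A <- fw$acts[[layer]]; G <- bk$grads[[layer]]
  if (is.null(G)) G <- array(0, dim(A))
  dim(A) <- dim(A)[1:3]
  dim(G) <- dim(G)[1:3]
  list(A = A, G = G, probs = fw$acts[[merged_probs]][, 1])
}

#' Saliency maps for every branch and the merged head
#'
#' @param model A `fusion_model` or `fusion_fit`.
#' @param image Input image.
#' @param class_index Target class (1-based); defaults to the predicted
#'   class.
#' @param method `"grad_cam"` or `"grad_cam_pp"`.
#' @param from Score to differentiate, see [grad_cam()].
#' @return Named list of `saliency_map` objects, one per branch layer.
#' @export
saliency_all_branches <- function(model, image,
                                  class_index = NULL,
                                  method = c("grad_cam_pp", "grad_cam"),
                                  from = "logit") {
  method <- match.arg(method)
  if (inherits(model, "fusion_fit")) model <- model$model
  if (is.null(class_index)) {
    p <- model_probs(model, image)
    class_index <- which.max(p[, 1])
  }
  fn <- if (method == "grad_cam") grad_cam else grad_cam_pp
  out <- lapply(model$branch_layers, function(l)
    fn(model, image, class_index, layer = l, from = from))
  names(out) <- names(model$branch_layers)
  out
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map> ", x$method, ", branch ", x$branch, ", class ",
      x$class_index, ", ", nrow(x$heatmap), "x", ncol(x$heatmap),
      if (x$all_zero) " (all zero: no positive evidence)", "\n", sep = "")
  invisible(x)
}

#' Bilinear upsampling of a heatmap
#'
#' @param map H x W matrix.
#' @param out_h,out_w Target size.
#' @return out_h x out_w matrix.
#' @export
bilinear_upsample <- function(map, out_h, out_w) {
  h <- nrow(map); w <- ncol(map)
  if (h == out_h && w == out_w) return(map)
  # align centers: output pixel centers mapped into input coordinates
  ry <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  rx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(rx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  m00 <- map[y0, x0, drop = FALSE]; m01 <- map[y0, x1, drop = FALSE]
  m10 <- map[y1, x0, drop = FALSE]; m11 <- map[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

#' Render a saliency overlay
#'
#' Upsamples the heatmap bilinearly to the image size, maps it through a
#' fixed blue-to-red colormap and alpha-blends it over the image.
#'
#' @param sal A `saliency_map`.
#' @param image H x W x 3 image in [0,1].
#' @param path Optional PNG output path; the raw upsampled heatmap can also
#'   be written as a whitespace-delimited text matrix via `matrix_path`.
#' @param alpha Blend weight of the heatmap; default 0.45.
#' @param matrix_path Optional text output for the upsampled heatmap.
#' @return The overlay H x W x 3 array, invisibly.
#' @export
render_overlay <- function(sal, image, path = NULL, alpha = 0.45,
                           matrix_path = NULL) {
  stopifnot(inherits(sal, "saliency_map"))
  d <- dim(image)
  hm <- bilinear_upsample(sal$heatmap, d[1], d[2])
  ramp <- grDevices::colorRamp(c("navy", "blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(hm)) / 255
  heat <- array(0, d)
  for (ch in 1:3) heat[, , ch] <- matrix(cols[, ch], d[1], d[2])
  overlay <- clip01((1 - alpha) * image + alpha * heat)
  if (!is.null(path)) png::writePNG(overlay, path)
  if (!is.null(matrix_path))
    utils::write.table(round(hm, 6), matrix_path, row.names = FALSE,
                       col.names = FALSE)
  invisible(overlay)
}
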