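# ---------------------------------------------------------------------------
# Fusion architectures: three strategies for combining multi-backbone
# features, with optional CBAM attention.
#   conv_reduce  — branches with larger spatial maps pass through one valid
#                  3x3 stride-1 convolution so all maps match, then channel
#                  concatenation, CBAM, GAP, dense head.
#   zero_pad     — branches with smaller maps are padded by rings of zeros up
#                  to the largest spatial dims, then as above.
#   dense_concat — classifier-level fusion: each branch gets its own CBAM,
#                  GAP and dense feature vector plus an auxiliary softmax
#                  head; the three dense vectors are concatenated into the
#                  merged classification layer. The model exposes four
#                  outputs and is trained on the sum of the four losses.
#   sum/mean/max — parallel (elementwise) feature fusion; requires identical
#                  branch map shapes.
# ---------------------------------------------------------------------------

#' Elementwise (parallel) feature-map fusion
#'
#' Combines feature maps of identical shape by elementwise sum, mean or max.
#' A shape mismatch is a hard error: shape identity is the defining
#' constraint of parallel fusion (use the conv_reduce or zero_pad strategies
#' for mismatched maps).
#'
#' @param maps List of numeric arrays of identical shape.
#' @param mode `"sum"`, `"mean"` or `"max"`.
#' @return A single array of the common shape.
#' @export
fuse_parallel <- function(maps, mode = c("sum", "mean", "max")) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 2L)
  shp <- lapply(maps, dim)
  if (!all(vapply(shp, function(s) identical(s, shp[[1]]), logical(1))))
    stop("parallel fusion requires identical feature-map shapes")
  switch(mode,
         sum = Reduce(`+`, maps),
         mean = Reduce(`+`, maps) / length(maps),
         max = Reduce(pmax, maps))
}

#' Pad a feature map with rings of zeros
#'
#' @param map H x W x C array.
#' @param rings Number of zero rings to add around the spatial dims.
#' @return (H + 2 rings) x (W + 2 rings) x C array with the original values
#'   centered and an exactly-zero border.
#' @export
zero_pad_map <- function(map, rings = 1L) {
  if (rings == 0L) return(map)
  d <- dim(map)
  out <- array(0, c(d[1] + 2L * rings, d[2] + 2L * rings, d[3]))
  out[rings + seq_len(d[1]), rings + seq_len(d[2]), ] <- map
  out
}

#' Convolutional block attention (CBAM)
#'
#' Appends a CBAM block to a graph: channel attention first (a shared
#' two-layer bottleneck applied to the global average- and max-pooled
#' descriptors, summed and passed through a sigmoid, gating the channels
#' multiplicatively), then spatial attention (a 7x7 convolution over the
#' concatenated channel-wise average and max planes, sigmoid, gating the
#' locations). Output shape equals input shape.
#'
#' @param g A [nn_graph()].
#' @param input Name of the feature-map node.
#' @param reduction_ratio Channel bottleneck ratio (default 16); the channel
#'   count must be divisible by it.
#' @param prefix Name prefix for the added nodes.
#' @param tag Node tag.
#' @return Name of the gated output node.
#' @export
cbam_block <- function(g, input, reduction_ratio = 16L, prefix = "cbam",
                       tag = "") {
  s <- nn_shape(g, input)
  stopifnot(length(s) == 3L)
  C <- s[3]
  if (C %% reduction_ratio != 0)
    stop("channel count ", C, " not divisible by reduction ratio ",
         reduction_ratio)
  p <- function(x) paste0(prefix, "_", x)
  avg <- nn_gap(g, p("avg"), input, tag = tag)
  mx <- nn_gmp(g, p("max"), input, tag = tag)
  f1a <- nn_dense(g, p("fc1_avg"), avg, C %/% reduction_ratio, "relu", tag = tag)
  f2a <- nn_dense(g, p("fc2_avg"), f1a, C, "linear", tag = tag)
  f1m <- nn_dense(g, p("fc1_max"), mx, NULL, "relu", tag = tag, share = f1a)
  f2m <- nn_dense(g, p("fc2_max"), f1m, NULL, "linear", tag = tag, share = f2a)
  casum <- nn_add(g, p("ch_sum"), c(f2a, f2m), tag = tag)
  cagate <- nn_activation(g, p("ch_gate"), casum, "sigmoid", tag = tag)
  chout <- nn_multiply(g, p("ch_out"), c(input, cagate), tag = tag)
  samean <- nn_channel_pool(g, p("sp_avg"), chout, "mean", tag = tag)
  samax <- nn_channel_pool(g, p("sp_max"), chout, "max", tag = tag)
  sacat <- nn_concat(g, p("sp_cat"), c(samean, samax), tag = tag)
  sagate <- nn_conv2d(g, p("sp_gate"), sacat, 1L, c(7L, 7L), 1L, "same",
                      "sigmoid", tag = tag)
  nn_multiply(g, p("out"), c(chout, sagate), tag = tag)
}

#' Fusion model configuration
#'
#' @param strategy One of `"conv_reduce"`, `"zero_pad"`, `"dense_concat"`,
#'   `"sum"`, `"mean"`, `"max"`.
#' @param backbones List of [backbone_spec()] objects (or standard
#'   architecture names); order defines branch order.
#' @param n_classes Number of output classes.
#' @param input_shape `c(H, W, C)` of the input images; default
#'   `c(450, 600, 3)`.
#' @param use_cbam Logical scalar or per-branch vector: insert CBAM after
#'   each backbone's final convolution (default `TRUE`).
#' @param cbam_reduction CBAM channel bottleneck ratio; default 16.
#' @param branch_dense_units Width of each branch's dense feature vector in
#'   the classifier-level strategy and of the merged head's dense layer;
#'   default 256.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(strategy = c("dense_concat", "conv_reduce",
                                       "zero_pad", "sum", "mean", "max"),
                          backbones, n_classes,
                          input_shape = c(450L, 600L, 3L),
                          use_cbam = TRUE, cbam_reduction = 16L,
                          branch_dense_units = 256L) {
  strategy <- match.arg(strategy)
  backbones <- lapply(backbones, function(b)
    if (inherits(b, "backbone_spec")) b else backbone(b))
  if (length(backbones) < 2L)
    stop("fusion requires at least 2 backbones")
  use_cbam <- rep_len(use_cbam, length(backbones))
  structure(list(strategy = strategy, backbones = backbones,
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 use_cbam = use_cbam,
                 cbam_reduction = as.integer(cbam_reduction),
                 branch_dense_units = as.integer(branch_dense_units)),
            class = "fusion_config")
}

#' Build a fusion model from a configuration
#'
#' Constructs the full layer graph for the configured strategy and
#' initializes its parameters. `build_fusion_conv_reduce`,
#' `build_fusion_zero_pad` and `build_fusion_dense_concat` are thin wrappers
#' fixing the strategy.
#'
#' @param cfg A [fusion_config()].
#' @param seed Seed for the random parameter initialization.
#' @param init Initialize parameters numerically (default `TRUE`; set
#'   `FALSE` for shape-only graphs such as the full-size standard backbones).
#' @return A list of class `fusion_model` with the graph, the output node
#'   names (auxiliary heads and/or `merged`), the per-branch saliency target
#'   layers and the configuration.
#' @export
build_fusion_model <- function(cfg, seed = 1L, init = TRUE) {
  stopifnot(inherits(cfg, "fusion_config"))
  g <- nn_graph(cfg$input_shape)
  nb <- names_for_branches(cfg)
  feats <- character(length(cfg$backbones))
  for (i in seq_along(cfg$backbones))
    feats[i] <- cfg$backbones[[i]]$build(g, "input", nb[i])

  branch_layers <- feats
  names(branch_layers) <- nb
  outputs <- character()
  logits_nodes <- character()

  if (cfg$strategy == "dense_concat") {
    dense_vecs <- character(length(feats))
    for (i in seq_along(feats)) {
      x <- feats[i]
      if (cfg$use_cbam[i]) {
        x <- cbam_block(g, x, cfg$cbam_reduction, paste0(nb[i], "_cbam"))
        branch_layers[i] <- x
      }
      v <- nn_gap(g, paste0(nb[i], "_gapv"), x)
      dv <- nn_dense(g, paste0(nb[i], "_dense"), v, cfg$branch_dense_units,
                     "relu")
      dense_vecs[i] <- dv
      lg <- nn_dense(g, paste0(nb[i], "_logits"), dv, cfg$n_classes)
      outputs <- c(outputs, nn_softmax(g, paste0(nb[i], "_probs"), lg))
      logits_nodes <- c(logits_nodes, lg)
    }
    cat_vec <- nn_concat(g, "merged_concat", dense_vecs)
    lg <- nn_dense(g, "merged_logits", cat_vec, cfg$n_classes)
    outputs <- c(outputs, nn_softmax(g, "merged_probs", lg))
    logits_nodes <- c(logits_nodes, lg)
  } else {
    shapes <- lapply(feats, function(f) nn_shape(g, f))
    hw <- vapply(shapes, function(s) s[1:2], integer(2))
    if (cfg$strategy %in% c("sum", "mean", "max")) {
      chans <- vapply(shapes, function(s) s[3], integer(1))
      if (length(unique(chans)) > 1L || length(unique(hw[1, ])) > 1L ||
          length(unique(hw[2, ])) > 1L)
        stop("parallel fusion requires identical feature-map shapes")
      fused <- nn_combine(g, "fused", feats, cfg$strategy)
    } else if (cfg$strategy == "conv_reduce") {
      target <- c(min(hw[1, ]), min(hw[2, ]))
      aligned <- feats
      for (i in seq_along(feats)) {
        s <- shapes[[i]]
        if (all(s[1:2] == target)) next
        ok <- tryCatch(conv_output_dims(s[1], s[2], f = 3L, p = 0L, s = 1L),
                       error = function(e) NULL)
        if (is.null(ok) || ok$h_out != target[1] || ok$w_out != target[2])
          stop("branch ", nb[i], " map ", s[1], "x", s[2],
               " is not reconcilable to ", target[1], "x", target[2],
               " by one valid 3x3 stride-1 convolution; ",
               "consider the zero_pad strategy")
        aligned[i] <- nn_conv2d(g, paste0(nb[i], "_reduce"), feats[i], s[3],
                                c(3L, 3L), 1L, "valid", "relu")
        branch_layers[i] <- aligned[i]
      }
      fused <- nn_concat(g, "fused", aligned)
    } else {  # zero_pad
      target <- c(max(hw[1, ]), max(hw[2, ]))
      aligned <- feats
      for (i in seq_along(feats)) {
        s <- shapes[[i]]
        if (all(s[1:2] == target)) next
        dh <- target[1] - s[1]; dw <- target[2] - s[2]
        if (dh != dw || dh %% 2L != 0L)
          stop("branch ", nb[i], " map ", s[1], "x", s[2],
               " cannot be ring-padded to ", target[1], "x", target[2])
        aligned[i] <- nn_zero_pad(g, paste0(nb[i], "_pad"), feats[i],
                                  rings = dh %/% 2L)
        branch_layers[i] <- aligned[i]
      }
      fused <- nn_concat(g, "fused", aligned)
    }
    x <- fused
    if (any(cfg$use_cbam))
      x <- cbam_block(g, x, cfg$cbam_reduction, "fused_cbam")
    v <- nn_gap(g, "merged_gap", x)
    dv <- nn_dense(g, "merged_feat", v, cfg$branch_dense_units, "relu")
    lg <- nn_dense(g, "merged_logits", dv, cfg$n_classes)
    outputs <- nn_softmax(g, "merged_probs", lg)
    logits_nodes <- lg
  }
  if (init) nn_init(g, seed)
  structure(list(graph = g, outputs = outputs, logits = logits_nodes,
                 branch_layers = branch_layers, config = cfg),
            class = "fusion_model")
}

names_for_branches <- function(cfg) {
  nb <- vapply(cfg$backbones, function(b) b$name, character(1))
  make.unique(nb, sep = "_")
}

#' @rdname build_fusion_model
#' @export
build_fusion_conv_reduce <- function(cfg, seed = 1L) {
  cfg$strategy <- "conv_reduce"
  build_fusion_model(cfg, seed)
}

#' @rdname build_fusion_model
#' @export
build_fusion_zero_pad <- function(cfg, seed = 1L) {
  cfg$strategy <- "zero_pad"
  build_fusion_model(cfg, seed)
}

#' @rdname build_fusion_model
#' @export
build_fusion_dense_concat <- function(cfg, seed = 1L) {
  cfg$strategy <- "dense_concat"
  build_fusion_model(cfg, seed)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model> strategy ", x$config$strategy, ", ",
      length(x$config$backbones), " backbones, ",
      length(x$outputs), " output(s), ",
      length(x$graph$order), " graph nodes\n", sep = "")
  cat("  branches:", paste(names(x$branch_layers), collapse = ", "), "\n")
  invisible(x)
}

#' Forward-pass class probabilities of a fusion model
#'
#' @param model A `fusion_model`.
#' @param x Input batch `c(H, W, C, N)` or single image `c(H, W, C)`.
#' @param output Which output node to read; default the merged head.
#' @return K x N matrix of class probabilities (columns sum to 1).
#' @export
model_probs <- function(model, x, output = NULL) {
  if (is.null(output)) output <- model$outputs[length(model$outputs)]
  fw <- nn_forward(model$graph, x)
  fw$acts[[output]]
}
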