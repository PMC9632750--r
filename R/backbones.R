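# ---------------------------------------------------------------------------
# Backbone feature extractors.
#
# The three standard ImageNet architectures are encoded layer-by-layer as
# nn_graph builders, so their feature-map dimensions for any input size fall
# out of the convolution/pooling size arithmetic at graph-construction time.
# For a 450 x 600 x 3 input they emit (12, 17, 2048), (12, 17, 1536) and
# (14, 19, 2048) respectively. A tiny randomly initialized backbone is
# provided as a desk-scale stand-in that exercises every numeric code path.
# ---------------------------------------------------------------------------

#' Backbone specification
#'
#' @param name Backbone name.
#' @param build Function `(g, input, prefix)` appending the backbone's layers
#'   to graph `g` downstream of node `input` and returning the name of the
#'   final convolutional feature-map node. All appended nodes carry the tag
#'   `"backbone"` so the two-phase trainer can freeze them.
#' @param expected_map Optional `c(H, W, C)` the backbone is declared to emit
#'   for a 450 x 600 x 3 input.
#' @return A list of class `backbone_spec`.
#' @export
backbone_spec <- function(name, build, expected_map = NULL) {
  structure(list(name = name, build = build, expected_map = expected_map),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat("<backbone_spec> ", x$name,
      if (!is.null(x$expected_map))
        paste0("  450x600x3 -> (", paste(x$expected_map, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Standard backbone architectures
#'
#' Returns the [backbone_spec()] for one of the three standard ImageNet
#' architectures (`"inception_v3"`, `"inception_resnet_v2"`, `"xception"`),
#' encoded as complete layer graphs.
#'
#' @param name Architecture name.
#' @return A [backbone_spec()].
#' @export
#' @examples
#' backbone_feature_shape("xception", c(450L, 600L, 3L))  # 14 19 2048
backbone <- function(name = c("inception_v3", "inception_resnet_v2",
                              "xception")) {
  name <- match.arg(name)
  switch(name,
    inception_v3 = backbone_spec("inception_v3", build_inception_v3,
                                 c(12L, 17L, 2048L)),
    inception_resnet_v2 = backbone_spec("inception_resnet_v2",
                                        build_inception_resnet_v2,
                                        c(12L, 17L, 1536L)),
    xception = backbone_spec("xception", build_xception,
                             c(14L, 19L, 2048L)))
}

#' Feature-map shape of a backbone for a given input size
#'
#' Constructs the backbone's layer graph on the given input and reads the
#' final convolutional feature map's dimensions.
#'
#' @param name Standard architecture name (see [backbone()]) or a
#'   [backbone_spec()].
#' @param input_shape `c(H, W, C)`; default `c(450, 600, 3)`.
#' @return Integer `c(H, W, C)` of the emitted feature map.
#' @export
backbone_feature_shape <- function(name, input_shape = c(450L, 600L, 3L)) {
  spec <- if (inherits(name, "backbone_spec")) name else backbone(name)
  g <- nn_graph(input_shape)
  feat <- spec$build(g, "input", spec$name)
  nn_shape(g, feat)
}

#' Tiny randomly initialized backbone (test double)
#'
#' A small convolutional stack (two stride-2 convolutions and an adaptive
#' average pooling stage) that emits a feature map of the requested shape,
#' enabling desk-scale numeric tests of every fusion builder, including the
#' 12x17 vs 14x19 spatial-mismatch case.
#'
#' @param out_map `c(H, W, C)` of the emitted map.
#' @param name Backbone name (default derived from the map shape).
#' @param mid_channels Channels of the intermediate convolution; default 8.
#' @return A [backbone_spec()].
#' @export
tiny_backbone <- function(out_map, name = NULL, mid_channels = 8L) {
  out_map <- as.integer(out_map)
  if (is.null(name)) name <- paste0("tiny", paste(out_map, collapse = "x"))
  build <- function(g, input, prefix) {
    p <- function(s) paste0(prefix, "_", s)
    in_hw <- nn_shape(g, input)[1:2]
    c1 <- nn_conv2d(g, p("conv1"), input, mid_channels, c(3L, 3L), 2L,
                    "same", "relu", tag = "backbone")
    # only halve again if the requested map still fits afterwards
    s2 <- if (all(ceiling(in_hw / 4) >= out_map[1:2])) 2L else 1L
    c2 <- nn_conv2d(g, p("conv2"), c1, out_map[3], c(3L, 3L), s2,
                    "same", "relu", tag = "backbone")
    if (any(nn_shape(g, c2)[1:2] < out_map[1:2]))
      stop("tiny_backbone: input ", paste(in_hw, collapse = "x"),
           " too small for requested map ",
           paste(out_map[1:2], collapse = "x"))
    nn_adaptive_avgpool(g, p("feat"), c2, out_map[1:2], tag = "backbone")
  }
  backbone_spec(name, build, out_map)
}

# ---- standard architectures -------------------------------------------------

# helpers shared by the builders; every node is tagged "backbone"
.bb_ops <- function(g, prefix) {
  cnt <- new.env(parent = emptyenv()); cnt$i <- 0L
  nm <- function(s) { cnt$i <- cnt$i + 1L; paste0(prefix, "_", cnt$i, "_", s) }
  list(
    conv = function(input, filters, k = c(3L, 3L), s = 1L, pad = "same",
                    act = "relu")
      nn_conv2d(g, nm("conv"), input, filters, k, s, pad, act,
                tag = "backbone"),
    sep = function(input, filters, s = 1L, act = "relu")
      nn_separable_conv2d(g, nm("sep"), input, filters, c(3L, 3L), s, "same",
                          act, tag = "backbone"),
    maxpool = function(input, k = c(3L, 3L), s = 2L, pad = "valid")
      nn_maxpool(g, nm("maxpool"), input, k, s, pad, tag = "backbone"),
    avgpool = function(input, k = c(3L, 3L), s = 1L, pad = "same")
      nn_avgpool(g, nm("avgpool"), input, k, s, pad, tag = "backbone"),
    concat = function(inputs) nn_concat(g, nm("concat"), inputs,
                                        tag = "backbone"),
    add = function(inputs) nn_add(g, nm("add"), inputs, tag = "backbone"))
}

build_inception_v3 <- function(g, input, prefix = "inception_v3") {
  o <- .bb_ops(g, prefix)
  x <- o$conv(input, 32L, s = 2L, pad = "valid")
  x <- o$conv(x, 32L, pad = "valid")
  x <- o$conv(x, 64L)
  x <- o$maxpool(x)
  x <- o$conv(x, 80L, k = c(1L, 1L), pad = "valid")
  x <- o$conv(x, 192L, pad = "valid")
  x <- o$maxpool(x)

  mixed_a <- function(x, pool_ch) {
    b0 <- o$conv(x, 64L, k = c(1L, 1L))
    b1 <- o$conv(o$conv(x, 48L, k = c(1L, 1L)), 64L, k = c(5L, 5L))
    b2 <- o$conv(o$conv(o$conv(x, 64L, k = c(1L, 1L)), 96L), 96L)
    b3 <- o$conv(o$avgpool(x), pool_ch, k = c(1L, 1L))
    o$concat(c(b0, b1, b2, b3))
  }
  x <- mixed_a(x, 32L); x <- mixed_a(x, 64L); x <- mixed_a(x, 64L)

  # reduction to the 17x17 stage
  b0 <- o$conv(x, 384L, s = 2L, pad = "valid")
  b1 <- o$conv(o$conv(o$conv(x, 64L, k = c(1L, 1L)), 96L), 96L,
               s = 2L, pad = "valid")
  x <- o$concat(c(b0, b1, o$maxpool(x)))

  mixed_b <- function(x, c7) {
    b0 <- o$conv(x, 192L, k = c(1L, 1L))
    b1 <- o$conv(o$conv(o$conv(x, c7, k = c(1L, 1L)), c7, k = c(1L, 7L)),
                 192L, k = c(7L, 1L))
    b2 <- x
    for (spec in list(c(c7, 7, 1), c(c7, 1, 7), c(c7, 7, 1), c(192, 1, 7)))
      b2 <- o$conv(if (identical(b2, x)) o$conv(x, c7, k = c(1L, 1L)) else b2,
                   spec[1], k = c(spec[2], spec[3]))
    b3 <- o$conv(o$avgpool(x), 192L, k = c(1L, 1L))
    o$concat(c(b0, b1, b2, b3))
  }
  for (c7 in c(128L, 160L, 160L, 192L)) x <- mixed_b(x, c7)

  # reduction to the 8x8 stage
  b0 <- o$conv(o$conv(x, 192L, k = c(1L, 1L)), 320L, s = 2L, pad = "valid")
  b1 <- o$conv(o$conv(o$conv(o$conv(x, 192L, k = c(1L, 1L)),
                             192L, k = c(1L, 7L)), 192L, k = c(7L, 1L)),
               192L, s = 2L, pad = "valid")
  x <- o$concat(c(b0, b1, o$maxpool(x)))

  mixed_c <- function(x) {
    b0 <- o$conv(x, 320L, k = c(1L, 1L))
    b1in <- o$conv(x, 384L, k = c(1L, 1L))
    b1 <- o$concat(c(o$conv(b1in, 384L, k = c(1L, 3L)),
                     o$conv(b1in, 384L, k = c(3L, 1L))))
    b2in <- o$conv(o$conv(x, 448L, k = c(1L, 1L)), 384L)
    b2 <- o$concat(c(o$conv(b2in, 384L, k = c(1L, 3L)),
                     o$conv(b2in, 384L, k = c(3L, 1L))))
    b3 <- o$conv(o$avgpool(x), 192L, k = c(1L, 1L))
    o$concat(c(b0, b1, b2, b3))
  }
  x <- mixed_c(x); x <- mixed_c(x)
  x
}

build_inception_resnet_v2 <- function(g, input,
                                      prefix = "inception_resnet_v2") {
  o <- .bb_ops(g, prefix)
  x <- o$conv(input, 32L, s = 2L, pad = "valid")
  x <- o$conv(x, 32L, pad = "valid")
  x <- o$conv(x, 64L)
  x <- o$maxpool(x)
  x <- o$conv(x, 80L, k = c(1L, 1L), pad = "valid")
  x <- o$conv(x, 192L, pad = "valid")
  x <- o$maxpool(x)

  # mixed_5b
  b0 <- o$conv(x, 96L, k = c(1L, 1L))
  b1 <- o$conv(o$conv(x, 48L, k = c(1L, 1L)), 64L, k = c(5L, 5L))
  b2 <- o$conv(o$conv(o$conv(x, 64L, k = c(1L, 1L)), 96L), 96L)
  b3 <- o$conv(o$avgpool(x), 64L, k = c(1L, 1L))
  x <- o$concat(c(b0, b1, b2, b3))                       # 320 channels

  residual <- function(x, branches, ch_out) {
    mix <- o$concat(branches)
    up <- o$conv(mix, ch_out, k = c(1L, 1L), act = "linear")
    o$add(c(x, up))
  }
  for (i in 1:10) {                                      # block35
    b0 <- o$conv(x, 32L, k = c(1L, 1L))
    b1 <- o$conv(o$conv(x, 32L, k = c(1L, 1L)), 32L)
    b2 <- o$conv(o$conv(o$conv(x, 32L, k = c(1L, 1L)), 48L), 64L)
    x <- residual(x, c(b0, b1, b2), 320L)
  }
  # mixed_6a
  b0 <- o$conv(x, 384L, s = 2L, pad = "valid")
  b1 <- o$conv(o$conv(o$conv(x, 256L, k = c(1L, 1L)), 256L), 384L,
               s = 2L, pad = "valid")
  x <- o$concat(c(b0, b1, o$maxpool(x)))                 # 1088 channels
  for (i in 1:20) {                                      # block17
    b0 <- o$conv(x, 192L, k = c(1L, 1L))
    b1 <- o$conv(o$conv(o$conv(x, 128L, k = c(1L, 1L)), 160L, k = c(1L, 7L)),
                 192L, k = c(7L, 1L))
    x <- residual(x, c(b0, b1), 1088L)
  }
  # mixed_7a
  b0 <- o$conv(o$conv(x, 256L, k = c(1L, 1L)), 384L, s = 2L, pad = "valid")
  b1 <- o$conv(o$conv(x, 256L, k = c(1L, 1L)), 288L, s = 2L, pad = "valid")
  b2 <- o$conv(o$conv(o$conv(x, 256L, k = c(1L, 1L)), 288L), 320L,
               s = 2L, pad = "valid")
  x <- o$concat(c(b0, b1, b2, o$maxpool(x)))             # 2080 channels
  for (i in 1:10) {                                      # block8
    b0 <- o$conv(x, 192L, k = c(1L, 1L))
    b1 <- o$conv(o$conv(o$conv(x, 192L, k = c(1L, 1L)), 224L, k = c(1L, 3L)),
                 256L, k = c(3L, 1L))
    x <- residual(x, c(b0, b1), 2080L)
  }
  o$conv(x, 1536L, k = c(1L, 1L))                        # conv_7b
}

build_xception <- function(g, input, prefix = "xception") {
  o <- .bb_ops(g, prefix)
  x <- o$conv(input, 32L, s = 2L, pad = "valid")
  x <- o$conv(x, 64L, pad = "valid")
  down_block <- function(x, filters) {
    short <- o$conv(x, filters, k = c(1L, 1L), s = 2L, act = "linear")
    y <- o$sep(x, filters)
    y <- o$sep(y, filters)
    y <- o$maxpool(y, pad = "same")
    o$add(c(y, short))
  }
  x <- down_block(x, 128L)
  x <- down_block(x, 256L)
  x <- down_block(x, 728L)
  for (i in 1:8) {                                       # middle flow
    y <- o$sep(x, 728L); y <- o$sep(y, 728L); y <- o$sep(y, 728L)
    x <- o$add(c(y, x))
  }
  short <- o$conv(x, 1024L, k = c(1L, 1L), s = 2L, act = "linear")
  y <- o$sep(x, 728L)
  y <- o$sep(y, 1024L)
  y <- o$maxpool(y, pad = "same")
  x <- o$add(c(y, short))
  x <- o$sep(x, 1536L)
  o$sep(x, 2048L)
}
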