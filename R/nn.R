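# ---------------------------------------------------------------------------
# Minimal layer-graph neural-network engine.
#
# A graph is a DAG of named nodes over 4-D map activations (H, W, C, N) and
# 2-D vector activations (units, N). Shapes are inferred at node-insertion
# time from the convolution/pooling output-size arithmetic, so a built graph
# knows its feature-map dimensions without any numeric forward pass. Numeric
# forward and hand-derived backward passes are implemented for every op used
# by the trainable models; gradients are finite-difference checked in the
# test suite.
#
# Conventions: column-major arrays, row-major image semantics (dim 1 = rows =
# height), channels last, batch last. "same" padding follows the asymmetric
# convention of mainstream frameworks (total pad split with the extra cell at
# the bottom/right); "valid" uses floor((in - k) / s) + 1.
# ---------------------------------------------------------------------------

#' Convolution output dimensions
#'
#' Completes the standard convolution size formula
#' `W_out = (W_in - F + 2P) / S + 1` (and likewise for the height) and errors
#' when the result is not integral.
#'
#' @param h_in,w_in Input height and width.
#' @param f Filter size.
#' @param p Padding size (cells added on each side).
#' @param s Stride.
#' @return Named list with `h_out` and `w_out`.
#' @export
#' @examples
#' conv_output_dims(14, 19, f = 3, p = 0, s = 1)  # 12 x 17
conv_output_dims <- function(h_in, w_in, f, p = 0L, s = 1L) {
  num_h <- h_in - f + 2 * p
  num_w <- w_in - f + 2 * p
  if (num_h %% s != 0)
    stop("height ", h_in, " is not reconcilable: (", num_h, ") not divisible by stride ", s)
  if (num_w %% s != 0)
    stop("width ", w_in, " is not reconcilable: (", num_w, ") not divisible by stride ", s)
  out <- list(h_out = as.integer(num_h %/% s + 1L),
              w_out = as.integer(num_w %/% s + 1L))
  if (out$h_out < 1L || out$w_out < 1L)
    stop("non-positive output dimension for input ", h_in, "x", w_in)
  out
}

# framework-style output size: valid = floor((in-k)/s)+1, same = ceil(in/s)
.out_dim <- function(n, k, s, padding) {
  if (padding == "valid") {
    o <- (n - k) %/% s + 1L
    if (o < 1L) stop("window ", k, " larger than input ", n, " (valid padding)")
    o
  } else as.integer(ceiling(n / s))
}

.same_pad <- function(n, k, s) {
  o <- as.integer(ceiling(n / s))
  total <- max((o - 1L) * s + k - n, 0L)
  c(beg = total %/% 2L, end = total - total %/% 2L)
}

#' Create an empty layer graph
#'
#' @param input_shape Integer vector `c(H, W, C)` of the input maps.
#' @param name Name of the input node (default `"input"`).
#' @return A graph environment of class `nn_graph`.
#' @export
nn_graph <- function(input_shape, name = "input") {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$order <- character()
  g$params <- list()
  g$cache <- new.env(parent = emptyenv())
  class(g) <- "nn_graph"
  add_node(g, name, "input", character(), list(), as.integer(input_shape))
  g
}

add_node <- function(g, name, op, inputs, cfg, out_shape,
                     trainable = FALSE, tag = "", share = NULL) {
  if (name %in% g$order) stop("duplicate node name: ", name)
  missing_in <- setdiff(inputs, g$order)
  if (length(missing_in))
    stop("unknown input node(s): ", paste(missing_in, collapse = ", "))
  g$nodes[[name]] <- list(name = name, op = op, inputs = inputs, cfg = cfg,
                          out_shape = as.integer(out_shape),
                          trainable = trainable, tag = tag, share = share)
  g$order <- c(g$order, name)
  invisible(name)
}

#' Shape of a node's output
#'
#' @param g A `nn_graph`.
#' @param name Node name; default the last added node.
#' @return Integer vector: `c(H, W, C)` for maps, `c(units)` for vectors.
#' @export
nn_shape <- function(g, name = NULL) {
  if (is.null(name)) name <- g$order[length(g$order)]
  g$nodes[[name]]$out_shape
}

#' @export
print.nn_graph <- function(x, ...) {
  cat("<nn_graph> ", length(x$order), " nodes\n", sep = "")
  for (nm in x$order) {
    nd <- x$nodes[[nm]]
    cat(sprintf("  %-28s %-16s (%s)%s\n", nm, nd$op,
                paste(nd$out_shape, collapse = ","),
                if (nzchar(nd$tag)) paste0(" [", nd$tag, "]") else ""))
  }
  invisible(x)
}

in_shape <- function(g, inputs) lapply(inputs, function(i) g$nodes[[i]]$out_shape)

# ---- node constructors -----------------------------------------------------

#' Layer constructors for `nn_graph` objects
#'
#' Each constructor appends one named node, infers its output shape and
#' returns the node name so calls can be chained. `padding` is `"same"`
#' (output `ceiling(in/stride)`) or `"valid"` (`floor((in-k)/stride)+1`).
#' `nn_dense` nodes may share their weights with a previously added dense
#' node via `share` (used by the CBAM channel-attention bottleneck).
#'
#' @param g A [nn_graph()].
#' @param name Unique node name.
#' @param input,inputs Name(s) of upstream node(s).
#' @param filters,units Output channels / units.
#' @param kernel Length-2 kernel size.
#' @param stride Stride (scalar).
#' @param padding `"same"` or `"valid"`.
#' @param activation `NULL`, `"relu"`, `"sigmoid"` or `"linear"`.
#' @param use_bias Add a bias term (default `TRUE`).
#' @param tag Free-form node tag (e.g. `"backbone"`, used for freezing).
#' @param share Name of a dense node whose parameters this node reuses.
#' @param pool Length-2 pooling window.
#' @param out Target `c(H, W)` for adaptive average pooling.
#' @param rings Number of zero rings to add around the map.
#' @param mode Elementwise combine mode: `"sum"`, `"mean"` or `"max"`.
#' @param stat Channel-pool statistic: `"mean"` or `"max"`.
#' @param fun Activation name for `nn_activation`.
#' @return The node name, invisibly usable for chaining.
#' @name nn_layers
NULL

#' @rdname nn_layers
#' @export
nn_conv2d <- function(g, name, input, filters, kernel = c(3L, 3L), stride = 1L,
                      padding = "same", activation = NULL, use_bias = TRUE,
                      tag = "") {
  s <- in_shape(g, input)[[1]]
  stopifnot(length(s) == 3L)
  out <- c(.out_dim(s[1], kernel[1], stride, padding),
           .out_dim(s[2], kernel[2], stride, padding), as.integer(filters))
  add_node(g, name, "conv2d", input,
           list(kernel = as.integer(kernel), stride = as.integer(stride),
                padding = padding, activation = activation,
                use_bias = use_bias, c_in = s[3]),
           out, trainable = TRUE, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_depthwise_conv2d <- function(g, name, input, kernel = c(3L, 3L), stride = 1L,
                                padding = "same", activation = NULL, tag = "") {
  s <- in_shape(g, input)[[1]]
  out <- c(.out_dim(s[1], kernel[1], stride, padding),
           .out_dim(s[2], kernel[2], stride, padding), s[3])
  add_node(g, name, "depthwise_conv2d", input,
           list(kernel = as.integer(kernel), stride = as.integer(stride),
                padding = padding, activation = activation, c_in = s[3]),
           out, trainable = TRUE, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_separable_conv2d <- function(g, name, input, filters, kernel = c(3L, 3L),
                                stride = 1L, padding = "same",
                                activation = NULL, tag = "") {
  dw <- nn_depthwise_conv2d(g, paste0(name, "_dw"), input, kernel, stride,
                            padding, tag = tag)
  nn_conv2d(g, name, dw, filters, kernel = c(1L, 1L), stride = 1L,
            padding = "valid", activation = activation, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_maxpool <- function(g, name, input, pool = c(2L, 2L), stride = 2L,
                       padding = "valid", tag = "") {
  s <- in_shape(g, input)[[1]]
  out <- c(.out_dim(s[1], pool[1], stride, padding),
           .out_dim(s[2], pool[2], stride, padding), s[3])
  add_node(g, name, "maxpool", input,
           list(pool = as.integer(pool), stride = as.integer(stride),
                padding = padding), out, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_avgpool <- function(g, name, input, pool = c(2L, 2L), stride = 2L,
                       padding = "valid", tag = "") {
  s <- in_shape(g, input)[[1]]
  out <- c(.out_dim(s[1], pool[1], stride, padding),
           .out_dim(s[2], pool[2], stride, padding), s[3])
  add_node(g, name, "avgpool", input,
           list(pool = as.integer(pool), stride = as.integer(stride),
                padding = padding), out, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_adaptive_avgpool <- function(g, name, input, out, tag = "") {
  s <- in_shape(g, input)[[1]]
  add_node(g, name, "adaptive_avgpool", input, list(out = as.integer(out)),
           c(as.integer(out), s[3]), tag = tag)
}

#' @rdname nn_layers
#' @export
nn_gap <- function(g, name, input, tag = "") {
  s <- in_shape(g, input)[[1]]
  add_node(g, name, "gap", input, list(), s[3], tag = tag)
}

#' @rdname nn_layers
#' @export
nn_gmp <- function(g, name, input, tag = "") {
  s <- in_shape(g, input)[[1]]
  add_node(g, name, "gmp", input, list(), s[3], tag = tag)
}

#' @rdname nn_layers
#' @export
nn_channel_pool <- function(g, name, input, stat = c("mean", "max"), tag = "") {
  stat <- match.arg(stat)
  s <- in_shape(g, input)[[1]]
  add_node(g, name, "channel_pool", input, list(stat = stat),
           c(s[1], s[2], 1L), tag = tag)
}

#' @rdname nn_layers
#' @export
nn_dense <- function(g, name, input, units, activation = NULL,
                     use_bias = TRUE, tag = "", share = NULL) {
  s <- in_shape(g, input)[[1]]
  stopifnot(length(s) == 1L)
  if (!is.null(share)) {
    owner <- g$nodes[[share]]
    if (is.null(owner) || owner$op != "dense")
      stop("share must reference an existing dense node")
    units <- owner$out_shape[1]
  }
  add_node(g, name, "dense", input,
           list(units = as.integer(units), activation = activation,
                use_bias = use_bias, n_in = s[1]),
           as.integer(units), trainable = is.null(share), tag = tag,
           share = share)
}

#' @rdname nn_layers
#' @export
nn_activation <- function(g, name, input, fun = c("relu", "sigmoid", "softmax"),
                          tag = "") {
  fun <- match.arg(fun)
  s <- in_shape(g, input)[[1]]
  add_node(g, name, "activation", input, list(fun = fun), s, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_add <- function(g, name, inputs, tag = "") {
  shp <- in_shape(g, inputs)
  if (!all(vapply(shp, function(s) identical(s, shp[[1]]), logical(1))))
    stop("nn_add requires identical input shapes")
  add_node(g, name, "combine", inputs, list(mode = "sum"), shp[[1]], tag = tag)
}

#' @rdname nn_layers
#' @export
nn_combine <- function(g, name, inputs, mode = c("sum", "mean", "max"), tag = "") {
  mode <- match.arg(mode)
  shp <- in_shape(g, inputs)
  if (!all(vapply(shp, function(s) identical(s, shp[[1]]), logical(1))))
    stop("parallel fusion requires identical feature-map shapes; got ",
         paste(vapply(shp, paste, "", collapse = "x"), collapse = " vs "))
  add_node(g, name, "combine", inputs, list(mode = mode), shp[[1]], tag = tag)
}

#' @rdname nn_layers
#' @export
nn_concat <- function(g, name, inputs, tag = "") {
  shp <- in_shape(g, inputs)
  if (length(shp[[1]]) == 3L) {
    hw <- lapply(shp, function(s) s[1:2])
    if (!all(vapply(hw, function(s) identical(s, hw[[1]]), logical(1))))
      stop("channel concatenation requires identical spatial dimensions")
    out <- c(shp[[1]][1:2], sum(vapply(shp, function(s) s[3], integer(1))))
  } else {
    out <- sum(vapply(shp, function(s) s[1], integer(1)))
  }
  add_node(g, name, "concat", inputs, list(), out, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_multiply <- function(g, name, inputs, tag = "") {
  stopifnot(length(inputs) == 2L)
  shp <- in_shape(g, inputs)
  main <- shp[[1]]; gate <- shp[[2]]
  ok <- length(main) == 3L &&
    ((length(gate) == 1L && gate[1] == main[3]) ||
     (length(gate) == 3L && gate[3] == 1L && all(gate[1:2] == main[1:2])))
  if (!ok) stop("nn_multiply expects (map, channel-gate vector) or (map, spatial-gate map)")
  add_node(g, name, "multiply", inputs, list(), main, tag = tag)
}

#' @rdname nn_layers
#' @export
nn_zero_pad <- function(g, name, input, rings = 1L, tag = "") {
  s <- in_shape(g, input)[[1]]
  add_node(g, name, "zero_pad", input, list(rings = as.integer(rings)),
           c(s[1] + 2L * rings, s[2] + 2L * rings, s[3]), tag = tag)
}

#' @rdname nn_layers
#' @export
nn_softmax <- function(g, name, input, tag = "") {
  s <- in_shape(g, input)[[1]]
  stopifnot(length(s) == 1L)
  add_node(g, name, "softmax", input, list(), s, tag = tag)
}

# ---- parameter initialization ---------------------------------------------

param_shapes <- function(nd) {
  switch(nd$op,
    conv2d = {
      k <- nd$cfg$kernel
      ps <- list(W = c(k[1], k[2], nd$cfg$c_in, nd$out_shape[3]))
      if (nd$cfg$use_bias) ps$b <- nd$out_shape[3]
      ps
    },
    depthwise_conv2d = {
      k <- nd$cfg$kernel
      list(W = c(k[1], k[2], nd$cfg$c_in))
    },
    dense = {
      ps <- list(W = c(nd$cfg$n_in, nd$cfg$units))
      if (nd$cfg$use_bias) ps$b <- nd$cfg$units
      ps
    },
    NULL)
}

#' Initialize graph parameters (Glorot uniform)
#'
#' @param g A [nn_graph()].
#' @param seed Integer seed.
#' @return The graph, invisibly; parameters live in `g$params`.
#' @export
nn_init <- function(g, seed = 1L) {
  rng <- local_rng(seed)
  for (nm in g$order) {
    nd <- g$nodes[[nm]]
    if (!is.null(nd$share)) next
    ps <- param_shapes(nd)
    if (is.null(ps)) next
    fan <- switch(nd$op,
      conv2d = {
        k <- nd$cfg$kernel
        c(k[1] * k[2] * nd$cfg$c_in, k[1] * k[2] * nd$out_shape[3])
      },
      depthwise_conv2d = {
        k <- nd$cfg$kernel; c(k[1] * k[2], k[1] * k[2])
      },
      dense = c(nd$cfg$n_in, nd$cfg$units))
    lim <- sqrt(6 / (fan[1] + fan[2]))
    g$params[[nm]] <- lapply(ps, function(shape) {
      if (length(shape) == 1L) numeric(shape)
      else array(rng$runif(prod(shape), -lim, lim), shape)
    })
  }
  invisible(g)
}

# owner of a node's parameters (follows weight sharing)
param_owner <- function(g, nm) {
  sh <- g$nodes[[nm]]$share
  if (is.null(sh)) nm else sh
}

# ---- geometry caches -------------------------------------------------------

conv_geom <- function(g, nm, in_h, in_w, k, s, padding, c_in) {
  key <- paste0("geom_", nm)
  if (!is.null(g$cache[[key]])) return(g$cache[[key]])
  if (padding == "same") {
    ph <- .same_pad(in_h, k[1], s); pw <- .same_pad(in_w, k[2], s)
  } else {
    ph <- c(beg = 0L, end = 0L); pw <- c(beg = 0L, end = 0L)
  }
  hp <- in_h + sum(ph); wp <- in_w + sum(pw)
  out_h <- .out_dim(in_h, k[1], s, padding)
  out_w <- .out_dim(in_w, k[2], s, padding)
  npos <- out_h * out_w
  oh <- rep(seq_len(out_h), times = out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  top <- (oh - 1L) * s + 1L
  left <- (ow - 1L) * s + 1L
  dh <- rep(seq_len(k[1]) - 1L, times = k[2])
  dw <- rep(seq_len(k[2]) - 1L, each = k[1])
  iplane <- outer(top, dh, "+") + (outer(left, dw, "+") - 1L) * hp  # npos x k1k2
  if (c_in > 1L) {
    ifull <- iplane[, rep(seq_len(ncol(iplane)), times = c_in), drop = FALSE] +
      matrix(rep((seq_len(c_in) - 1L) * (hp * wp), each = ncol(iplane)),
             npos, ncol(iplane) * c_in, byrow = TRUE)
  } else ifull <- iplane
  geom <- list(ph = ph, pw = pw, hp = hp, wp = wp, out_h = out_h,
               out_w = out_w, npos = npos, iplane = iplane, ifull = ifull,
               in_h = in_h, in_w = in_w)
  g$cache[[key]] <- geom
  geom
}

# extract sample i of a (H, W, C, N) batch as a 3-D array, never dropping dims
slice4 <- function(a, i) {
  x <- a[, , , i, drop = FALSE]
  dim(x) <- dim(a)[1:3]
  x
}

pad_sample <- function(x, geom, fill = 0) {
  if (geom$hp == dim(x)[1] && geom$wp == dim(x)[2]) return(x)
  xp <- array(fill, c(geom$hp, geom$wp, dim(x)[3]))
  xp[geom$ph["beg"] + seq_len(dim(x)[1]),
     geom$pw["beg"] + seq_len(dim(x)[2]), ] <- x
  xp
}

crop_sample <- function(xp, geom) {
  xp[geom$ph["beg"] + seq_len(geom$in_h),
     geom$pw["beg"] + seq_len(geom$in_w), , drop = FALSE]
}

# scatter-add values into a zero vector of length n, grouped by idx
scatter_add <- function(n, idx, vals) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

apply_act <- function(x, act) {
  if (is.null(act) || act == "linear") x
  else if (act == "relu") pmax(x, 0)
  else if (act == "sigmoid") 1 / (1 + exp(-x))
  else stop("unknown activation: ", act)
}

act_grad <- function(pre, out, grad, act) {
  if (is.null(act) || act == "linear") grad
  else if (act == "relu") grad * (pre > 0)
  else if (act == "sigmoid") grad * out * (1 - out)
  else stop("unknown activation: ", act)
}

adaptive_cells <- function(g, nm, in_hw, out_hw) {
  key <- paste0("geom_", nm)
  if (!is.null(g$cache[[key]])) return(g$cache[[key]])
  if (any(out_hw > in_hw))
    stop("adaptive average pooling cannot upsample: input ",
         paste(in_hw, collapse = "x"), " to output ",
         paste(out_hw, collapse = "x"))
  bin <- function(n_in, n_out) {
    # contiguous near-equal bins: row h belongs to bin floor((h-1)*n_out/n_in)+1
    as.integer(floor((seq_len(n_in) - 1L) * n_out / n_in) + 1L)
  }
  rb <- bin(in_hw[1], out_hw[1])
  cb <- bin(in_hw[2], out_hw[2])
  cellid <- rb[row(matrix(0, in_hw[1], in_hw[2]))] +
    (cb[col(matrix(0, in_hw[1], in_hw[2]))] - 1L) * out_hw[1]
  counts <- tabulate(cellid, nbins = prod(out_hw))
  geom <- list(cellid = as.vector(cellid), counts = counts)
  g$cache[[key]] <- geom
  geom
}

# ---- forward ----------------------------------------------------------------

#' Run a forward pass
#'
#' @param g An initialized [nn_graph()].
#' @param x Input batch: array `c(H, W, C, N)` (a single `c(H, W, C)` image is
#'   promoted to a batch of one).
#' @param need_grads Keep the caches required by [nn_backward()].
#' @param override Named list mapping node names to replacement activations;
#'   the node's computation is skipped and the supplied values are used
#'   downstream (used by the finite-difference tests).
#' @return List with `acts` (environment of node activations) and `caches`.
#' @export
nn_forward <- function(g, x, need_grads = FALSE, override = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  acts <- new.env(parent = emptyenv())
  caches <- new.env(parent = emptyenv())
  for (nm in g$order) {
    nd <- g$nodes[[nm]]
    if (!is.null(override) && nm %in% names(override)) {
      a <- override[[nm]]
      if (length(nd$out_shape) == 3L && length(dim(a)) == 3L)
        dim(a) <- c(dim(a), 1L)
      acts[[nm]] <- a
      next
    }
    ins <- lapply(nd$inputs, function(i) acts[[i]])
    res <- op_forward(g, nd, ins, x, need_grads)
    acts[[nm]] <- res$out
    if (need_grads && !is.null(res$cache)) caches[[nm]] <- res$cache
  }
  list(acts = acts, caches = caches)
}

batch_n <- function(a) if (is.matrix(a)) ncol(a) else dim(a)[length(dim(a))]

op_forward <- function(g, nd, ins, x, need_grads) {
  op <- nd$op
  if (op == "input") return(list(out = x))
  a <- ins[[1]]
  pw <- g$params[[param_owner(g, nd$name)]]

  if (op == "conv2d" || op == "depthwise_conv2d") {
    k <- nd$cfg$kernel; s <- nd$cfg$stride
    d <- dim(a); n <- d[4]
    geom <- conv_geom(g, nd$name, d[1], d[2], k, s, nd$cfg$padding, nd$cfg$c_in)
    cout <- nd$out_shape[3]
    out <- array(0, c(geom$out_h, geom$out_w, cout, n))
    xp_list <- if (need_grads) vector("list", n) else NULL
    pre_list <- if (need_grads) vector("list", n) else NULL
    if (op == "conv2d") {
      wm <- matrix(pw$W, ncol = cout)
      for (i in seq_len(n)) {
        xp <- pad_sample(slice4(a, i), geom)
        p <- matrix(xp[geom$ifull], geom$npos)
        pre <- p %*% wm
        if (!is.null(pw$b)) pre <- pre + rep(pw$b, each = geom$npos)
        o <- apply_act(pre, nd$cfg$activation)
        out[, , , i] <- o
        if (need_grads) { xp_list[[i]] <- xp; pre_list[[i]] <- pre }
      }
    } else {
      # depthwise: each channel convolved with its own k x k filter
      wm <- matrix(pw$W, ncol = nd$cfg$c_in)  # (k1*k2, C)
      for (i in seq_len(n)) {
        xp <- pad_sample(slice4(a, i), geom)
        pre <- matrix(0, geom$npos, nd$cfg$c_in)
        for (ch in seq_len(nd$cfg$c_in)) {
          pch <- matrix(xp[geom$iplane + (ch - 1L) * (geom$hp * geom$wp)],
                        geom$npos)
          pre[, ch] <- pch %*% wm[, ch]
        }
        o <- apply_act(pre, nd$cfg$activation)
        out[, , , i] <- o
        if (need_grads) { xp_list[[i]] <- xp; pre_list[[i]] <- pre }
      }
    }
    return(list(out = out,
                cache = if (need_grads) list(xp = xp_list, pre = pre_list)))
  }

  if (op == "maxpool" || op == "avgpool") {
    k <- nd$cfg$pool; s <- nd$cfg$stride
    d <- dim(a); n <- d[4]; C <- d[3]
    geom <- conv_geom(g, nd$name, d[1], d[2], k, s, nd$cfg$padding, 1L)
    out <- array(0, c(geom$out_h, geom$out_w, C, n))
    arg <- if (need_grads && op == "maxpool")
      array(0L, c(geom$npos, C, n)) else NULL
    for (i in seq_len(n)) {
      xp <- pad_sample(slice4(a, i), geom,
                       fill = if (op == "maxpool") -Inf else 0)
      for (ch in seq_len(C)) {
        m <- matrix(xp[geom$iplane + (ch - 1L) * (geom$hp * geom$wp)],
                    geom$npos)
        if (op == "maxpool") {
          j <- max.col(m, ties.method = "first")
          out[, , ch, i] <- m[cbind(seq_len(geom$npos), j)]
          if (!is.null(arg)) arg[, ch, i] <- j
        } else {
          out[, , ch, i] <- rowMeans(m)
        }
      }
    }
    return(list(out = out, cache = if (need_grads) list(arg = arg)))
  }

  if (op == "adaptive_avgpool") {
    d <- dim(a); n <- d[4]; C <- d[3]
    geom <- adaptive_cells(g, nd$name, d[1:2], nd$cfg$out)
    out <- array(0, c(nd$cfg$out, C, n))
    for (i in seq_len(n)) {
      m <- matrix(a[, , , i], d[1] * d[2], C)
      out[, , , i] <- rowsum(m, geom$cellid) / geom$counts
    }
    return(list(out = out, cache = NULL))
  }

  if (op == "gap") {
    d <- dim(a); n <- d[4]
    out <- vapply(seq_len(n),
                  function(i) colMeans(matrix(a[, , , i], d[1] * d[2], d[3])),
                  numeric(d[3]))
    if (is.null(dim(out))) dim(out) <- c(d[3], n)
    return(list(out = out))
  }

  if (op == "gmp") {
    d <- dim(a); n <- d[4]
    out <- matrix(0, d[3], n)
    arg <- if (need_grads) matrix(0L, d[3], n) else NULL
    for (i in seq_len(n)) {
      m <- matrix(a[, , , i], d[1] * d[2], d[3])
      j <- max.col(t(m), ties.method = "first")
      out[, i] <- m[cbind(j, seq_len(d[3]))]
      if (need_grads) arg[, i] <- j
    }
    return(list(out = out, cache = if (need_grads) list(arg = arg)))
  }

  if (op == "channel_pool") {
    d <- dim(a); n <- d[4]
    out <- array(0, c(d[1], d[2], 1L, n))
    arg <- if (need_grads && nd$cfg$stat == "max")
      matrix(0L, d[1] * d[2], n) else NULL
    for (i in seq_len(n)) {
      m <- matrix(a[, , , i], d[1] * d[2], d[3])
      if (nd$cfg$stat == "mean") out[, , 1, i] <- rowMeans(m)
      else {
        j <- max.col(m, ties.method = "first")
        out[, , 1, i] <- m[cbind(seq_len(nrow(m)), j)]
        if (!is.null(arg)) arg[, i] <- j
      }
    }
    return(list(out = out, cache = if (need_grads) list(arg = arg)))
  }

  if (op == "dense") {
    pre <- crossprod(pw$W, a)
    if (!is.null(pw$b)) pre <- pre + pw$b
    out <- apply_act(pre, nd$cfg$activation)
    return(list(out = out, cache = if (need_grads) list(pre = pre)))
  }

  if (op == "activation") {
    f <- nd$cfg$fun
    if (f == "softmax") return(list(out = softmax_cols(a)))
    return(list(out = apply_act(a, f)))
  }

  if (op == "softmax") return(list(out = softmax_cols(a)))

  if (op == "combine") {
    mode <- nd$cfg$mode
    if (mode == "sum" || mode == "mean") {
      out <- Reduce(`+`, ins)
      if (mode == "mean") out <- out / length(ins)
      return(list(out = out))
    }
    out <- ins[[1]]; arg <- array(1L, dim(out))
    for (j in seq_along(ins)[-1]) {
      upd <- ins[[j]] > out
      arg[upd] <- j
      out[upd] <- ins[[j]][upd]
    }
    return(list(out = out, cache = if (need_grads) list(arg = arg)))
  }

  if (op == "concat") {
    if (length(nd$out_shape) == 3L) {
      d1 <- dim(ins[[1]]); n <- d1[4]
      out <- array(0, c(d1[1], d1[2], nd$out_shape[3], n))
      off <- 0L
      for (v in ins) {
        cc <- dim(v)[3]
        out[, , off + seq_len(cc), ] <- v
        off <- off + cc
      }
    } else out <- do.call(rbind, ins)
    return(list(out = out))
  }

  if (op == "multiply") {
    m <- ins[[1]]; gate <- ins[[2]]
    d <- dim(m); n <- d[4]
    out <- m
    for (i in seq_len(n)) {
      if (is.matrix(gate)) out[, , , i] <- m[, , , i] * rep(gate[, i], each = d[1] * d[2])
      else out[, , , i] <- m[, , , i] * as.vector(gate[, , 1, i])
    }
    return(list(out = out))
  }

  if (op == "zero_pad") {
    r <- nd$cfg$rings
    d <- dim(a); n <- d[4]
    out <- array(0, c(d[1] + 2L * r, d[2] + 2L * r, d[3], n))
    out[r + seq_len(d[1]), r + seq_len(d[2]), , ] <- a
    return(list(out = out))
  }

  stop("unknown op: ", op)
}

softmax_cols <- function(x) {
  z <- exp(sweep(x, 2, apply(x, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# ---- backward ---------------------------------------------------------------

#' Run a backward pass
#'
#' Propagates gradients from seed nodes back through the graph.
#'
#' @param g An initialized [nn_graph()].
#' @param fw Result of `nn_forward(..., need_grads = TRUE)`.
#' @param seeds Named list: node name -> gradient of the scalar objective
#'   with respect to that node's output (same shape as the activation).
#' @return List with `grads` (environment: gradients w.r.t. every node
#'   output) and `pgrads` (list: gradients w.r.t. parameters, keyed by the
#'   owning node name).
#' @export
nn_backward <- function(g, fw, seeds) {
  acts <- fw$acts; caches <- fw$caches
  grads <- new.env(parent = emptyenv())
  pgrads <- list()
  add_grad <- function(nm, val) {
    if (is.null(grads[[nm]])) grads[[nm]] <- val
    else grads[[nm]] <- grads[[nm]] + val
  }
  for (nm in names(seeds)) {
    sd <- seeds[[nm]]
    a <- acts[[nm]]
    if (!is.matrix(a) && length(dim(sd)) == 3L) dim(sd) <- c(dim(sd), 1L)
    add_grad(nm, sd)
  }
  for (nm in rev(g$order)) {
    go <- grads[[nm]]
    if (is.null(go)) next
    nd <- g$nodes[[nm]]
    res <- op_backward(g, nd, go, acts, caches[[nm]])
    for (j in seq_along(nd$inputs)) add_grad(nd$inputs[j], res$gin[[j]])
    if (!is.null(res$gp)) {
      owner <- param_owner(g, nm)
      if (is.null(pgrads[[owner]])) pgrads[[owner]] <- res$gp
      else pgrads[[owner]] <- Map(`+`, pgrads[[owner]], res$gp)
    }
  }
  list(grads = grads, pgrads = pgrads)
}

op_backward <- function(g, nd, go, acts, cache) {
  op <- nd$op
  ins <- lapply(nd$inputs, function(i) acts[[i]])
  pw <- g$params[[param_owner(g, nd$name)]]

  if (op == "conv2d" || op == "depthwise_conv2d") {
    a <- ins[[1]]; d <- dim(a); n <- d[4]
    k <- nd$cfg$kernel
    geom <- g$cache[[paste0("geom_", nd$name)]]
    cout <- nd$out_shape[3]
    gin <- array(0, d)
    if (op == "conv2d") {
      wm <- matrix(pw$W, ncol = cout)
      gw <- matrix(0, nrow(wm), cout)
      gb <- if (!is.null(pw$b)) numeric(cout) else NULL
      for (i in seq_len(n)) {
        gmat <- matrix(go[, , , i], geom$npos, cout)
        gmat <- act_grad(cache$pre[[i]],
                         matrix(acts[[nd$name]][, , , i], geom$npos, cout),
                         gmat, nd$cfg$activation)
        xp <- cache$xp[[i]]
        p <- matrix(xp[geom$ifull], geom$npos)
        gw <- gw + crossprod(p, gmat)
        if (!is.null(gb)) gb <- gb + colSums(gmat)
        gp <- gmat %*% t(wm)                       # npos x (k1*k2*Cin)
        gpad <- scatter_add(geom$hp * geom$wp * d[3],
                            as.vector(geom$ifull), as.vector(gp))
        dim(gpad) <- c(geom$hp, geom$wp, d[3])
        gin[, , , i] <- crop_sample(gpad, geom)
      }
      gp_list <- list(W = array(gw, dim(pw$W)))
      if (!is.null(gb)) gp_list$b <- gb
      return(list(gin = list(gin), gp = gp_list))
    } else {
      wm <- matrix(pw$W, ncol = nd$cfg$c_in)
      gw <- matrix(0, k[1] * k[2], nd$cfg$c_in)
      for (i in seq_len(n)) {
        gmat <- matrix(go[, , , i], geom$npos, nd$cfg$c_in)
        gmat <- act_grad(cache$pre[[i]],
                         matrix(acts[[nd$name]][, , , i], geom$npos,
                                nd$cfg$c_in),
                         gmat, nd$cfg$activation)
        xp <- cache$xp[[i]]
        gpad <- array(0, c(geom$hp, geom$wp, d[3]))
        for (ch in seq_len(nd$cfg$c_in)) {
          pch <- matrix(xp[geom$iplane + (ch - 1L) * (geom$hp * geom$wp)],
                        geom$npos)
          gw[, ch] <- gw[, ch] + crossprod(pch, gmat[, ch])
          gpch <- tcrossprod(gmat[, ch], wm[, ch])  # npos x k1k2
          gplane <- scatter_add(geom$hp * geom$wp, as.vector(geom$iplane),
                                as.vector(gpch))
          gpad[, , ch] <- gplane
        }
        gin[, , , i] <- crop_sample(gpad, geom)
      }
      return(list(gin = list(gin), gp = list(W = array(gw, dim(pw$W)))))
    }
  }

  if (op == "maxpool") {
    a <- ins[[1]]; d <- dim(a); n <- d[4]
    geom <- g$cache[[paste0("geom_", nd$name)]]
    gin <- array(0, d)
    for (i in seq_len(n)) {
      gpad <- array(0, c(geom$hp, geom$wp, d[3]))
      for (ch in seq_len(d[3])) {
        j <- cache$arg[, ch, i]
        lin <- geom$iplane[cbind(seq_len(geom$npos), j)]
        gpad[, , ch] <- scatter_add(geom$hp * geom$wp, lin,
                                    as.vector(go[, , ch, i]))
      }
      gin[, , , i] <- crop_sample(gpad, geom)
    }
    return(list(gin = list(gin)))
  }

  if (op == "avgpool") {
    a <- ins[[1]]; d <- dim(a); n <- d[4]
    geom <- g$cache[[paste0("geom_", nd$name)]]
    kk <- ncol(geom$iplane)
    gin <- array(0, d)
    for (i in seq_len(n)) {
      gpad <- array(0, c(geom$hp, geom$wp, d[3]))
      for (ch in seq_len(d[3])) {
        gv <- rep(as.vector(go[, , ch, i]) / kk, times = kk)
        gpad[, , ch] <- scatter_add(geom$hp * geom$wp,
                                    as.vector(geom$iplane), gv)
      }
      gin[, , , i] <- crop_sample(gpad, geom)
    }
    return(list(gin = list(gin)))
  }

  if (op == "adaptive_avgpool") {
    a <- ins[[1]]; d <- dim(a); n <- d[4]
    geom <- g$cache[[paste0("geom_", nd$name)]]
    gin <- array(0, d)
    for (i in seq_len(n)) {
      gm <- matrix(go[, , , i], prod(nd$cfg$out), d[3])
      gin[, , , i] <- (gm / geom$counts)[geom$cellid, ]
    }
    return(list(gin = list(gin)))
  }

  if (op == "gap") {
    a <- ins[[1]]; d <- dim(a); n <- d[4]
    gin <- array(0, d)
    for (i in seq_len(n))
      gin[, , , i] <- rep(go[, i] / (d[1] * d[2]), each = d[1] * d[2])
    return(list(gin = list(gin)))
  }

  if (op == "gmp") {
    a <- ins[[1]]; d <- dim(a); n <- d[4]
    gin <- array(0, d)
    for (i in seq_len(n)) {
      m <- matrix(0, d[1] * d[2], d[3])
      m[cbind(cache$arg[, i], seq_len(d[3]))] <- go[, i]
      gin[, , , i] <- m
    }
    return(list(gin = list(gin)))
  }

  if (op == "channel_pool") {
    a <- ins[[1]]; d <- dim(a); n <- d[4]
    gin <- array(0, d)
    for (i in seq_len(n)) {
      gv <- as.vector(go[, , 1, i])
      if (nd$cfg$stat == "mean") {
        gin[, , , i] <- rep(gv / d[3], times = d[3])
      } else {
        m <- matrix(0, d[1] * d[2], d[3])
        m[cbind(seq_len(nrow(m)), cache$arg[, i])] <- gv
        gin[, , , i] <- m
      }
    }
    return(list(gin = list(gin)))
  }

  if (op == "dense") {
    a <- ins[[1]]
    gpre <- act_grad(cache$pre, acts[[nd$name]], go, nd$cfg$activation)
    gp <- list(W = a %*% t(gpre))
    if (!is.null(pw$b)) gp$b <- rowSums(gpre)
    return(list(gin = list(pw$W %*% gpre), gp = gp))
  }

  if (op == "activation") {
    f <- nd$cfg$fun
    out <- acts[[nd$name]]
    if (f == "softmax") {
      p <- out
      gin <- p * sweep(go, 2, colSums(go * p))
      return(list(gin = list(gin)))
    }
    gin <- if (f == "relu") go * (out > 0) else go * out * (1 - out)
    return(list(gin = list(gin)))
  }

  if (op == "softmax") {
    p <- acts[[nd$name]]
    gin <- p * sweep(go, 2, colSums(go * p))
    return(list(gin = list(gin)))
  }

  if (op == "combine") {
    mode <- nd$cfg$mode
    if (mode == "sum") return(list(gin = rep(list(go), length(ins))))
    if (mode == "mean")
      return(list(gin = rep(list(go / length(ins)), length(ins))))
    gin <- lapply(seq_along(ins), function(j) go * (cache$arg == j))
    return(list(gin = gin))
  }

  if (op == "concat") {
    if (length(nd$out_shape) == 3L) {
      off <- 0L
      gin <- lapply(ins, function(v) {
        cc <- dim(v)[3]
        gpart <- go[, , off + seq_len(cc), , drop = FALSE]
        off <<- off + cc
        gpart
      })
    } else {
      off <- 0L
      gin <- lapply(ins, function(v) {
        u <- nrow(v)
        gpart <- go[off + seq_len(u), , drop = FALSE]
        off <<- off + u
        gpart
      })
    }
    return(list(gin = gin))
  }

  if (op == "multiply") {
    m <- ins[[1]]; gate <- ins[[2]]
    d <- dim(m); n <- d[4]
    gm <- array(0, d)
    if (is.matrix(gate)) {
      gg <- matrix(0, nrow(gate), n)
      for (i in seq_len(n)) {
        gm[, , , i] <- go[, , , i] * rep(gate[, i], each = d[1] * d[2])
        gg[, i] <- colSums(matrix(go[, , , i] * m[, , , i], d[1] * d[2], d[3]))
      }
    } else {
      gg <- array(0, dim(gate))
      for (i in seq_len(n)) {
        sv <- as.vector(gate[, , 1, i])
        gm[, , , i] <- go[, , , i] * sv
        gg[, , 1, i] <- rowSums(matrix(go[, , , i] * m[, , , i],
                                       d[1] * d[2], d[3]))
      }
    }
    return(list(gin = list(gm, gg)))
  }

  if (op == "zero_pad") {
    r <- nd$cfg$rings
    d <- dim(ins[[1]])
    gin <- go[r + seq_len(d[1]), r + seq_len(d[2]), , , drop = FALSE]
    return(list(gin = list(gin)))
  }

  if (op == "input") return(list(gin = list()))
  stop("no backward rule for op: ", op)
}

# ---- optimizer --------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(g, pgrads, lr, state, include = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$t)) state$t <- 0L
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(pgrads)) {
    if (!is.null(include) && !nm %in% include) next
    for (pn in names(pgrads[[nm]])) {
      key <- paste0(nm, ".", pn)
      gr <- pgrads[[nm]][[pn]]
      if (is.null(state[[key]]))
        state[[key]] <- list(m = gr * 0, v = gr * 0)
      st <- state[[key]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr^2
      state[[key]] <- st
      g$params[[nm]][[pn]] <- g$params[[nm]][[pn]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
    }
  }
  invisible(state)
}
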