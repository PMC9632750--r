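# RGB <-> YCbCr (BT.601 full-range) transform used as the decorrelated
# luminance/chrominance space for statistical style transfer.
.rgb2ycc <- matrix(c( 0.299,     0.587,     0.114,
                     -0.168736, -0.331264,  0.5,
                      0.5,      -0.418688, -0.081312),
                   nrow = 3, byrow = TRUE)
.ycc2rgb <- solve(.rgb2ycc)

rgb_to_ycc <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3L) %*% t(.rgb2ycc)
  array(m, d)
}

ycc_to_rgb <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3L) %*% t(.ycc2rgb)
  array(m, d)
}

#' Statistical colour/texture style transfer
#'
#' A first-principles stylizer: the content image is mapped into a
#' decorrelated luminance/chrominance space (YCbCr), each channel is affinely
#' rescaled so its mean and standard deviation match the style image's, the
#' result is blended with the original channel by `strength`, mapped back to
#' RGB and clipped to [0,1]. With `strength = 0` the content is returned
#' unchanged; with `strength = 1` the transfer-space first and second moments
#' equal the style's (up to gamut clipping). A zero-variance style channel
#' keeps the content statistics for that channel.
#'
#' @param content,style H x W x 3 arrays in [0,1]; shapes may differ, the
#'   output always has the content's shape.
#' @param strength Blend fraction in [0,1]; default 1.
#' @return Stylized H x W x 3 array in [0,1].
#' @export
statistical_style_transfer <- function(content, style, strength = 1) {
  stopifnot(length(dim(content)) == 3L, dim(content)[3] == 3L,
            length(dim(style)) == 3L, dim(style)[3] == 3L,
            strength >= 0, strength <= 1)
  if (strength == 0) return(content)
  cc <- rgb_to_ycc(content)
  ss <- rgb_to_ycc(style)
  out <- cc
  for (ch in 1:3) {
    x <- cc[, , ch]
    mu_c <- mean(x); sd_c <- stats::sd(as.vector(x))
    mu_s <- mean(ss[, , ch]); sd_s <- stats::sd(as.vector(ss[, , ch]))
    if (!is.finite(sd_s) || sd_s == 0) { mu_s <- mu_c; sd_s <- sd_c }
    transferred <- if (sd_c == 0) x - mu_c + mu_s
                   else (x - mu_c) / sd_c * sd_s + mu_s
    out[, , ch] <- strength * transferred + (1 - strength) * x
  }
  clip01(ycc_to_rgb(out))
}

# ---- stylizer backend registry -------------------------------------------

.stylizers <- new.env(parent = emptyenv())

#' Stylizer backend registry
#'
#' Stylization is pluggable: a backend is a function
#' `function(content, style, strength, seed)` returning an array with the
#' content's shape and values in [0,1]. The `"statistical"` backend
#' ([statistical_style_transfer()]) is registered by default; an external
#' neural stylizer can be swapped in without touching the planner.
#'
#' @param name Backend name.
#' @param fn Stylization function.
#' @return `register_stylizer` returns `name` invisibly; `get_stylizer`
#'   returns the registered function.
#' @export
register_stylizer <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .stylizers)
  invisible(name)
}

#' @rdname register_stylizer
#' @export
get_stylizer <- function(name) {
  if (!exists(name, envir = .stylizers))
    stop("unknown stylizer backend: ", name,
         " (registered: ", paste(ls(.stylizers), collapse = ", "), ")")
  get(name, envir = .stylizers)
}

#' Execute a style-transfer augmentation plan
#'
#' Realizes an [compute_allocation()] plan on a training set. For classes
#' with `num_add >= 1`, every image acts as a content image and spawns
#' `num_add` styled images whose style sources are distinct images of the
#' same class (the content image itself is excluded); if fewer candidates
#' exist than needed, styles are drawn with replacement and a warning is
#' issued. For classes with `ratio < 1`, `num_sub` randomly chosen content
#' images each spawn one styled image. Realized per-class counts equal the
#' plan's `n_after` and the result is deterministic under a fixed seed.
#'
#' @param train A [labeled_dataset()] of preprocessed records (the training
#'   split only; validation/test data are never touched).
#' @param plan An `augmentation_plan` computed from this dataset's counts.
#' @param backend Stylizer backend name (default `"statistical"`).
#' @param strength Style strength passed to the backend; default 1.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with styled records appended.
#' @export
execute_plan <- function(train, plan, backend = "statistical",
                         strength = 1, seed = 1L) {
  stopifnot(inherits(plan, "augmentation_plan"))
  if (!setequal(plan$class, train$classes) ||
      !all(plan$n_before[match(train$classes, plan$class)] == train$counts))
    stop("plan does not match the dataset's per-class counts")
  stylize <- get_stylizer(backend)
  rng <- local_rng(seed)
  labels <- dataset_labels(train)
  extra <- vector("list", sum(plan$num_add * plan$n_before + plan$num_sub))
  k <- 0L
  for (i in seq_len(nrow(plan))) {
    cl <- plan$class[i]
    idx <- which(labels == cl)
    if (plan$num_add[i] >= 1) {
      for (ci in idx) {
        cand <- setdiff(idx, ci)
        replace <- length(cand) < plan$num_add[i]
        if (replace)
          warning("class ", cl, ": fewer style candidates than num_add; ",
                  "sampling styles with replacement")
        styles <- cand[rng$sample_int(length(cand), plan$num_add[i],
                                      replace = replace)]
        content <- train$records[[ci]]
        for (j in seq_along(styles)) {
          sr <- train$records[[styles[j]]]
          k <- k + 1L
          extra[[k]] <- image_record(
            id = paste0(content$id, "_st", j),
            pixels = stylize(content$pixels, sr$pixels, strength),
            label = cl, provenance = "styled",
            source_id = content$id, style_id = sr$id)
        }
      }
    } else if (plan$num_sub[i] > 0) {
      picks <- idx[rng$sample_int(length(idx), plan$num_sub[i])]
      for (ci in picks) {
        content <- train$records[[ci]]
        cand <- setdiff(idx, ci)
        sr <- train$records[[cand[rng$sample_int(length(cand), 1L)]]]
        k <- k + 1L
        extra[[k]] <- image_record(
          id = paste0(content$id, "_st1"),
          pixels = stylize(content$pixels, sr$pixels, strength),
          label = cl, provenance = "styled",
          source_id = content$id, style_id = sr$id)
      }
    }
  }
  labeled_dataset(c(train$records, extra[seq_len(k)]), train$classes)
}
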