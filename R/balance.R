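#' Mirror rotations
#'
#' The three basic upsampling transforms: `rotate_lr` mirrors an image about
#' its vertical centerline (left-right flip), `rotate_ud` mirrors about the
#' horizontal centerline (up-down flip) and `rotate_sym` applies both, which
#' equals a 180-degree rotation.
#'
#' @param img H x W x C numeric array.
#' @return Array of the same shape.
#' @export
rotate_lr <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

#' @rdname rotate_lr
#' @export
rotate_ud <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

#' @rdname rotate_lr
#' @export
rotate_sym <- function(img) rotate_ud(rotate_lr(img))

#' Rotation upsampling of a training set
#'
#' Every record of every non-majority class is retained and joined by its
#' three mirror rotations, quadrupling those classes. Majority-class records
#' are kept unchanged. Provenance and the source id are recorded on each
#' derived record.
#'
#' @param train A [labeled_dataset()] (training split only).
#' @param majority_class Name of the majority class, left un-augmented.
#' @return A [labeled_dataset()] with the rotated records appended.
#' @export
augment_rotations <- function(train, majority_class) {
  if (!majority_class %in% train$classes)
    stop("majority class '", majority_class, "' not among dataset classes")
  out <- vector("list", 4L * length(train$records))
  k <- 0L
  for (r in train$records) {
    k <- k + 1L; out[[k]] <- r
    if (r$label == majority_class) next
    for (rot in c("rotate_lr", "rotate_ud", "rotate_sym")) {
      k <- k + 1L
      out[[k]] <- image_record(
        id = paste0(r$id, "_", sub("rotate_", "", rot)),
        pixels = get(rot)(r$pixels),
        label = r$label, provenance = rot, source_id = r$id)
    }
  }
  labeled_dataset(out[seq_len(k)], train$classes)
}

#' Style-transfer allocation plan
#'
#' For each class `i` with post-rotation count `n_i` and majority count `N`,
#' the upsampling ratio is `(N - n_i) / n_i`. When the ratio is at least 1,
#' `num_add = floor(ratio)` styled images are generated per existing image,
#' giving `n_i * (1 + num_add)` images; flooring means such classes can end
#' slightly below the majority count, by design. When the ratio is below 1,
#' exactly the deficit `num_sub = N - n_i` of randomly chosen images each
#' spawn one styled image, topping the class up to `N`.
#'
#' @param counts Named per-class counts after rotation upsampling.
#' @param majority_class Name of the majority class; must hold the maximum.
#' @return A data frame of class `augmentation_plan` with columns `class`,
#'   `n_before`, `n_target`, `ratio`, `num_add`, `num_sub`, `n_after`.
#' @export
compute_allocation <- function(counts, majority_class) {
  if (is.null(names(counts))) stop("counts must be named by class")
  if (any(counts <= 0))
    stop("empty class: ", paste(names(counts)[counts <= 0], collapse = ", "))
  if (!majority_class %in% names(counts))
    stop("majority class '", majority_class, "' not in counts")
  n_target <- counts[[majority_class]]
  if (n_target < max(counts))
    stop("majority class does not hold the maximum count")
  ratio <- (n_target - counts) / counts
  num_add <- ifelse(ratio >= 1, floor(ratio), 0L)
  num_sub <- ifelse(ratio < 1, n_target - counts, 0L)
  n_after <- ifelse(ratio >= 1, counts * (1 + num_add), n_target)
  plan <- data.frame(class = names(counts),
                     n_before = as.integer(counts),
                     n_target = as.integer(n_target),
                     ratio = as.numeric(ratio),
                     num_add = as.integer(num_add),
                     num_sub = as.integer(num_sub),
                     n_after = as.integer(n_after),
                     row.names = NULL, stringsAsFactors = FALSE)
  class(plan) <- c("augmentation_plan", "data.frame")
  plan
}

#' Inverse-frequency class weights
#'
#' `weight_i = n_samples / (n_classes * count_i)`: balanced classes get unit
#' weights and smaller classes get strictly larger weights, so the weighted
#' loss penalizes errors on rare classes more. The weights satisfy
#' `sum(weight_i * count_i) == n_samples`.
#'
#' @param labels Character vector of training labels, or a named per-class
#'   count vector.
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  counts <- if (!is.null(names(labels)) && is.numeric(labels)) labels
            else table(labels)
  counts <- counts[order(names(counts))]
  if (any(counts <= 0))
    stop("empty class: ", paste(names(counts)[counts <= 0], collapse = ", "))
  n <- sum(counts)
  w <- as.numeric(n / (length(counts) * counts))
  names(w) <- names(counts)
  w
}

#' Pixel-perturbation specification for a minority class
#'
#' The perturbation magnitude pool for a class is the integer interval
#' `[1, floor(differences / (2 * n_classes))]` where `differences` is the gap
#' to the majority-class count. Magnitudes are drawn without replacement (the
#' pool resets with a warning once exhausted) and added or subtracted, with a
#' random sign, to all channels of an image.
#'
#' @param differences Count gap between this class and the majority class.
#' @param n_classes Number of classes.
#' @return A list of class `perturbation_spec` with `pixel_max` and a
#'   stateful `draw(rng)` function returning `list(value, sign)`.
#' @export
perturbation_spec <- function(differences, n_classes) {
  pixel_max <- floor(differences / (2 * n_classes))
  if (pixel_max < 1)
    stop("pixel perturbation needs pixel_max >= 1 (got ", pixel_max, ")")
  pool <- new.env(parent = emptyenv())
  pool$left <- seq_len(pixel_max)
  draw <- function(rng) {
    if (!length(pool$left)) {
      warning("perturbation interval exhausted; resetting pool")
      pool$left <- seq_len(pixel_max)
    }
    i <- rng$sample_int(length(pool$left), 1L)
    v <- pool$left[i]
    pool$left <- pool$left[-i]
    list(value = v, sign = if (rng$runif(1) < 0.5) -1 else 1)
  }
  structure(list(pixel_max = pixel_max, draw = draw),
            class = "perturbation_spec")
}

#' Apply one pixel perturbation to an image
#'
#' Adds `sign * value` (an 8-bit magnitude, scaled by 1/255 for images in
#' [0,1]) to every channel and clips to the valid range.
#'
#' @param img H x W x C array with intensities in [0,1].
#' @param value Integer magnitude from the spec's pool.
#' @param sign +1 or -1.
#' @return Perturbed image, clipped to [0,1].
#' @export
apply_pixel_perturbation <- function(img, value, sign) {
  clip01(img + sign * value / 255)
}

#' Pixel-perturbation upsampling (ablation arm)
#'
#' Balances every minority class exactly up to the majority count by cloning
#' randomly chosen images (with replacement across rounds, without
#' replacement within a round) and shifting all their intensities by a
#' magnitude drawn without replacement from the class's perturbation pool.
#' This arm is kept for comparison; style-transfer upsampling is the
#' recommended treatment.
#'
#' @param train A [labeled_dataset()] of preprocessed records.
#' @param majority_class Majority class name.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with perturbed records appended so that all
#'   classes match the majority count.
#' @export
pixel_perturbation_upsample <- function(train, majority_class, seed = 1L) {
  rng <- local_rng(seed)
  n_target <- train$counts[[majority_class]]
  n_classes <- length(train$classes)
  labels <- dataset_labels(train)
  extra <- list()
  for (cl in setdiff(train$classes, majority_class)) {
    deficit <- n_target - train$counts[[cl]]
    if (deficit <= 0) next
    spec <- perturbation_spec(deficit, n_classes)
    idx <- which(labels == cl)
    picks <- idx[rng$sample_int(length(idx), deficit, replace = deficit > length(idx))]
    for (k in seq_along(picks)) {
      r <- train$records[[picks[k]]]
      d <- spec$draw(rng)
      extra[[length(extra) + 1L]] <- image_record(
        id = paste0(r$id, "_px", k),
        pixels = apply_pixel_perturbation(r$pixels, d$value, d$sign),
        label = cl, provenance = "perturbed", source_id = r$id)
    }
  }
  labeled_dataset(c(train$records, extra), train$classes)
}
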