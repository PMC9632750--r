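#' Synthetic dermoscopy dataset specification
#'
#' Describes a synthetic labeled lesion-image collection emulating the class
#' imbalance of the HAM10000 archive: by default the per-class counts are the
#' archive's printed counts (6705/1113/1099/514/327/142/115) scaled by
#' `scale`, rounded, with a floor of 2 per class so a 3:1:1 stratified split
#' stays feasible. Each class is given a distinct lesion hue so that classes
#' are separable by colour — a property real dermoscopy data does not share,
#' which keeps desk-scale training tests meaningful but easy.
#'
#' @param scale Multiplier applied to the HAM10000 counts; default 1.
#' @param class_counts Optional named counts overriding the scaled defaults.
#' @param image_size `c(H, W)` of the generated images; default `c(64, 64)`.
#' @param min_count Per-class floor after scaling; default 2.
#' @param hues Optional named per-class lesion hues in [0,1); defaults to
#'   evenly spaced, hence disjoint, hue ranges.
#' @param border_amp Amplitude of the sinusoidal border irregularity
#'   (fraction of the radius); default 0.12.
#' @param noise_sd Pixel noise standard deviation (8-bit scale fraction);
#'   default 0.02.
#' @param seed Base seed for generation.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(scale = 1, class_counts = NULL,
                           image_size = c(64L, 64L), min_count = 2L,
                           hues = NULL, border_amp = 0.12, noise_sd = 0.02,
                           seed = 1L) {
  if (is.null(class_counts))
    class_counts <- scale_counts(ham10000_counts(), scale, min_count)
  if (is.null(names(class_counts))) stop("class_counts must be named")
  if (any(class_counts <= 0)) stop("class counts must be positive")
  classes <- names(class_counts)
  if (is.null(hues)) {
    hues <- (seq_along(classes) - 1) * 0.9 / length(classes)
    names(hues) <- classes
  }
  structure(list(class_counts = class_counts, classes = classes,
                 image_size = as.integer(image_size), hues = hues,
                 border_amp = border_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Scale the per-class counts of an imbalanced dataset
#'
#' @param counts Named per-class counts.
#' @param scale Multiplier.
#' @param min_count Floor applied after rounding; default 2.
#' @return Named integer counts `pmax(round(counts * scale), min_count)`.
#' @export
scale_counts <- function(counts, scale, min_count = 2L) {
  out <- pmax(as.integer(round(counts * scale)), as.integer(min_count))
  names(out) <- names(counts)
  out
}

#' Majority-class share of a dataset
#'
#' @param counts Named per-class counts.
#' @return Percentage (0-100) of the largest class.
#' @export
#' @examples
#' majority_share(ham10000_counts())  # 66.95
majority_share <- function(counts) 100 * max(counts) / sum(counts)

#' Generate one synthetic lesion image
#'
#' A skin-tone background with additive Gaussian noise and one roughly
#' elliptical lesion whose hue is class-dependent, whose radius is jittered
#' and whose border is perturbed sinusoidally (an irregular-border analogue).
#' Deterministic for a given rng stream position.
#'
#' @param class_name Class label (must be in the spec).
#' @param spec A [synthetic_spec()].
#' @param rng A stream from `local_rng()`; pass the same stream across calls
#'   for a reproducible sequence.
#' @param id Record identifier.
#' @return An [image_record()] with raw 8-bit pixels (0-255).
#' @export
generate_lesion_image <- function(class_name, spec, rng,
                                  id = paste0(class_name, "_1")) {
  stopifnot(class_name %in% spec$classes)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  # skin-tone background with noise
  base <- c(0.91, 0.76, 0.65)
  img <- array(rep(base, each = h * w), c(h, w, 3)) +
    array(rng$rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3))
  # lesion geometry: centre jitter, semi-axes jitter, sinusoidal border
  cy <- h / 2 + rng$runif(1, -0.08, 0.08) * h
  cx <- w / 2 + rng$runif(1, -0.08, 0.08) * w
  a <- h * 0.28 * (1 + rng$runif(1, -0.15, 0.15))
  b <- w * 0.28 * (1 + rng$runif(1, -0.15, 0.15))
  k <- sample_wave <- floor(rng$runif(1, 3, 7))
  phase <- rng$runif(1, 0, 2 * pi)
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  theta <- atan2(yy / a, xx / b)
  rad <- sqrt((yy / a)^2 + (xx / b)^2)
  mask <- rad <= 1 + spec$border_amp * sin(k * theta + phase)
  # lesion colour from the class hue (converted from HSV), with jitter
  hue <- (spec$hues[[class_name]] + rng$runif(1, -0.02, 0.02)) %% 1
  col <- grDevices::col2rgb(grDevices::hsv(hue, 0.65, 0.55)) / 255
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- col[ch] + rng$rnorm(sum(mask), 0, spec$noise_sd * 2)
    img[, , ch] <- plane
  }
  attr_area <- pi * a * b
  rec <- image_record(id, round(clip01(img) * 255), class_name)
  attr(rec, "lesion_area") <- attr_area
  attr(rec, "lesion_pixels") <- sum(mask)
  rec
}

#' Generate a synthetic labeled dataset
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory: images are written as PNG plus a
#'   `metadata.csv` with columns `image_id,label`, consumable by
#'   [load_dataset()].
#' @return A [labeled_dataset()] of raw records (and, invisibly via files,
#'   the on-disk copy when `dir` is given).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  records <- list()
  for (cl in spec$classes) {
    for (i in seq_len(spec$class_counts[[cl]])) {
      records[[length(records) + 1L]] <-
        generate_lesion_image(cl, spec, rng, id = sprintf("%s_%04d", cl, i))
    }
  }
  ds <- labeled_dataset(records, spec$classes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (r in ds$records)
      png::writePNG(r$pixels / 255, file.path(dir, paste0(r$id, ".png")))
    utils::write.csv(
      data.frame(image_id = dataset_ids(ds), label = dataset_labels(ds)),
      file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  ds
}
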