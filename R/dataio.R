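#' HAM10000 class labels and image counts
#'
#' The seven diagnostic categories of the HAM10000 dermoscopy archive and the
#' number of images per category, ordered as the archive reports them:
#' melanocytic nevi (nv), melanoma (mel), benign keratosis-like lesions (bkl),
#' basal cell carcinoma (bcc), actinic keratoses / Bowen's disease (akiec),
#' vascular lesions (vasc) and dermatofibroma (df).
#'
#' @return Named integer vector of per-class image counts (total 10,015).
#' @export
#' @examples
#' ham10000_counts()
ham10000_counts <- function() {
  c(nv = 6705L, mel = 1113L, bkl = 1099L, bcc = 514L,
    akiec = 327L, vasc = 142L, df = 115L)
}

valid_provenance <- c("original", "rotate_lr", "rotate_ud", "rotate_sym",
                      "styled", "perturbed")

#' Construct a single labeled image record
#'
#' @param id Unique record identifier.
#' @param pixels Numeric H x W x 3 array. Raw records hold 8-bit intensities
#'   (0-255); preprocessed and derived records hold intensities in [0,1].
#' @param label Class label.
#' @param provenance One of `"original"`, `"rotate_lr"`, `"rotate_ud"`,
#'   `"rotate_sym"`, `"styled"`, `"perturbed"`.
#' @param source_id Identifier of the originating image for derived records;
#'   must equal `id` when (and only when) provenance is `"original"`.
#' @param style_id Optional identifier of the style image for styled records.
#' @return A list of class `image_record`.
#' @export
image_record <- function(id, pixels, label, provenance = "original",
                         source_id = id, style_id = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!provenance %in% valid_provenance)
    stop("unknown provenance: ", provenance)
  if ((provenance == "original") != identical(source_id, id))
    stop("provenance 'original' requires source_id == id (record ", id, ")")
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array (record ", id, ")")
  structure(list(id = id, pixels = pixels, label = label,
                 provenance = provenance, source_id = source_id,
                 style_id = style_id),
            class = "image_record")
}

#' Construct a labeled image dataset
#'
#' @param records List of [image_record()] objects.
#' @param classes Ordered character vector of class names. Defaults to the
#'   sorted unique labels present.
#' @return A list of class `labeled_dataset` with elements `records`,
#'   `classes` and `counts` (named per-class record counts).
#' @export
labeled_dataset <- function(records, classes = NULL) {
  labels <- vapply(records, function(r) r$label, character(1))
  if (is.null(classes)) classes <- sort(unique(labels))
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stop("labels outside the declared class list: ", paste(bad, collapse = ", "))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  structure(list(records = records, classes = classes, counts = counts),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", length(x$records), " records, ",
      length(x$classes), " classes\n", sep = "")
  print(x$counts)
  invisible(x)
}

dataset_labels <- function(ds) vapply(ds$records, function(r) r$label, character(1))
dataset_ids <- function(ds) vapply(ds$records, function(r) r$id, character(1))

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", path))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  # readPNG/readJPEG return [0,1]; restore 8-bit integer intensities so the
  # fixed-range normalization of preprocess_image() applies to raw values
  round(img * 255)
}

#' Load an image dataset from a directory plus a metadata table
#'
#' Reads a CSV with required columns `image_id,label` and one PNG/JPEG file
#' per row under `image_dir` (the file name is `<image_id>.<ext>` with `ext`
#' one of png/jpg/jpeg). Pixels are kept raw (8-bit 0-255); apply
#' [preprocess_dataset()] afterwards.
#'
#' @param image_dir Directory containing the image files.
#' @param metadata Path to the metadata CSV, or a data frame with columns
#'   `image_id` and `label`.
#' @param classes Optional declared class list; labels outside it error.
#' @return A [labeled_dataset()] with one `original` record per metadata row.
#' @export
load_dataset <- function(image_dir, metadata, classes = NULL) {
  meta <- if (is.character(metadata))
    utils::read.csv(metadata, stringsAsFactors = FALSE) else as.data.frame(metadata)
  if (!all(c("image_id", "label") %in% names(meta)))
    stop("metadata must have columns image_id and label")
  if (nrow(meta) == 0L) stop("empty dataset: metadata has no rows")
  if (!is.null(classes)) {
    bad <- setdiff(unique(meta$label), classes)
    if (length(bad))
      stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  records <- lapply(seq_len(nrow(meta)), function(i) {
    id <- as.character(meta$image_id[i])
    cand <- file.path(image_dir, paste0(id, c(".png", ".jpg", ".jpeg")))
    path <- cand[file.exists(cand)][1]
    if (is.na(path))
      stop("image file not found for id '", id, "' under ", image_dir)
    image_record(id, read_image_file(path), as.character(meta$label[i]))
  })
  labeled_dataset(records, classes)
}

#' Nearest-neighbour image resize
#'
#' Maps output pixel `i` (1-based) to source pixel `floor((i-1) * n_in /
#' n_out) + 1`, row-major with the origin at the top-left, independently per
#' channel.
#'
#' @param img H x W x C numeric array.
#' @param target_h,target_w Positive output dimensions.
#' @return target_h x target_w x C array.
#' @export
resize_nearest <- function(img, target_h, target_w) {
  d <- dim(img)
  if (d[1] == target_h && d[2] == target_w) return(img)
  ri <- floor((seq_len(target_h) - 1) * d[1] / target_h) + 1
  ci <- floor((seq_len(target_w) - 1) * d[2] / target_w) + 1
  img[ri, ci, , drop = FALSE]
}

#' Preprocess one raw image: resize then min-max normalize
#'
#' Resizes to the target size by nearest-neighbour interpolation, then
#' rescales intensities as `(X - X_min) / (X_max - X_min)`. In the default
#' `"fixed"` mode the 8-bit range is used (`X_min = 0`, `X_max = 255`), so
#' relative contrast between images is preserved. In `"per_image"` mode the
#' image's own min/max are used; a constant image (max == min) maps to all
#' zeros by convention rather than erroring.
#'
#' @param raw H x W x 3 numeric array of 8-bit intensities (0-255).
#' @param target_h,target_w Target size; defaults 450 x 600.
#' @param mode `"fixed"` (default) or `"per_image"`.
#' @return target_h x target_w x 3 array with values in [0,1].
#' @export
preprocess_image <- function(raw, target_h = 450L, target_w = 600L,
                             mode = c("fixed", "per_image")) {
  mode <- match.arg(mode)
  if (length(dim(raw)) != 3L || dim(raw)[3] != 3L)
    stop("raw image must be H x W x 3")
  if (target_h < 1L || target_w < 1L) stop("target dimensions must be positive")
  img <- resize_nearest(raw, target_h, target_w)
  if (mode == "fixed") {
    img / 255
  } else {
    lo <- min(img); hi <- max(img)
    if (hi == lo) array(0, dim(img)) else (img - lo) / (hi - lo)
  }
}

#' Preprocess every record of a dataset
#'
#' @param ds A [labeled_dataset()] of raw records.
#' @inheritParams preprocess_image
#' @return A [labeled_dataset()] whose records hold preprocessed pixels.
#' @export
preprocess_dataset <- function(ds, target_h = 450L, target_w = 600L,
                               mode = "fixed") {
  ds$records <- lapply(ds$records, function(r) {
    r$pixels <- preprocess_image(r$pixels, target_h, target_w, mode)
    r
  })
  ds
}

# floor-and-distribute allocation of n items to parts proportional to ratio
split_counts <- function(n, ratio) {
  exact <- n * ratio / sum(ratio)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    # distribute leftovers by largest fractional part; ties favour earlier parts
    ord <- order(exact - base, -seq_along(ratio), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits a dataset class-by-class into three disjoint parts in the given
#' ratio (default 3:1:1) using floor-and-distribute rounding, so every part's
#' per-class size is within one record of the exact proportion. Deterministic
#' under a fixed seed.
#'
#' @param ds A [labeled_dataset()].
#' @param ratio Positive integer triple; default `c(3, 1, 1)`.
#' @param seed Integer seed controlling the per-class shuffle.
#' @return A list of class `dataset_splits` with elements `train`, `valid`,
#'   `test` (each a `labeled_dataset`) and `ratio`.
#' @export
stratified_split <- function(ds, ratio = c(3L, 1L, 1L), seed = 1L) {
  stopifnot(length(ratio) == 3L, all(ratio > 0))
  if (any(ds$counts == 0L))
    stop("class with zero members: ",
         paste(names(ds$counts)[ds$counts == 0L], collapse = ", "))
  labels <- dataset_labels(ds)
  rng <- local_rng(seed)
  part <- integer(length(ds$records))
  for (cl in ds$classes) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_int(length(idx), length(idx))]
    sizes <- split_counts(length(idx), ratio)
    part[idx] <- rep(1:3, times = sizes)
  }
  mk <- function(k) labeled_dataset(ds$records[part == k], ds$classes)
  structure(list(train = mk(1L), valid = mk(2L), test = mk(3L), ratio = ratio),
            class = "dataset_splits")
}

#' @export
print.dataset_splits <- function(x, ...) {
  cat("<dataset_splits> ratio ", paste(x$ratio, collapse = ":"), "\n", sep = "")
  for (p in c("train", "valid", "test"))
    cat(sprintf("  %-5s %d\n", p, length(x[[p]]$records)))
  invisible(x)
}

#' Write a split manifest CSV
#'
#' One row per record with columns
#' `image_id,label,split,provenance,source_id`.
#'
#' @param splits A `dataset_splits` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(splits, path) {
  rows <- do.call(rbind, lapply(c("train", "valid", "test"), function(p) {
    ds <- splits[[p]]
    if (!length(ds$records)) return(NULL)
    data.frame(
      image_id = dataset_ids(ds),
      label = dataset_labels(ds),
      split = p,
      provenance = vapply(ds$records, function(r) r$provenance, character(1)),
      source_id = vapply(ds$records, function(r) r$source_id, character(1)),
      stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
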