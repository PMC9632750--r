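test_that("fixed-range normalization maps 8-bit endpoints to [0,1]", {
  const255 <- array(255, c(4, 5, 3))
  expect_equal(preprocess_image(const255, 4, 5), array(1, c(4, 5, 3)))
  const0 <- array(0, c(4, 5, 3))
  expect_equal(preprocess_image(const0, 4, 5), array(0, c(4, 5, 3)))
  # per-image mode on a constant image: max == min convention -> all zeros
  const128 <- array(128, c(4, 5, 3))
  expect_equal(preprocess_image(const128, 4, 5, mode = "per_image"),
               array(0, c(4, 5, 3)))
})

test_that("nearest-neighbour upscale of a checkerboard gives exact blocks", {
  cb <- array(0, c(2, 2, 3))
  cb[1, 2, ] <- 255; cb[2, 1, ] <- 255
  out <- preprocess_image(cb, 4, 4)
  # each source pixel becomes a 2x2 block
  expected <- matrix(c(0, 0, 1, 1,
                       0, 0, 1, 1,
                       1, 1, 0, 0,
                       1, 1, 0, 0), 4, 4, byrow = TRUE)
  for (ch in 1:3) expect_equal(out[, , ch], expected)
})

test_that("preprocessing is idempotent on already-sized fixed-range input", {
  set.seed(3)
  raw <- array(sample(0:255, 6 * 7 * 3, TRUE), c(6, 7, 3))
  once <- preprocess_image(raw, 6, 7)
  # re-quantize to 8-bit and preprocess again: round trip is exact
  twice <- preprocess_image(round(once * 255), 6, 7)
  expect_equal(twice, once)
})

test_that("load_dataset ingests images and validates labels and files", {
  dir <- withr::local_tempdir()
  classes <- c("a", "b")
  set.seed(1)
  for (id in c("a_1", "b_1")) {
    img <- array(runif(4 * 4 * 3), c(4, 4, 3))
    png::writePNG(img, file.path(dir, paste0(id, ".png")))
  }
  meta <- data.frame(image_id = c("a_1", "b_1"), label = c("a", "b"))
  ds <- load_dataset(dir, meta, classes)
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(unname(ds$counts), c(1L, 1L))
  expect_true(all(vapply(ds$records, function(r) r$provenance, "") == "original"))
  # raw 8-bit intensities, untouched by preprocessing
  expect_true(all(ds$records[[1]]$pixels == round(ds$records[[1]]$pixels)))
  expect_true(max(ds$records[[1]]$pixels) > 1)

  expect_error(load_dataset(dir, data.frame(image_id = "missing", label = "a"),
                            classes), "missing")
  expect_error(load_dataset(dir, data.frame(image_id = "a_1", label = "zz"),
                            classes), "unknown label")
  expect_error(load_dataset(dir, meta[0, ], classes), "empty")
})

test_that("synthetic manifest at full archive scale reproduces printed counts", {
  counts <- ham10000_counts()
  meta <- data.frame(
    image_id = unlist(lapply(names(counts), function(cl)
      sprintf("%s_%05d", cl, seq_len(counts[[cl]])))),
    label = rep(names(counts), counts))
  labels <- meta$label
  tab <- vapply(names(counts), function(cl) sum(labels == cl), integer(1))
  expect_identical(tab, counts)
  expect_identical(sum(tab), 10015L)
})

test_that("stratified split is an exact partition, deterministic under seed", {
  ds <- make_dataset(c(a = 5L, b = 10L, c = 7L), h = 2L, w = 2L)
  sp1 <- stratified_split(ds, c(3L, 1L, 1L), seed = 42)
  sp2 <- stratified_split(ds, c(3L, 1L, 1L), seed = 42)
  ids <- function(d) sort(vapply(d$records, function(r) r$id, ""))
  # determinism
  for (p in c("train", "valid", "test"))
    expect_identical(ids(sp1[[p]]), ids(sp2[[p]]))
  # partition: disjoint union recovers all ids
  all_ids <- c(ids(sp1$train), ids(sp1$valid), ids(sp1$test))
  expect_identical(sort(all_ids), ids(ds))
  expect_identical(anyDuplicated(all_ids), 0L)
  # exact divisibility: 5 of one class at 3:1:1 -> 3/1/1
  expect_identical(unname(sp1$train$counts["a"]), 3L)
  expect_identical(unname(sp1$valid$counts["a"]), 1L)
  expect_identical(unname(sp1$test$counts["a"]), 1L)
})

test_that("split rounding keeps every class within one record of 60% train", {
  counts <- ham10000_counts()
  # multinomial rounding oracle on a manifest the size of the full archive
  ds_counts <- counts
  sizes <- vapply(ds_counts, function(n) {
    exact <- n * 3 / 5
    c(floor(exact), ceiling(exact))
  }, numeric(2))
  ds <- make_dataset(c(a = 327L, b = 115L, c = 142L), h = 2L, w = 2L)
  sp <- stratified_split(ds, c(3L, 1L, 1L), seed = 1)
  for (cl in ds$classes) {
    exact <- ds$counts[[cl]] * 0.6
    expect_lte(abs(sp$train$counts[[cl]] - exact), 1)
  }
  expect_error(stratified_split(make_dataset(c(a = 3L), h = 2, w = 2)),
               NA)
  empty <- labeled_dataset(make_dataset(c(a = 2L), h = 2, w = 2)$records,
                           classes = c("a", "ghost"))
  expect_error(stratified_split(empty), "zero members")
})

test_that("split manifest round-trips through CSV", {
  ds <- make_dataset(c(a = 5L, b = 5L), h = 2L, w = 2L)
  sp <- stratified_split(ds, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  man <- read.csv(path)
  expect_setequal(names(man),
                  c("image_id", "label", "split", "provenance", "source_id"))
  expect_equal(nrow(man), 10L)
  expect_setequal(unique(man$split), c("train", "valid", "test"))
})
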