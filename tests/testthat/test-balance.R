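test_that("mirror rotations are involutions and compose into the 180-degree flip", {
  set.seed(2)
  img <- array(runif(5 * 7 * 3), c(5, 7, 3))
  expect_equal(rotate_lr(rotate_lr(img)), img)
  expect_equal(rotate_ud(rotate_ud(img)), img)
  expect_equal(rotate_sym(img), rotate_ud(rotate_lr(img)))
  expect_equal(rotate_sym(rotate_sym(img)), img)
})

test_that("a 2x3 image mirrors to the hand-enumerated arrays", {
  img <- array(0, c(2, 3, 3))
  img[, , 1] <- matrix(1:6, 2, 3, byrow = TRUE)  # rows (1,2,3) and (4,5,6)
  img[, , 2] <- img[, , 1] + 10
  img[, , 3] <- img[, , 1] + 20
  lr <- rotate_lr(img)
  expect_equal(lr[1, , 1], c(3, 2, 1))
  expect_equal(lr[2, , 1], c(6, 5, 4))
  ud <- rotate_ud(img)
  expect_equal(ud[1, , 1], c(4, 5, 6))
  expect_equal(ud[2, , 1], c(1, 2, 3))
  sym <- rotate_sym(img)
  expect_equal(sym[1, , 1], c(6, 5, 4))
  expect_equal(sym[2, , 1], c(3, 2, 1))
  expect_equal(sym[, , 2], rotate_sym(img[, , 2, drop = FALSE])[, , 1])
})

test_that("the four rotation variants of an asymmetric image are distinct", {
  set.seed(9)
  img <- array(runif(4 * 5 * 3), c(4, 5, 3))
  variants <- list(img, rotate_lr(img), rotate_ud(img), rotate_sym(img))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(variants[[i]], variants[[j]]))
})

test_that("rotation upsampling quadruples minorities and keeps the majority", {
  ds <- make_preprocessed(c(nv = 12L, akiec = 3L, df = 2L), h = 4L, w = 4L)
  out <- augment_rotations(ds, "nv")
  expect_equal(unname(out$counts["nv"]), 12L)
  expect_equal(unname(out$counts["akiec"]), 12L)
  expect_equal(unname(out$counts["df"]), 8L)
  prov <- vapply(out$records, function(r) r$provenance, "")
  expect_equal(sum(prov == "original"), 17L)
  expect_setequal(unique(prov[prov != "original"]),
                  c("rotate_lr", "rotate_ud", "rotate_sym"))
  # derived records point back at their source
  derived <- Filter(function(r) r$provenance != "original", out$records)
  expect_true(all(vapply(derived, function(r) r$source_id != r$id, TRUE)))
})

test_that("allocation reproduces the archive's training-set arithmetic", {
  # post-rotation counts for per-class training sets of
  # 209/329/703/74/4291/712/91 images
  counts <- c(akiec = 836, bcc = 1316, bkl = 2812, df = 296,
              nv = 4291, mel = 2848, vasc = 364)
  plan <- compute_allocation(counts, "nv")
  get <- function(cl, col) plan[plan$class == cl, col]
  expect_equal(get("akiec", "num_add"), 4L)   # floor(4.13)
  expect_equal(get("akiec", "n_after"), 4180L)
  expect_equal(get("bcc", "num_add"), 2L)     # floor(2.26)
  expect_equal(get("bcc", "n_after"), 3948L)
  expect_equal(get("df", "num_add"), 13L)     # floor(13.49)
  expect_equal(get("df", "n_after"), 4144L)
  expect_equal(get("vasc", "num_add"), 10L)   # floor(10.79)
  expect_equal(get("vasc", "n_after"), 4004L)
  # ratio-below-1 classes are topped up exactly to the majority count
  expect_equal(get("bkl", "num_sub"), 4291L - 2812L)
  expect_equal(get("bkl", "n_after"), 4291L)
  expect_equal(get("mel", "n_after"), 4291L)
  # majority class: ratio 0, untouched
  expect_equal(get("nv", "ratio"), 0)
  expect_equal(get("nv", "n_after"), 4291L)
})

test_that("allocation invariants hold and degenerate inputs error", {
  plan <- compute_allocation(c(a = 10, b = 10), "a")
  expect_equal(plan$num_add, c(0L, 0L))
  expect_equal(plan$n_after, c(10L, 10L))
  ok <- plan$ratio >= 1
  expect_error(compute_allocation(c(a = 5, b = 9), "a"), "maximum")
  expect_error(compute_allocation(c(a = 0, b = 2), "b"), "empty class")
})

test_that("class weights follow inverse frequency and its algebraic identity", {
  expect_equal(unname(class_weights(c(a = 2, b = 2))), c(1, 1))
  # archive training counts: weight of the rarest class df
  counts <- c(akiec = 209, bcc = 329, bkl = 703, df = 74,
              nv = 4291, mel = 712, vasc = 91)
  w <- class_weights(counts)
  expect_equal(unname(w["df"]), 6409 / (7 * 74), tolerance = 1e-12)
  # sum_i weight_i * count_i == n_samples
  expect_equal(sum(w * counts[names(w)]), sum(counts))
  # scale invariance
  expect_equal(class_weights(counts * 2), w)
  # strictly larger weight for strictly smaller class
  ord <- order(counts[names(w)])
  expect_true(all(diff(w[names(counts)[order(counts, decreasing = TRUE)]]) >= 0))
  expect_error(class_weights(c(a = 0, b = 3)), "empty class")
})

test_that("pixel perturbation draws without replacement and clips", {
  spec <- perturbation_spec(differences = 28, n_classes = 7)  # pixel_max = 2
  expect_equal(spec$pixel_max, 2)
  rng <- lesionfuse:::local_rng(1)
  d1 <- spec$draw(rng); d2 <- spec$draw(rng)
  expect_setequal(c(d1$value, d2$value), c(1, 2))  # exhaustive, no repeat
  expect_warning(spec$draw(rng), "exhausted")
  # singleton interval: only magnitude 1 possible
  s1 <- perturbation_spec(14, 7)
  expect_equal(s1$pixel_max, 1)
  expect_equal(s1$draw(rng)$value, 1)
  # zeros stay zeros under subtraction (clip boundary)
  z <- array(0, c(2, 2, 3))
  expect_equal(apply_pixel_perturbation(z, 5, -1), z)
  expect_error(perturbation_spec(5, 7), "pixel_max")
})

test_that("pixel-perturbation upsampling balances classes deterministically", {
  ds <- make_preprocessed(c(a = 20L, b = 4L, c = 3L), h = 4L, w = 4L, seed = 2)
  out1 <- pixel_perturbation_upsample(ds, "a", seed = 7)
  out2 <- pixel_perturbation_upsample(ds, "a", seed = 7)
  expect_equal(unname(out1$counts), c(20L, 20L, 20L))
  expect_identical(
    lapply(out1$records, function(r) r$pixels),
    lapply(out2$records, function(r) r$pixels))
  prov <- vapply(out1$records, function(r) r$provenance, "")
  expect_equal(sum(prov == "perturbed"), 33L)
})
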