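# minimal two-class model whose merged score for class 1 is w * mean(channel 1)
# of the target feature map; analytic Grad-CAM: heatmap proportional to that
# channel's activations
analytic_model <- function(h = 4L, w = 4L) {
  g <- nn_graph(c(h, w, 2L))
  nn_conv2d(g, "feat", "input", 2L, c(1L, 1L), 1L, "valid", "linear",
            use_bias = FALSE)
  nn_gap(g, "gapn", "feat")
  nn_dense(g, "logits", "gapn", 2L, use_bias = FALSE)
  nn_softmax(g, "probs", "logits")
  nn_init(g, 1L)
  W <- array(0, c(1, 1, 2, 2)); W[1, 1, 1, 1] <- 1; W[1, 1, 2, 2] <- 1
  g$params[["feat"]]$W <- W                      # feat == input
  g$params[["logits"]]$W <- matrix(c(2, 0, 0, 1), 2, 2)  # class1 <- channel1
  structure(list(graph = g, outputs = "probs", logits = "logits",
                 branch_layers = c(feat = "feat"),
                 config = list(n_classes = 2L)),
            class = "fusion_model")
}

test_that("a mean-of-one-channel score yields a heatmap proportional to it", {
  set.seed(30)
  m <- analytic_model()
  x <- array(runif(4 * 4 * 2, 0.1, 1), c(4, 4, 2))
  sal <- grad_cam(m, x, class_index = 1L, layer = "feat")
  expect_equal(sal$heatmap,
               (x[, , 1] - min(x[, , 1])) / (max(x[, , 1]) - min(x[, , 1])),
               tolerance = 1e-9)
  # channel weights: spatial mean of the gradient (2/16 for ch1, 0 for ch2)
  expect_equal(unname(sal$weights), c(2 / 16, 0), tolerance = 1e-12)
  expect_false(sal$all_zero)
  expect_equal(max(sal$heatmap), 1)
})

test_that("in the uniform-gradient limit Grad-CAM++ matches Grad-CAM", {
  set.seed(31)
  m <- analytic_model()
  x <- array(runif(4 * 4 * 2, 0.1, 1), c(4, 4, 2))
  s1 <- grad_cam(m, x, 1L, layer = "feat")
  s2 <- grad_cam_pp(m, x, 1L, layer = "feat")
  expect_equal(s2$heatmap, s1$heatmap, tolerance = 1e-9)
})

test_that("negative evidence everywhere is flagged as an all-zero map", {
  m <- analytic_model()
  m$graph$params[["logits"]]$W <- matrix(c(-1, 0, -1, 0), 2, 2)
  x <- array(runif(4 * 4 * 2, 0.1, 1), c(4, 4, 2))
  sal <- grad_cam(m, x, 1L, layer = "feat")
  expect_true(sal$all_zero)
  expect_true(all(sal$heatmap == 0))
})

test_that("Grad-CAM channel weights match finite-difference gradients", {
  # three-layer toy model with smooth activations so FD is well posed
  set.seed(32)
  g <- nn_graph(c(5L, 6L, 3L))
  nn_conv2d(g, "c1", "input", 4L, c(3L, 3L), 1L, "same", "sigmoid")
  nn_conv2d(g, "feat", "c1", 3L, c(1L, 1L), 1L, "valid", "linear")
  nn_gap(g, "gapn", "feat")
  nn_dense(g, "logits", "gapn", 3L)
  nn_softmax(g, "probs", "logits")
  nn_init(g, 33L)
  m <- structure(list(graph = g, outputs = "probs", logits = "logits",
                      branch_layers = c(feat = "feat"),
                      config = list(n_classes = 3L)),
                 class = "fusion_model")
  x <- array(runif(5 * 6 * 3), c(5, 6, 3))
  target <- 2L
  sal <- grad_cam(m, x, target, layer = "feat")
  # FD oracle: perturb each activation of the target layer, re-run the head
  fw <- nn_forward(g, x)
  A <- fw$acts[["feat"]]
  eps <- 1e-5
  score_at <- function(Aov) {
    f2 <- nn_forward(g, x, override = list(feat = Aov))
    f2$acts[["logits"]][target, 1]
  }
  fd_grad <- array(0, dim(A))
  for (i in seq_along(A)) {
    Ap <- A; Ap[i] <- A[i] + eps
    Am <- A; Am[i] <- A[i] - eps
    fd_grad[i] <- (score_at(Ap) - score_at(Am)) / (2 * eps)
  }
  d <- dim(A)
  fd_weights <- colMeans(matrix(fd_grad, d[1] * d[2], d[3]))
  rel <- abs(fd_weights - sal$weights) /
    pmax(1e-8, abs(fd_weights), abs(sal$weights))
  expect_true(all(rel < 1e-3))
  expect_true(all(sal$heatmap >= 0 & sal$heatmap <= 1))
})

test_that("branch saliency maps of a fused classifier keep their layer dims", {
  cfg <- tiny_fusion_config("dense_concat", n_classes = 3L,
                            maps = list(c(2L, 2L, 4L), c(3L, 3L, 4L),
                                        c(2L, 2L, 4L)))
  m <- build_fusion_model(cfg, seed = 34)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  sal <- saliency_all_branches(m, x, method = "grad_cam_pp")
  expect_named(sal, c("tb1", "tb2", "tb3"))
  expect_equal(dim(sal$tb1$heatmap), c(2L, 2L))
  expect_equal(dim(sal$tb2$heatmap), c(3L, 3L))
  for (s in sal) {
    expect_s3_class(s, "saliency_map")
    expect_true(all(s$heatmap >= 0 & s$heatmap <= 1))
    expect_true(s$all_zero || max(s$heatmap) == 1)
  }
})

test_that("bilinear upsampling and overlay rendering are well behaved", {
  map <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  up <- bilinear_upsample(map, 8, 8)
  expect_equal(dim(up), c(8L, 8L))
  expect_true(all(up >= min(map) - 1e-12 & up <= max(map) + 1e-12))
  expect_equal(bilinear_upsample(map, 2, 2), map)
  # constant maps stay constant
  expect_true(all(abs(bilinear_upsample(matrix(0.3, 3, 3), 7, 9) - 0.3) < 1e-12))
  sal <- structure(list(heatmap = map, branch = "b", class_index = 1L,
                        method = "grad_cam", all_zero = FALSE),
                   class = "saliency_map")
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  png_path <- withr::local_tempfile(fileext = ".png")
  txt_path <- withr::local_tempfile(fileext = ".txt")
  ov <- render_overlay(sal, img, path = png_path, matrix_path = txt_path)
  expect_equal(dim(ov), dim(img))
  expect_true(all(ov >= 0 & ov <= 1))
  expect_true(file.exists(png_path))
  hm <- as.matrix(read.table(txt_path))
  expect_equal(dim(hm), c(8L, 8L))
})
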