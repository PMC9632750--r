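test_that("parallel fusion combines elementwise and enforces shape identity", {
  m1 <- array(c(1, 3, 2, 8, 0, 5, 4, 7), c(2, 2, 2))
  m2 <- array(c(2, 1, 6, 4, 9, 3, 0, 2), c(2, 2, 2))
  expect_equal(fuse_parallel(list(m1, m2), "sum"), m1 + m2)
  expect_equal(fuse_parallel(list(m1, m2), "mean"), (m1 + m2) / 2)
  expect_equal(fuse_parallel(list(m1, m2), "max"), pmax(m1, m2))
  # hand-computed 2x2 single-channel enumeration
  a <- array(c(1, 2, 3, 4), c(2, 2, 1))
  b <- array(c(4, 1, 5, 2), c(2, 2, 1))
  expect_equal(as.vector(fuse_parallel(list(a, b), "sum")), c(5, 3, 8, 6))
  expect_equal(as.vector(fuse_parallel(list(a, b), "mean")), c(2.5, 1.5, 4, 3))
  expect_equal(as.vector(fuse_parallel(list(a, b), "max")), c(4, 2, 5, 4))
  # idempotence and order property
  expect_equal(fuse_parallel(list(m1, m1, m1), "mean"), m1)
  expect_true(all(fuse_parallel(list(m1, m2), "max") >=
                  fuse_parallel(list(m1, m2), "mean")))
  expect_error(fuse_parallel(list(m1, array(0, c(2, 3, 2))), "sum"),
               "identical")
})

test_that("ring zero-padding centers values and preserves their sum", {
  set.seed(1)
  map <- array(runif(12 * 17 * 3), c(12, 17, 3))
  out <- zero_pad_map(map, 1L)
  expect_equal(dim(out), c(14L, 19L, 3L))
  expect_equal(out[2:13, 2:18, ], map)
  border <- out; border[2:13, 2:18, ] <- NA
  expect_true(all(border[!is.na(border)] == 0))
  expect_equal(sum(out), sum(map))
  expect_identical(zero_pad_map(map, 0L), map)
})

test_that("CBAM preserves shape and collapses to 0.25x with zero logits", {
  g <- nn_graph(c(5L, 6L, 4L))
  out <- cbam_block(g, "input", reduction_ratio = 2L, prefix = "cb")
  expect_equal(nn_shape(g, out), c(5L, 6L, 4L))
  nn_init(g, 3L)
  # force all attention logits to zero: both sigmoid gates become 0.5
  for (nm in names(g$params)) g$params[[nm]] <- lapply(g$params[[nm]],
                                                       function(p) p * 0)
  x <- array(runif(5 * 6 * 4), c(5, 6, 4, 1))
  res <- nn_forward(g, x)$acts[[out]]
  expect_equal(res, x * 0.25, tolerance = 1e-12)
  expect_error(cbam_block(g, "input", reduction_ratio = 3L), "divisible")
})

test_that("CBAM channel gate matches a hand-computed bottleneck forward pass", {
  # 2x2 map with 2 channels and hand-set shared MLP weights
  g <- nn_graph(c(2L, 2L, 2L))
  out <- cbam_block(g, "input", reduction_ratio = 2L, prefix = "cb")
  nn_init(g, 1L)
  W1 <- matrix(c(1, -1), 2, 1)          # 2 -> 1 bottleneck
  W2 <- matrix(c(0.5, -0.25), 1, 2)     # 1 -> 2
  g$params[["cb_fc1_avg"]] <- list(W = W1, b = 0)
  g$params[["cb_fc2_avg"]] <- list(W = W2, b = c(0, 0))
  # neutralize the spatial gate so only the channel gate acts
  g$params[["cb_sp_gate"]]$W[] <- 0
  g$params[["cb_sp_gate"]]$b[] <- 100   # sigmoid(100) ~ 1
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2, 1))
  res <- nn_forward(g, x)$acts[[out]]
  # hand computation with plain arithmetic
  relu <- function(v) pmax(v, 0); sig <- function(v) 1 / (1 + exp(-v))
  avg <- c(mean(x[, , 1, 1]), mean(x[, , 2, 1]))   # (2.5, 6.5)
  mx <- c(max(x[, , 1, 1]), max(x[, , 2, 1]))      # (4, 8)
  mlp <- function(v) as.vector(t(W2) %*% relu(t(W1) %*% v))
  gate <- sig(mlp(avg) + mlp(mx))
  expected <- x
  expected[, , 1, 1] <- x[, , 1, 1] * gate[1]
  expected[, , 2, 1] <- x[, , 2, 1] * gate[2]
  expect_equal(res, expected, tolerance = 1e-9)
})

test_that("conv_reduce aligns a 14x19 branch onto 12x17 and forwards", {
  cfg <- tiny_fusion_config("conv_reduce", n_classes = 3L,
                            input_shape = c(48L, 64L, 3L),
                            maps = list(c(12L, 17L, 8L), c(12L, 17L, 6L),
                                        c(14L, 19L, 8L)),
                            use_cbam = TRUE)
  cfg$cbam_reduction <- 2L
  m <- build_fusion_model(cfg, seed = 2)
  # the mismatched branch passes through a valid 3x3 stride-1 convolution
  expect_true("tb3_reduce" %in% m$graph$order)
  expect_equal(nn_shape(m$graph, "tb3_reduce"), c(12L, 17L, 8L))
  expect_equal(nn_shape(m$graph, "fused"), c(12L, 17L, 22L))
  x <- array(runif(48 * 64 * 3 * 2), c(48, 64, 3, 2))
  p <- model_probs(m, x)
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(colSums(p), c(1, 1), tolerance = 1e-9)
})

test_that("irreconcilable spatial mismatch suggests zero padding", {
  cfg <- tiny_fusion_config("conv_reduce", n_classes = 3L,
                            input_shape = c(48L, 64L, 3L),
                            maps = list(c(6L, 6L, 4L), c(12L, 17L, 4L)))
  cfg$backbones <- cfg$backbones[1:2]
  cfg$use_cbam <- cfg$use_cbam[1:2]
  expect_error(build_fusion_model(cfg), "zero_pad")
})

test_that("zero_pad fusion pads 12x17 branches up to 14x19 and forwards", {
  cfg <- tiny_fusion_config("zero_pad", n_classes = 4L,
                            input_shape = c(48L, 64L, 3L),
                            maps = list(c(12L, 17L, 8L), c(12L, 17L, 6L),
                                        c(14L, 19L, 8L)))
  m <- build_fusion_model(cfg, seed = 3)
  expect_equal(nn_shape(m$graph, "tb1_pad"), c(14L, 19L, 8L))
  expect_equal(nn_shape(m$graph, "fused"), c(14L, 19L, 22L))
  x <- array(runif(48 * 64 * 3), c(48, 64, 3, 1))
  fw <- nn_forward(m$graph, x)
  # padding adds nothing: activation sums invariant
  expect_equal(sum(fw$acts[["tb1_pad"]]), sum(fw$acts[["tb1_feat"]]))
  p <- fw$acts[[m$outputs]]
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("classifier-level fusion exposes four probability outputs", {
  cfg <- tiny_fusion_config("dense_concat", n_classes = 3L)
  m <- build_fusion_model(cfg, seed = 4)
  expect_length(m$outputs, 4L)
  expect_equal(m$outputs[4], "merged_probs")
  x <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  fw <- nn_forward(m$graph, x)
  for (o in m$outputs) {
    p <- fw$acts[[o]]
    expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  }
  # fewer than two branches is rejected
  expect_error(fusion_config("dense_concat",
                             list(tiny_backbone(c(2L, 2L, 4L))), 3L),
               "at least 2")
})

test_that("parallel strategies demand identical branch shapes", {
  cfg <- tiny_fusion_config("sum", n_classes = 3L,
                            maps = list(c(2L, 2L, 4L), c(3L, 3L, 4L),
                                        c(2L, 2L, 4L)))
  expect_error(build_fusion_model(cfg), "identical")
  cfg2 <- tiny_fusion_config("mean", n_classes = 3L,
                             maps = list(c(2L, 2L, 4L), c(2L, 2L, 4L)))
  cfg2$backbones <- cfg2$backbones[1:2]
  cfg2$use_cbam <- cfg2$use_cbam[1:2]
  m <- build_fusion_model(cfg2, seed = 5)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  expect_equal(sum(model_probs(m, x)), 1, tolerance = 1e-9)
})
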