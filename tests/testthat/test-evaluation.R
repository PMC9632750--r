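test_that("confusion counts match a 4-sample hand enumeration", {
  cc <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  a <- cc$counts[cc$counts$class == "A", ]
  expect_equal(c(a$TP, a$FN, a$FP, a$TN), c(1, 1, 0, 2))
  b <- cc$counts[cc$counts$class == "B", ]
  expect_equal(c(b$TP, b$FN, b$FP, b$TN), c(2, 0, 1, 1))
  expect_equal(sum(diag(cc$matrix)), 3)
})

test_that("perfect and degenerate predictors give the expected counts", {
  y <- rep(c("x", "y", "z"), times = c(5, 3, 2))
  cc <- confusion_matrix(y, y)
  expect_true(all(cc$matrix[row(cc$matrix) != col(cc$matrix)] == 0))
  expect_true(all(cc$counts$FP == 0) && all(cc$counts$FN == 0))
  # all-one-class predictor: that class's FP = total - support
  cc2 <- confusion_matrix(y, rep("x", 10))
  xrow <- cc2$counts[cc2$counts$class == "x", ]
  expect_equal(xrow$FP, 10 - xrow$support)
  # one-vs-rest counts always sum to the sample count
  expect_true(all(rowSums(cc2$counts[, c("TP", "FP", "FN", "TN")]) == 10))
})

test_that("per-class metrics are formula-exact with a safe 0/0 convention", {
  cc <- confusion_matrix(c("p", "p", "p", "p", "n", "n", "n", "n", "n", "n"),
                         c("p", "p", "p", "n", "n", "n", "n", "n", "n", "n"))
  pc <- per_class_metrics(cc)
  p <- pc[pc$class == "p", ]
  expect_equal(p$recall, 0.75)       # TP=3, FN=1
  expect_equal(p$precision, 1.0)     # FP=0
  expect_equal(p$f1, 6 / 7)
  expect_equal(p$accuracy, 0.9)
  # symmetric counts TP=FP=FN=TN=1
  cc2 <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "a", "b"))
  pc2 <- per_class_metrics(cc2)
  expect_equal(pc2$precision, c(0.5, 0.5))
  expect_equal(pc2$recall, c(0.5, 0.5))
  expect_equal(pc2$f1, c(0.5, 0.5))
  # class never predicted and never present -> flagged 0, not NaN
  cc3 <- confusion_matrix(factor(c("a", "a"), c("a", "b")),
                          factor(c("a", "a"), c("a", "b")),
                          classes = c("a", "b"))
  pc3 <- per_class_metrics(cc3)
  expect_equal(pc3$precision[2], 0)
  expect_true(pc3$undefined[2])
})

test_that("weighted averages follow the support proportions", {
  expect_equal(weighted_average(c(1, 0), c(3, 1)), 0.75)
  expect_equal(weighted_average(c(0.4, 0.8), c(5, 5)), 0.6)  # equal supports
  expect_equal(weighted_average(0.37, 9), 0.37)              # single class
})

test_that("midrank AUC equals the brute-force pair-counting oracle", {
  set.seed(20)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    k <- sample(2:4, 1)
    classes <- letters[1:k]
    y <- sample(classes, n, replace = TRUE)
    scores <- matrix(round(runif(n * k), 2), n, k,
                     dimnames = list(NULL, classes))
    a <- roc_auc(scores, y, classes)
    for (j in seq_len(k)) {
      oracle <- auc_pair_oracle(scores[, j], y == classes[j])
      expect_equal(unname(a$per_class[j]), oracle, info = paste("rep", rep))
    }
  }
})

test_that("AUC endpoints: perfect separation gives 1, constant scores give 0.5", {
  y <- c("a", "a", "b", "b", "b")
  s <- cbind(a = c(0.9, 0.8, 0.1, 0.2, 0.3), b = c(0.1, 0.2, 0.9, 0.8, 0.7))
  expect_equal(unname(roc_auc(s, y)$per_class), c(1, 1))
  s0 <- cbind(a = rep(0.5, 5), b = rep(0.5, 5))
  expect_equal(unname(roc_auc(s0, y)$per_class), c(0.5, 0.5))
  # absent class is NA and excluded from the weighted average
  s2 <- cbind(a = runif(5), b = runif(5), c = runif(5))
  a2 <- roc_auc(s2, y, c("a", "b", "c"))
  expect_true(is.na(a2$per_class["c"]))
  expect_false(is.na(a2$weighted))
})

test_that("midrank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- sample(c("pos", "neg"), 40, replace = TRUE, prob = c(0.4, 0.6))
  s <- round(runif(40), 1)  # coarse scores force ties
  mine <- roc_auc(cbind(pos = s, neg = 1 - s), y, c("pos", "neg"))
  ref <- suppressMessages(pROC::auc(pROC::roc(y == "pos", s, quiet = TRUE)))
  expect_equal(unname(mine$per_class["pos"]), as.numeric(ref))
})

test_that("the assembled report is internally consistent", {
  set.seed(22)
  classes <- c("a", "b", "c")
  y <- sample(classes, 30, replace = TRUE)
  scores <- matrix(runif(90), 30, 3, dimnames = list(NULL, classes))
  scores <- scores / rowSums(scores)
  rep <- metrics_report(y, scores = scores)
  # micro consistency: trace of the K x K matrix = sum of per-class TP
  expect_equal(sum(diag(rep$confusion$matrix)),
               sum(rep$confusion$counts$TP))
  expect_equal(rep$overall_accuracy,
               sum(diag(rep$confusion$matrix)) / 30)
  # weighted averages lie within the per-class range
  for (v in c("accuracy", "recall", "precision", "f1")) {
    expect_gte(rep$weighted[[v]], min(rep$per_class[[v]]))
    expect_lte(rep$weighted[[v]], max(rep$per_class[[v]]))
  }
  expect_true(all(rep$per_class$accuracy ==
    (rep$confusion$counts$TP + rep$confusion$counts$TN) / 30))
  # JSON + CSV round trip
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_metrics(rep, jp, cp)
  expect_true(file.exists(jp) && file.exists(cp))
  back <- jsonlite::read_json(jp)
  expect_equal(back$overall_accuracy, rep$overall_accuracy)
})
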