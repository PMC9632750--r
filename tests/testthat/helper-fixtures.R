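# Shared fixtures and independent oracles used across the suite.

# tiny in-memory dataset: n records per class, images h x w, raw 8-bit scale
make_dataset <- function(counts, h = 8L, w = 8L, seed = 1L) {
  set.seed(seed)
  records <- list()
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      px <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
      records[[length(records) + 1L]] <-
        image_record(sprintf("%s_%03d", cl, i), px, cl)
    }
  }
  labeled_dataset(records, names(counts))
}

# preprocessed ([0,1]) variant
make_preprocessed <- function(counts, h = 8L, w = 8L, seed = 1L) {
  preprocess_dataset(make_dataset(counts, h, w, seed), h, w)
}

# brute-force one-vs-rest AUC by pair counting (ties count half)
auc_pair_oracle <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# direct per-class counting oracle for the confusion-derived metrics
metrics_count_oracle <- function(y_true, y_pred, cl) {
  tp <- sum(y_true == cl & y_pred == cl)
  fp <- sum(y_true != cl & y_pred == cl)
  fn <- sum(y_true == cl & y_pred != cl)
  tn <- sum(y_true != cl & y_pred != cl)
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
  list(TP = tp, FP = fp, FN = fn, TN = tn,
       accuracy = (tp + tn) / length(y_true),
       recall = rec,
       specificity = div(tn, tn + fp),
       precision = prec,
       f1 = div(2 * prec * rec, prec + rec))
}

# small fusion config over tiny backbones (fast numeric paths)
tiny_fusion_config <- function(strategy = "dense_concat", n_classes = 3L,
                               input_shape = c(16L, 16L, 3L),
                               maps = list(c(2L, 2L, 4L), c(2L, 2L, 4L),
                                           c(3L, 3L, 4L)),
                               use_cbam = TRUE) {
  bbs <- lapply(seq_along(maps), function(i)
    tiny_backbone(maps[[i]], name = paste0("tb", i)))
  fusion_config(strategy, bbs, n_classes = n_classes,
                input_shape = input_shape, use_cbam = use_cbam,
                cbam_reduction = 2L, branch_dense_units = 6L)
}
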