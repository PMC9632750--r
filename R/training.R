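#' Training configuration for the two-phase protocol
#'
#' Phase 1 trains with all backbone parameters frozen (only the attention,
#' dense and classification layers learn); phase 2 unfreezes everything and
#' fine-tunes the whole network at a learning rate no larger than phase 1's.
#'
#' @param phase1_epochs,phase2_epochs Epochs per phase; defaults 5 and 20.
#' @param batch_size Mini-batch size; default 16.
#' @param lr_phase1,lr_phase2 Adam learning rates; defaults 1e-3 and 1e-5.
#'   `lr_phase2` must not exceed `lr_phase1`.
#' @param class_weights Optional named per-class loss weights (see
#'   [class_weights()]); `NULL` disables weighting.
#' @param seed Seed controlling mini-batch order.
#' @return A list of class `train_config`.
#' @export
train_config <- function(phase1_epochs = 5L, phase2_epochs = 20L,
                         batch_size = 16L, lr_phase1 = 1e-3,
                         lr_phase2 = 1e-5, class_weights = NULL, seed = 1L) {
  if (lr_phase2 > lr_phase1)
    stop("phase-2 learning rate must not exceed phase-1 learning rate")
  structure(list(phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "train_config")
}

#' Convert a dataset to a numeric batch
#'
#' @param ds A [labeled_dataset()] of preprocessed records (uniform size).
#' @return List with `x` (H x W x C x N array), `y` (K x N one-hot matrix
#'   over `ds$classes`) and `labels`.
#' @export
dataset_to_batch <- function(ds) {
  n <- length(ds$records)
  stopifnot(n > 0L)
  d <- dim(ds$records[[1]]$pixels)
  x <- array(0, c(d, n))
  for (i in seq_len(n)) x[, , , i] <- ds$records[[i]]$pixels
  labels <- dataset_labels(ds)
  y <- matrix(0, length(ds$classes), n,
              dimnames = list(ds$classes, NULL))
  y[cbind(match(labels, ds$classes), seq_len(n))] <- 1
  list(x = x, y = y, labels = labels)
}

ce_loss <- function(p, y, w = NULL, eps = 1e-9) {
  l <- -colSums(y * log(p + eps))
  if (!is.null(w)) l <- l * w
  mean(l)
}

ce_grad <- function(p, y, w = NULL, eps = 1e-9) {
  gseed <- -(y / (p + eps)) / ncol(p)
  if (!is.null(w)) gseed <- sweep(gseed, 2, w, "*")
  gseed
}

#' Two-phase transfer-learning trainer
#'
#' Trains a [build_fusion_model()] network on the training split with
#' categorical cross-entropy summed over all output heads (for the
#' classifier-level strategy the total loss is the sum of the three
#' auxiliary losses and the merged loss). Phase 1 updates only parameters
#' outside the backbone (the backbone weights stay bit-identical); phase 2
#' fine-tunes every parameter. Mini-batch order is deterministic under the
#' configuration seed.
#'
#' @param model A `fusion_model`.
#' @param splits A `dataset_splits` (only `train` and `valid` are used) or a
#'   `labeled_dataset` used as the training set.
#' @param cfg A [train_config()].
#' @return An object of class `fusion_fit` with the trained model, per-epoch
#'   `history`, per-step `loss_trace` (total and per-head losses) and the
#'   configurations.
#' @export
two_phase_train <- function(model, splits, cfg = train_config()) {
  stopifnot(inherits(model, "fusion_model"))
  train <- if (inherits(splits, "dataset_splits")) splits$train else splits
  valid <- if (inherits(splits, "dataset_splits")) splits$valid else NULL
  if (!length(train$records)) stop("empty training set")
  batch <- dataset_to_batch(train)
  vbatch <- if (!is.null(valid) && length(valid$records))
    dataset_to_batch(valid) else NULL
  g <- model$graph
  wmap <- NULL
  if (!is.null(cfg$class_weights))
    wmap <- cfg$class_weights[batch$labels]

  backbone_nodes <- names(Filter(function(nd) nd$tag == "backbone", g$nodes))
  all_owners <- names(g$params)
  head_owners <- setdiff(all_owners, backbone_nodes)

  rng <- local_rng(cfg$seed)
  state <- adam_state()
  n <- length(train$records)
  history <- list()
  trace <- list()
  step <- 0L

  run_phase <- function(phase, epochs, lr, include) {
    for (ep in seq_len(epochs)) {
      ord <- rng$sample_int(n, n)
      ep_losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- batch$x[, , , idx, drop = FALSE]
        yb <- batch$y[, idx, drop = FALSE]
        wb <- if (!is.null(wmap)) wmap[idx] else NULL
        fw <- nn_forward(g, xb, need_grads = TRUE)
        head_losses <- vapply(model$outputs, function(o)
          ce_loss(fw$acts[[o]], yb, wb), numeric(1))
        total <- sum(head_losses)
        if (!is.finite(total))
          stop("divergent loss (", total, ") in phase ", phase,
               " epoch ", ep, "; lower the learning rate")
        seeds <- lapply(model$outputs, function(o)
          ce_grad(fw$acts[[o]], yb, wb))
        names(seeds) <- model$outputs
        bk <- nn_backward(g, fw, seeds)
        adam_step(g, bk$pgrads, lr, state, include = include)
        step <<- step + 1L
        trace[[step]] <<- c(step = step, phase = phase, total = total,
                            head_losses)
        ep_losses <- c(ep_losses, total)
      }
      vacc <- NA_real_
      if (!is.null(vbatch)) {
        vp <- predict_in_batches(g, model$outputs[length(model$outputs)],
                                 vbatch$x, cfg$batch_size)
        vacc <- mean(max.col(t(vp)) == match(vbatch$labels, train$classes))
      }
      history[[length(history) + 1L]] <<- data.frame(
        phase = phase, epoch = ep, loss = mean(ep_losses),
        valid_accuracy = vacc)
    }
  }

  if (cfg$phase1_epochs > 0L)
    run_phase(1L, cfg$phase1_epochs, cfg$lr_phase1, include = head_owners)
  if (cfg$phase2_epochs > 0L)
    run_phase(2L, cfg$phase2_epochs, cfg$lr_phase2, include = NULL)

  trace_df <- as.data.frame(do.call(rbind, trace))
  names(trace_df) <- c("step", "phase", "total",
                       paste0("loss_", model$outputs))
  structure(list(model = model, classes = train$classes,
                 history = do.call(rbind, history), loss_trace = trace_df,
                 train_config = cfg),
            class = "fusion_fit")
}

predict_in_batches <- function(g, output, x, batch_size = 32L) {
  n <- dim(x)[4]
  cols <- lapply(seq(1L, n, by = batch_size), function(start) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- nn_forward(g, x[, , , idx, drop = FALSE])
    fw$acts[[output]]
  })
  do.call(cbind, cols)
}

#' Fit a fusion network to a dataset split
#'
#' Convenience wrapper: builds the model from a [fusion_config()] and trains
#' it with [two_phase_train()].
#'
#' @param splits A `dataset_splits` or training `labeled_dataset`.
#' @param config A [fusion_config()].
#' @param train_cfg A [train_config()].
#' @param seed Seed for parameter initialization.
#' @return A `fusion_fit` object.
#' @export
fusion_fit <- function(splits, config, train_cfg = train_config(),
                       seed = 1L) {
  model <- build_fusion_model(config, seed = seed)
  two_phase_train(model, splits, train_cfg)
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat("<fusion_fit> strategy ", x$model$config$strategy, ", ",
      length(x$classes), " classes\n", sep = "")
  h <- x$history
  cat("  trained ", sum(h$phase == 1), "+", sum(h$phase == 2),
      " epochs; final loss ", signif(h$loss[nrow(h)], 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.fusion_fit <- function(object, ...) {
  cat("Two-phase fusion-network fit\n")
  cat("  strategy:          ", object$model$config$strategy, "\n")
  cat("  backbones:         ",
      paste(vapply(object$model$config$backbones, `[[`, "", "name"),
            collapse = ", "), "\n")
  cat("  classes:           ", paste(object$classes, collapse = ", "), "\n")
  cat("  output heads:      ", length(object$model$outputs), "\n")
  cat("  training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Predict from a fitted fusion network
#'
#' @param object A `fusion_fit`.
#' @param newdata A `labeled_dataset` or an H x W x C x N array.
#' @param type `"prob"` (K x N probability matrix), `"class"` (character
#'   labels) or `"branch_prob"` (list of per-head probability matrices, for
#'   hard voting).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.fusion_fit <- function(object, newdata,
                               type = c("prob", "class", "branch_prob"),
                               ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "labeled_dataset")) dataset_to_batch(newdata)$x
       else newdata
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  g <- object$model$graph
  if (type == "branch_prob") {
    out <- lapply(object$model$outputs, function(o)
      predict_in_batches(g, o, x))
    names(out) <- object$model$outputs
    return(out)
  }
  p <- predict_in_batches(g, object$model$outputs[length(object$model$outputs)], x)
  rownames(p) <- object$classes
  if (type == "prob") p else object$classes[max.col(t(p))]
}

#' @export
plot.fusion_fit <- function(x, ...) {
  h <- x$history
  plot(seq_len(nrow(h)), h$loss, type = "b", xlab = "epoch",
       ylab = "mean total loss",
       main = "Two-phase training", col = h$phase, pch = 19, ...)
  graphics::legend("topright", legend = c("phase 1 (frozen)", "phase 2"),
                   col = 1:2, pch = 19, bty = "n")
  invisible(x)
}

#' Hard-voting ensemble prediction
#'
#' Majority vote over the class predictions of several voters; ties are
#' broken in favour of the tied label with the highest mean predicted
#' probability (or the earliest tied label if no probabilities are given).
#'
#' @param votes Matrix of class indices, voters in rows and samples in
#'   columns (or a list of per-voter index vectors).
#' @param probs Optional list of K x N per-voter probability matrices.
#' @return Integer vector of winning class indices per sample.
#' @export
hard_voting_predict <- function(votes, probs = NULL) {
  if (is.list(votes)) votes <- do.call(rbind, votes)
  stopifnot(nrow(votes) >= 2L)
  n <- ncol(votes)
  meanp <- if (!is.null(probs)) Reduce(`+`, probs) / length(probs) else NULL
  vapply(seq_len(n), function(j) {
    tab <- table(votes[, j])
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) return(top)
    if (is.null(meanp)) return(top[1])
    top[which.max(meanp[top, j])]
  }, integer(1))
}
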