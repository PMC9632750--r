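#' Pipeline configuration
#'
#' One declarative object drives the whole run: data source (a directory +
#' metadata CSV, or a synthetic specification), preprocessing target size,
#' split ratio, imbalance strategy, stylizer backend, fusion architecture and
#' training protocol. When read from YAML, explicit arguments override the
#' file's values.
#'
#' @param image_dir,metadata Image directory and metadata CSV (real data).
#' @param synthetic_scale If not `NULL`, generate a synthetic dataset at this
#'   scale instead of reading files.
#' @param image_size `c(H, W)` target size used both for synthetic generation
#'   and preprocessing; default `c(32, 32)` (desk scale).
#' @param split_ratio Train/valid/test ratio; default `c(3, 1, 1)`.
#' @param strategy Imbalance treatment: `"rotation_style"` (default;
#'   rotations then style-transfer upsampling), `"rotation"`, `"pixel"`,
#'   `"class_weight"` or `"none"`.
#' @param stylizer Stylizer backend name; default `"statistical"`.
#' @param style_strength Blend strength; default 1.
#' @param majority_class Majority class; default the largest training class.
#' @param fusion_strategy,use_cbam,cbam_reduction,branch_dense_units Fusion
#'   model settings (see [fusion_config()]).
#' @param backbones List of backbone specs; entries may be standard names,
#'   `"tiny"` (a stride-2 tiny backbone) or lists `list(out_map = c(H,W,C))`.
#'   Default: three tiny backbones with distinct map shapes.
#' @param phase1_epochs,phase2_epochs,batch_size,lr_phase1,lr_phase2 Training
#'   settings (see [train_config()]).
#' @param n_explain Number of test images to render saliency overlays for.
#' @param seed Master seed; stage seeds derive from it.
#' @param out_dir Output directory for run artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(image_dir = NULL, metadata = NULL,
                            synthetic_scale = NULL,
                            image_size = c(32L, 32L),
                            split_ratio = c(3L, 1L, 1L),
                            strategy = c("rotation_style", "rotation",
                                         "pixel", "class_weight", "none"),
                            stylizer = "statistical", style_strength = 1,
                            majority_class = NULL,
                            fusion_strategy = "dense_concat",
                            use_cbam = TRUE, cbam_reduction = 4L,
                            branch_dense_units = 16L,
                            backbones = NULL,
                            phase1_epochs = 1L, phase2_epochs = 2L,
                            batch_size = 16L, lr_phase1 = 1e-3,
                            lr_phase2 = 1e-4, n_explain = 2L,
                            seed = 1L, out_dir = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(backbones))
    backbones <- list(list(out_map = c(4L, 4L, 8L)),
                      list(out_map = c(4L, 4L, 8L)),
                      list(out_map = c(4L, 4L, 8L)))
  structure(list(image_dir = image_dir, metadata = metadata,
                 synthetic_scale = synthetic_scale,
                 image_size = as.integer(image_size),
                 split_ratio = as.integer(split_ratio),
                 strategy = strategy, stylizer = stylizer,
                 style_strength = style_strength,
                 majority_class = majority_class,
                 fusion_strategy = fusion_strategy, use_cbam = use_cbam,
                 cbam_reduction = as.integer(cbam_reduction),
                 branch_dense_units = as.integer(branch_dense_units),
                 backbones = backbones,
                 phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 n_explain = as.integer(n_explain),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config()].
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

resolve_backbones <- function(entries) {
  lapply(seq_along(entries), function(i) {
    b <- entries[[i]]
    if (inherits(b, "backbone_spec")) return(b)
    if (is.character(b) && b != "tiny") return(backbone(b))
    out_map <- if (is.list(b) && !is.null(b$out_map)) as.integer(b$out_map)
               else c(4L, 4L, 8L)
    tiny_backbone(out_map, name = paste0("tiny", i))
  })
}

#' Run the full pipeline
#'
#' Executes prepare (load or simulate, preprocess, stratified split), augment
#' (per the configured imbalance strategy), train (two-phase protocol),
#' evaluate (full metric suite on the test split) and explain (saliency
#' overlays), writing a self-describing set of artifacts to `out_dir`:
#' `config.json`, `split_manifest.csv`, `augmentation_plan.json`,
#' `augment_manifest.csv`, `history.csv`, `metrics.json`,
#' `per_class_metrics.csv`, saliency PNGs and a `run_manifest.json` capturing
#' seeds, counts and versions. Any stage failure halts the run with the stage
#' name after persisting the partial manifest.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the splits, plan, fit, metrics report and
#'   output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (is.null(out)) out <- tempfile("lesionfuse_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, strategy = cfg$strategy,
                   package_version = as.character(utils::packageVersion("lesionfuse")),
                   r_version = R.version.string,
                   stages = character())
  persist <- function()
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    persist()
    res
  }
  cfg_json <- cfg[!vapply(cfg, is.null, logical(1))]
  cfg_json$backbones <- lapply(cfg$backbones, function(b) {
    if (inherits(b, "backbone_spec"))
      list(name = b$name, out_map = b$expected_map)
    else b
  })
  jsonlite::write_json(cfg_json, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- prepare ---------------------------------------------------------------
  splits <- stage("prepare", function() {
    ds <- if (!is.null(cfg$synthetic_scale)) {
      generate_dataset(synthetic_spec(scale = cfg$synthetic_scale,
                                      image_size = cfg$image_size,
                                      seed = cfg$seed))
    } else {
      if (is.null(cfg$image_dir) || is.null(cfg$metadata))
        stop("either synthetic_scale or image_dir+metadata must be set")
      load_dataset(cfg$image_dir, cfg$metadata)
    }
    ds <- preprocess_dataset(ds, cfg$image_size[1], cfg$image_size[2])
    sp <- stratified_split(ds, cfg$split_ratio, seed = cfg$seed)
    write_split_manifest(sp, file.path(out, "split_manifest.csv"))
    manifest$class_counts <<- as.list(ds$counts)
    sp
  })

  # -- augment ---------------------------------------------------------------
  aug <- stage("augment", function() {
    train <- splits$train
    maj <- cfg$majority_class
    if (is.null(maj)) maj <- names(which.max(train$counts))
    plan <- NULL; weights <- NULL
    if (cfg$strategy %in% c("rotation", "rotation_style", "pixel")) {
      train <- augment_rotations(train, maj)
    }
    if (cfg$strategy == "rotation_style") {
      # rotation can leave a quadrupled minority above the original majority;
      # the allocation targets whichever class holds the post-rotation maximum
      plan <- compute_allocation(train$counts,
                                 names(which.max(train$counts)))
      train <- execute_plan(train, plan, backend = cfg$stylizer,
                            strength = cfg$style_strength,
                            seed = cfg$seed + 1L)
      jsonlite::write_json(plan, file.path(out, "augmentation_plan.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (cfg$strategy == "pixel")
      train <- pixel_perturbation_upsample(train, maj, seed = cfg$seed + 1L)
    if (cfg$strategy == "class_weight")
      weights <- class_weights(dataset_labels(train))
    utils::write.csv(
      data.frame(image_id = dataset_ids(train),
                 label = dataset_labels(train),
                 provenance = vapply(train$records, `[[`, "", "provenance"),
                 source_id = vapply(train$records, `[[`, "", "source_id")),
      file.path(out, "augment_manifest.csv"), row.names = FALSE)
    manifest$augmented_counts <<- as.list(train$counts)
    manifest$majority_class <<- maj
    list(train = train, plan = plan, weights = weights)
  })

  # -- train -----------------------------------------------------------------
  fit <- stage("train", function() {
    fc <- fusion_config(cfg$fusion_strategy,
                        resolve_backbones(cfg$backbones),
                        n_classes = length(splits$train$classes),
                        input_shape = c(cfg$image_size, 3L),
                        use_cbam = cfg$use_cbam,
                        cbam_reduction = cfg$cbam_reduction,
                        branch_dense_units = cfg$branch_dense_units)
    model <- build_fusion_model(fc, seed = cfg$seed + 2L)
    manifest$model_outputs <<- as.list(model$outputs)
    tc <- train_config(cfg$phase1_epochs, cfg$phase2_epochs, cfg$batch_size,
                       cfg$lr_phase1, cfg$lr_phase2,
                       class_weights = aug$weights, seed = cfg$seed + 3L)
    f <- two_phase_train(model,
                         list(train = aug$train, valid = splits$valid) |>
                           structure(class = "dataset_splits"),
                         tc)
    utils::write.csv(f$history, file.path(out, "history.csv"),
                     row.names = FALSE)
    f
  })

  # -- evaluate ----------------------------------------------------------------
  report <- stage("evaluate", function() {
    test <- splits$test
    p <- predict(fit, test)                      # K x N
    rep <- metrics_report(dataset_labels(test), scores = t(p),
                          classes = fit$classes)
    write_metrics(rep, file.path(out, "metrics.json"),
                  file.path(out, "per_class_metrics.csv"))
    manifest$overall_accuracy <<- rep$overall_accuracy
    rep
  })

  # -- explain -----------------------------------------------------------------
  stage("explain", function() {
    test <- splits$test
    n <- min(cfg$n_explain, length(test$records))
    for (i in seq_len(n)) {
      r <- test$records[[i]]
      sal <- saliency_all_branches(fit$model, r$pixels)
      for (nm in names(sal))
        render_overlay(sal[[nm]], r$pixels,
                       path = file.path(out, sprintf("saliency_%s_%s.png",
                                                     r$id, nm)),
                       matrix_path = file.path(out,
                         sprintf("saliency_%s_%s.txt", r$id, nm)))
    }
    invisible(NULL)
  })

  persist()
  invisible(list(splits = splits, plan = aug$plan, fit = fit,
                 report = report, out_dir = out))
}
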