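# End-to-end orchestration of the cascade: phantom cohort -> preprocessing
# -> segmentation training/inference -> postprocessing -> radiomics ->
# per-side classification -> reports.  One global seed fans out to
# per-stage seeds (derive_seeds), so each stage is reproducible in
# isolation; every artifact lands under the work directory together with a
# config snapshot.

#' Cascade run configuration
#'
#' Nested configuration for [run_cascade()].  Section defaults reproduce
#' the published settings where stated (PLI orientation, (1,1,3) mm
#' spacing, abdominal window 350/40, patch 96^3, lr 3e-4 decayed by 0.9
#' every 20 epochs); phantom-scale settings default to desk-scale values.
#'
#' @param work_dir working directory for all artifacts.
#' @param seed global seed.
#' @param phantom list: n, prevalence, dims, spacing, noise_sigma,
#'   contrast_range, split_ratio.
#' @param preprocess a [preprocess_config()].
#' @param segnet list: channel_plan, residual, n_classes, train
#'   (a [train_config()]), patch_size, overlap, skip (use ground-truth
#'   masks downstream instead of training/inferring).
#' @param radiomics list: bin_width, caps (per-side feature caps).
#' @param classify list: model_set, seed offsets are derived.
#' @param verbose logical.
#' @return A `RunConfig` list.
#' @export
run_config <- function(work_dir = tempfile("cascade_"), seed = 1,
                       phantom = list(), preprocess = preprocess_config(),
                       segnet = list(), radiomics = list(),
                       classify = list(), verbose = FALSE) {
  ph <- utils::modifyList(list(n = 30, prevalence = 0.5,
                               laterality_weights = c(0.65, 0.14, 0.21),
                               dims = c(48, 48, 24), spacing = c(1, 1, 3),
                               noise_sigma = 5, contrast_range = c(20, 60),
                               split_ratio = c(0.7, 0.3)), phantom)
  sg <- utils::modifyList(list(channel_plan = c(8, 16, 32), residual = TRUE,
                               n_classes = 3, train = train_config(),
                               patch_size = c(32, 32, 24), overlap = 0.25,
                               skip = FALSE), segnet)
  rd <- utils::modifyList(list(bin_width = 0.04,
                               caps = c(left = 24, right = 6)), radiomics)
  cl <- utils::modifyList(list(model_set = SUPPORTED_MODELS), classify)
  structure(list(work_dir = work_dir, seed = as.integer(seed), phantom = ph,
                 preprocess = preprocess, segnet = sg, radiomics = rd,
                 classify = cl, verbose = isTRUE(verbose)),
            class = "RunConfig")
}

load_split_records <- function(manifest, split, pre_config) {
  recs <- manifest[manifest$split == split, ]
  lapply(seq_len(nrow(recs)), function(i) {
    vol <- load_volume(recs$image[i])
    msk <- load_volume(recs$mask[i], as_mask = TRUE)
    pp <- preprocess_volume(vol, msk, pre_config)
    list(id = recs$id[i], volume = pp$volume, mask = pp$mask)
  })
}

#' Run the full cascade
#'
#' Stage graph: phantom cohort generation -> stratified split ->
#' preprocessing -> segmentation training -> sliding-window inference +
#' postprocessing -> segmentation metrics (validation split) -> radiomics
#' -> per-side feature selection -> classifier panel -> per-side
#' ROC/threshold/confusion summary.  With `config$segnet$skip = TRUE` the
#' segmentation stage is bypassed and ground-truth masks feed the
#' classification arm (the manual-ROI pipeline).  A stage failure aborts
#' with the stage name.
#'
#' @param config a [run_config()].
#' @return run report: list(manifest, seg_summary, clf_summary, benches,
#'   config).
#' @export
run_cascade <- function(config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- derive_seeds(config$seed, 5L, salt = 3L)
  say <- function(...) if (config$verbose) message("[cascade] ", ...)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("generating phantom cohort")
  manifest <- run_stage("phantom", {
    m <- generate_cohort(
      n = config$phantom$n, prevalence = config$phantom$prevalence,
      laterality_weights = config$phantom$laterality_weights,
      contrast_range = config$phantom$contrast_range,
      dims = config$phantom$dims, spacing = config$phantom$spacing,
      noise_sigma = config$phantom$noise_sigma, seed = stage_seeds[1],
      out_dir = file.path(config$work_dir, "cohort"))
    split_cohort(m, config$phantom$split_ratio, seed = stage_seeds[2])
  })
  write_manifest(manifest, file.path(config$work_dir, "manifest.csv"))

  seg_summary <- NULL
  mask_paths <- NULL
  history <- NULL
  if (!config$segnet$skip) {
    say("training segmentation model")
    model <- run_stage("train-seg", {
      train_set <- load_split_records(manifest, "train", config$preprocess)
      valid_set <- load_split_records(manifest, "valid", config$preprocess)
      model <- build_model(config$segnet$channel_plan,
                           config$segnet$n_classes,
                           residual = config$segnet$residual,
                           seed = stage_seeds[3])
      fit <- train_segmodel(model, train_set, valid_set,
                            config = config$segnet$train,
                            pre_config = config$preprocess,
                            verbose = config$verbose)
      history <<- fit$history
      save_checkpoint(fit$model, file.path(config$work_dir, "seg_model.rds"),
                      history = fit$history, config = config$segnet)
      fit$model
    })
    say("inference + postprocessing")
    pred_dir <- file.path(config$work_dir, "pred_masks")
    dir.create(pred_dir, showWarnings = FALSE)
    reports <- list()
    mask_paths <- character(0)
    run_stage("infer-seg", {
      for (i in seq_len(nrow(manifest))) {
        rec <- manifest[i, ]
        vol <- load_volume(rec$image)
        msk <- load_volume(rec$mask, as_mask = TRUE)
        pp <- preprocess_volume(vol, msk, config$preprocess)
        inf <- sliding_window_infer(model, pp$volume,
                                    config$segnet$patch_size,
                                    config$segnet$overlap)
        cleaned <- suppressWarnings(postprocess_mask(inf$mask))
        path <- file.path(pred_dir, paste0(rec$id, "_pred.nii.gz"))
        save_volume(cleaned, path)
        mask_paths[rec$id] <- path
        if (rec$split == "valid")
          reports[[rec$id]] <- evaluate_segmentation(cleaned, pp$mask)
      }
    })
    seg_summary <- aggregate_seg_reports(reports)
  } else {
    say("segmentation stage skipped; using ground-truth masks")
  }

  say("radiomics + classification")
  table <- run_stage("extract-features", build_feature_table(
    manifest, mask_paths = mask_paths, pre_config = config$preprocess,
    bin_width = config$radiomics$bin_width))
  utils::write.csv(table, file.path(config$work_dir, "features.csv"),
                   row.names = FALSE)
  benches <- list(); clf_summary <- list()
  for (side in c("left", "right")) {
    res <- run_stage(paste0("classify-", side), {
      sel <- select_features(table, side,
                             cap = config$radiomics$caps[[side]],
                             split = c("train", "valid"))
      fit_classifiers(table, sel, model_set = config$classify$model_set,
                      seed = stage_seeds[4])
    })
    benches[[side]] <- res
    clf_summary[[side]] <- summarize_bench(res)
  }
  clf_summary <- do.call(rbind, clf_summary)

  report <- list(manifest = manifest, seg_summary = seg_summary,
                 clf_summary = clf_summary, benches = benches,
                 history = history, config = config)
  jsonlite::write_json(
    list(seed = config$seed,
         seg_summary = seg_summary, clf_summary = clf_summary),
    file.path(config$work_dir, "report.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  report
}

#' Compare manual vs automatic segmentation for AI classification
#'
#' Builds the feature table and per-side classifiers twice -- once from the
#' manual (ground-truth) masks, once from the provided automatic masks --
#' and compares the two validation ROC curves per side with the paired
#' DeLong test.
#'
#' @param manifest cohort manifest (manual masks in its `mask` column).
#' @param auto_masks named character vector of automatic mask paths,
#'   names = patient ids; must cover the same patients.
#' @param config a [run_config()] (radiomics/classify sections used).
#' @return list with per-side `list(delong, roc_manual, roc_auto)`.
#' @export
compare_manual_vs_auto <- function(manifest, auto_masks,
                                   config = run_config()) {
  missing_ids <- setdiff(manifest$id, names(auto_masks))
  if (length(missing_ids))
    stop("auto masks missing for: ", paste(missing_ids, collapse = ", "))
  tables <- list(
    manual = build_feature_table(manifest, pre_config = config$preprocess,
                                 bin_width = config$radiomics$bin_width),
    auto = build_feature_table(manifest, mask_paths = auto_masks,
                               pre_config = config$preprocess,
                               bin_width = config$radiomics$bin_width))
  seeds <- derive_seeds(config$seed, 2L, salt = 29L)
  out <- list()
  for (side in c("left", "right")) {
    benches <- lapply(tables, function(tb) {
      sel <- select_features(tb, side, cap = config$radiomics$caps[[side]],
                             split = c("train", "valid"))
      fit_classifiers(tb, sel, model_set = config$classify$model_set,
                      seed = seeds[1])
    })
    sm <- benches$manual; sa <- benches$auto
    stopifnot(identical(sm$ids, sa$ids))
    out[[side]] <- list(
      delong = delong_test(sm$scores[[sm$selected]],
                           sa$scores[[sa$selected]], sm$labels),
      roc_manual = sm$roc[[sm$selected]],
      roc_auto = sa$roc[[sa$selected]])
  }
  out
}
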