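# End-to-end pipeline: generate (or load) -> preprocess -> extract ->
# select -> split -> train -> evaluate, with every stage's artifact
# persisted under the output directory together with a manifest of input
# hashes and seeds.

# Deterministic content fingerprint (rolling polynomial over the serialized
# object); used for the manifest's provenance records.
content_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, xdr = TRUE))
  w <- (seq_along(b) - 1L) %% 64L + 1L
  sprintf("%012.0f", sum(as.numeric(b) * w * 2654435761) %% 2^40)
}

#' Assemble a pipeline configuration
#'
#' One block per stage; every tunable that any stage understands appears
#' here with its default. The global seed deterministically derives the
#' per-stage seeds.
#'
#' @param seed global seed.
#' @param out_dir artifact directory.
#' @param generate per-modality generator settings.
#' @param preprocess denoising/outlier settings.
#' @param select hybrid-selection settings (`top_k`, `alpha`,
#'   `k_neighbors`, `skip` to train on all features).
#' @param model classifier overrides (epochs, batch size, learning rate...).
#' @param split train fraction.
#' @param metrics averaging mode.
#' @return An object of class `pipeline_config` (plain nested list).
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("cardiopipe_run_"),
                            generate = list(), preprocess = list(),
                            select = list(), model = list(), split = list(),
                            metrics = list()) {
  defaults <- list(
    seed = seed, out_dir = out_dir,
    generate = list(n_per_class = 100L, n_classes = 5L, beat_len = 187L,
                    noise_sd = 0.05, class_sep = 1, image_size = 64L,
                    n = 500L, n_signal = 5L, n_noise = 8L,
                    missing_frac = 0.02, outlier_frac = 0.01, dup_frac = 0.05),
    preprocess = list(wavelet = "db4", level = 3L,
                      threshold_rule = "universal-hard",
                      z_threshold = 3, winsorize = TRUE),
    select = list(skip = FALSE, top_k = 5L, alpha = 0.5, k_neighbors = 10L),
    model = list(epochs = 10L, batch_size = 32L, lr = 1e-3, dropout = 0.5),
    split = list(train_fraction = 0.8, stratified = TRUE),
    metrics = list(averaging = "macro"))
  cfg <- defaults
  for (blk in c("generate", "preprocess", "select", "model", "split", "metrics"))
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], get(blk))
  structure(cfg, class = "pipeline_config")
}

pipeline_generate <- function(cfg, modality, seed) {
  g <- cfg$generate
  switch(modality,
    ecg = gen_ecg_beats(g$n_per_class, g$n_classes, g$beat_len, g$noise_sd,
                        g$class_sep, seed = seed),
    image = gen_cardiac_images(g$n_per_class, 3L, g$image_size, seed = seed),
    tabular = gen_patient_records(g$n, g$n_signal, g$n_noise, g$missing_frac,
                                  g$outlier_frac, seed = seed),
    metadata = gen_metadata(g$n, g$dup_frac, seed = seed))
}

pipeline_preprocess <- function(cfg, modality, data) {
  p <- cfg$preprocess
  if (modality == "ecg") {
    spec <- denoise_spec(p$wavelet, p$level, p$threshold_rule)
    den <- t(apply(data$signals, 1, function(s)
      minmax_normalize(wavelet_denoise(s, spec))))
    return(beat_table(den, data$labels, data$fs))
  }
  if (modality == "image") {
    imgs <- lapply(data$images, function(im) hist_equalize(im, data$levels))
    return(image_set(imgs, data$labels, data$masks, data$levels))
  }
  # tabular / metadata: clean, impute, winsorize outliers
  out <- clean_metadata(data)
  out <- impute_mean(out)
  if (isTRUE(p$winsorize))
    for (j in seq_along(out$data))
      out$data[[j]] <- winsorize_outliers(out$data[[j]], p$z_threshold)
  out
}

#' Run the full pipeline for one modality
#'
#' Generates (or accepts) the modality's data, preprocesses it, extracts
#' features, runs hybrid feature selection (unless `select$skip`), splits
#' stratified train/test, trains the two-pathway classifier on the
#' selected features — or on raw beats for ECG — and reports the
#' nine-metric evaluation on the held-out test set. All intermediates, the
#' report, and a manifest (stage hashes, seeds, feature schema) are written
#' under `cfg$out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @param modality `"ecg"`, `"image"`, `"tabular"` or `"metadata"`.
#' @param data optional pre-made container (skips generation).
#' @param raw_beats train the ECG model on denoised beats rather than the
#'   extracted feature vectors (default TRUE, mirroring the per-modality
#'   design).
#' @return List: `report`, `model`, `scores` (or NULL when skipped),
#'   `selected`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         modality = c("ecg", "image", "tabular", "metadata"),
                         data = NULL, raw_beats = TRUE) {
  modality <- match.arg(modality)
  for (blk in c("generate", "preprocess", "select", "model", "split", "metrics"))
    if (is.null(cfg[[blk]]))
      stop_invalid("pipeline config is missing the '", blk, "' block")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(modality = modality, seed = cfg$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (is.null(data))
    data <- pipeline_generate(cfg, modality, derive_seed(cfg$seed, "generate"))
  manifest$input_hash <- content_hash(data)
  pre <- pipeline_preprocess(cfg, modality, data)
  manifest$preprocessed_hash <- content_hash(pre)
  feats <- extract_all(modality, pre)
  write_feature_csv(feats, file.path(cfg$out_dir, "features.csv"))
  manifest$features_hash <- content_hash(feats)
  manifest$feature_schema <- feats$names
  scores <- NULL
  selected <- seq_along(feats$names)
  if (!isTRUE(cfg$select$skip)) {
    scores <- hybrid_selection(feats, k_neighbors = cfg$select$k_neighbors,
                               alpha = cfg$select$alpha,
                               seed = derive_seed(cfg$seed, "select"))
    selected <- select_top(scores, k = cfg$select$top_k)
    write_scores_csv(scores, file.path(cfg$out_dir, "selection_scores.csv"))
    jsonlite::write_json(feats$names[selected],
                         file.path(cfg$out_dir, "selected_features.json"))
  }
  model_input <- if (modality == "ecg" && raw_beats) pre
    else feature_table(feats$values[, selected, drop = FALSE],
                       feats$names[selected], feats$labels)
  n_model_features <- if (inherits(model_input, "beat_table"))
    ncol(model_input$signals) else length(selected)
  n_cls <- length(unique(data_labels(model_input)))
  input_len <- if (inherits(model_input, "beat_table"))
    ncol(model_input$signals) else ncol(model_input$values)
  # short selected-feature vectors are zero-padded up to the smallest
  # length the convolution/pooling chain admits
  probe <- cilad_config(input_len = 1000L, n_classes = n_cls)
  lmin <- min_input_len(probe)
  if (inherits(model_input, "feature_table") && input_len < lmin) {
    padded <- cbind(model_input$values,
                    matrix(0, nrow(model_input$values), lmin - input_len))
    model_input <- feature_table(padded,
                                 c(model_input$names,
                                   sprintf("pad%02d", seq_len(lmin - input_len))),
                                 model_input$labels)
    input_len <- lmin
  }
  sp <- split_data(model_input,
                   split_spec(cfg$split$train_fraction, cfg$split$stratified,
                              derive_seed(cfg$seed, "split")))
  mcfg <- cilad_config(input_len = input_len, n_classes = n_cls,
                       epochs = cfg$model$epochs,
                       batch_size = cfg$model$batch_size, lr = cfg$model$lr,
                       dropout = cfg$model$dropout,
                       seed = derive_seed(cfg$seed, "model"))
  model <- train_model(build_cilad(mcfg), sp$train)
  utils::write.csv(model$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  pred <- predict(model, sp$test)
  report <- classification_report(data_labels(sp$test), pred$labels,
                                  cfg$metrics$averaging)
  write_report_json(report, file.path(cfg$out_dir, "report.json"))
  manifest$n_features_model <- n_model_features
  manifest$model_input_len <- input_len
  manifest$model_hash <- content_hash(model[c("p1", "p2", "head")])
  manifest$report_hash <- content_hash(report)
  manifest$stages <- c("generate", "preprocess", "extract",
                       if (!isTRUE(cfg$select$skip)) "select",
                       "split", "train", "evaluate")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  list(report = report, model = model, scores = scores, selected = selected,
       manifest = manifest, out_dir = cfg$out_dir)
}
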