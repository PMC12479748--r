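# End-to-end pipeline: simulate -> render -> digitize -> (features ->
# subsystem 1) and (audio -> spectrogram -> subsystem 2) -> weighted ensemble
# -> evaluation -> Grad-CAM region metrics. Every run is a pure function of
# its configuration (including the seed) and writes a manifest.

#' Pipeline configuration
#'
#' @param n_per_class synthetic records per class.
#' @param seed global seed; every stage derives its own stream from it.
#' @param noise_sd,duration generator settings (see [make_ecg_dataset()]).
#' @param test_fraction held-out test share for the stratified split.
#' @param subsystems which classifiers to run: 1, 2, or c(1, 2).
#' @param weights an [ensemble_weights()].
#' @param s1_config,s2_config [train_config()]s for the two subsystems.
#' @param audio_rate intermediate audio rate (Hz) for WAV export.
#' @param spec_config a [spectrogram_config()]; the audio is resampled to
#'   `spec_config$sampling_rate` immediately before the STFT.
#' @param explain_n number of test heatmaps for the region metrics (0 skips).
#' @param out_dir optional output directory for metrics/manifest JSON.
#' @return A `run_config` object.
#' @export
pipeline_config <- function(n_per_class = 100, seed = 1L, noise_sd = 0.05,
                            duration = 10, test_fraction = 0.2,
                            subsystems = c(1, 2),
                            weights = ensemble_weights(0.5, 0.5),
                            s1_config = train_config(seed = seed),
                            s2_config = train_config(learning_rate = 1e-2,
                                                     batch_size = 16,
                                                     epochs = 60, patience = 10,
                                                     seed = seed),
                            audio_rate = 8000,
                            spec_config = spectrogram_config(),
                            explain_n = 50, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

# Digitize a record's rendered image and restore physical time calibration.
digitized_trace <- function(rec, cfg = digitizer_config()) {
  cps <- ncol(rec$image) / rec$spec$duration
  digitize_image(rec$image, cfg, columns_per_second = cps)
}

# Trace -> 224x224x3 spectrogram image (with frame-count attribute), going
# through audio normalization and resampling to the spectrogram rate.
trace_to_spectrogram <- function(trace, spec_config = spectrogram_config()) {
  norm <- normalize_trace(trace)
  w <- resample_trace(norm, spec_config$sampling_rate)
  spectrogram_image(w, spec_config)
}

#' Run the full two-subsystem pipeline on synthetic data
#'
#' Generates the dataset, renders and digitizes the plot images, trains the
#' requested subsystems on the stratified training split, aggregates their
#' probabilities, evaluates on the held-out test split, and (when both
#' subsystems run) computes Grad-CAM region metrics on test heatmaps.
#'
#' @param cfg a [pipeline_config()].
#' @param progress print stage progress?
#' @return A `pipeline_result`: per-subsystem and ensemble metric tables,
#'   AUCs, trained models, region metrics, split indices, and the manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), progress = interactive()) {
  say <- function(...) if (progress) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  say("simulate: %d records/class", cfg$n_per_class)
  dataset <- stage("simulate",
    make_ecg_dataset(cfg$n_per_class, seed = derive_seed(cfg$seed, "data"),
                     noise_sd = cfg$noise_sd, duration = cfg$duration))
  labels <- factor(vapply(dataset, `[[`, character(1), "label"))

  say("digitize: %d images", length(dataset))
  traces <- stage("digitize", lapply(dataset, digitized_trace))

  split <- stratified_split(labels, cfg$test_fraction,
                            seed = derive_seed(cfg$seed, "split"))
  result <- list(labels = labels, split = split, config = cfg)

  p1 <- p2 <- NULL
  if (1 %in% cfg$subsystems) {
    say("subsystem 1: features + training")
    feats <- stage("features", lapply(traces, extract_features))
    m1 <- stage("train-subsystem1",
      train_subsystem1(feats[split$train], labels[split$train], cfg$s1_config))
    p1 <- predict(m1, feats[split$test])
    result$model1 <- m1
    result$features <- feats
  }
  if (2 %in% cfg$subsystems) {
    say("subsystem 2: audio + spectrogram + training")
    specs <- stage("spectrogram",
      lapply(traces, trace_to_spectrogram, spec_config = cfg$spec_config))
    m2 <- stage("train-subsystem2",
      train_subsystem2(specs[split$train], labels[split$train], cfg$s2_config))
    p2 <- predict(m2, specs[split$test])
    result$model2 <- m2
    result$spectrograms <- specs
  }

  test_labels <- labels[split$test]
  eval_probs <- function(probs) {
    pred <- colnames(probs)[max.col(probs)]
    m <- metrics_from_confusion(confusion(test_labels, pred, "le_positive"))
    list(metrics = m,
         auc = 100 * roc_auc(probs[, "le_positive"], test_labels, "le_positive"),
         accuracy = mean(pred == test_labels))
  }
  if (!is.null(p1)) result$subsystem1 <- eval_probs(p1)
  if (!is.null(p2)) result$subsystem2 <- eval_probs(p2)
  if (!is.null(p1) && !is.null(p2)) {
    agg <- ensemble_predict(p1, p2, cfg$weights)
    m <- metrics_from_confusion(confusion(test_labels, agg$label, "le_positive"))
    result$ensemble <- list(
      metrics = m,
      auc = 100 * roc_auc(agg$probs[, "le_positive"], test_labels, "le_positive"),
      accuracy = mean(agg$label == test_labels))
  }

  if (!is.null(result$model2) && cfg$explain_n > 0) {
    say("explain: Grad-CAM region metrics")
    result$region_metrics <- stage("explain",
      pipeline_region_metrics(result, dataset, n = cfg$explain_n))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(seed = cfg$seed, n_per_class = cfg$n_per_class,
                   subsystems = cfg$subsystems)
    for (nm in c("subsystem1", "subsystem2", "ensemble")) {
      if (!is.null(result[[nm]])) {
        report[[nm]] <- list(accuracy = result[[nm]]$accuracy,
                             auc = result[[nm]]$auc,
                             metrics = result[[nm]]$metrics)
      }
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(seed = cfg$seed,
                     config_hash = digest_config(cfg),
                     r_version = as.character(getRversion()),
                     created = "run")
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(result, class = "pipeline_result")
}

# Stable hash of the run configuration (names + deparsed values).
digest_config <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)))
}

# Grad-CAM region metrics over test-set positive-class heatmaps: per-sample
# QRS overlap and RAA against the generator's ground-truth QRS windows mapped
# into spectrogram-image coordinates.
pipeline_region_metrics <- function(result, dataset, n = 50,
                                    activation_threshold = 0.5) {
  cfg <- result$config
  idx <- result$split$test
  idx <- idx[seq_len(min(n, length(idx)))]
  heatmaps <- list(); zones <- list()
  overlaps <- numeric(0); areas <- numeric(0)
  for (i in idx) {
    img <- result$spectrograms[[i]]
    hm <- grad_cam(result$model2, img)   # predicted-class heatmap
    zb <- qrs_zones_to_image(dataset[[i]]$annotations$qrs_windows,
                             dataset[[i]]$trace$sampling_rate,
                             cfg$spec_config, attr(img, "n_frames"),
                             size = nrow(hm))
    mask <- zones_to_mask(zb, dim(hm))
    heatmaps[[length(heatmaps) + 1]] <- hm
    zones[[length(zones) + 1]] <- zb
    overlaps <- c(overlaps, qrs_overlap(hm, mask, activation_threshold))
    areas <- c(areas, mean(mask))
  }
  raa <- region_attention_accuracy(heatmaps, zones, activation_threshold)
  perm <- overlap_permutation_test(overlaps, areas,
                                   seed = derive_seed(cfg$seed, "perm"))
  list(per_sample = data.frame(qrs_overlap = overlaps, area_fraction = areas),
       summary = summarize_region_metrics(
         data.frame(raa = raa, qrs_overlap = overlaps)),
       raa = raa, mean_overlap = mean(overlaps),
       mean_area_fraction = mean(areas),
       permutation = perm)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in c("subsystem1", "subsystem2", "ensemble")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: accuracy %.3f, AUC %.1f%%\n",
                  nm, x[[nm]]$accuracy, x[[nm]]$auc))
    }
  }
  if (!is.null(x$region_metrics)) {
    cat(sprintf("  Grad-CAM: mean QRS overlap %.1f%% (zone area %.1f%%), p = %.4f\n",
                x$region_metrics$mean_overlap,
                100 * x$region_metrics$mean_area_fraction,
                x$region_metrics$permutation$p_value))
  }
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments; nested `s1_config`,
#' `s2_config` and `spec_config` blocks are passed to their constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("s1_config", "s2_config", "spec_config", "weights"))]
  if (!is.null(raw$s1_config)) args$s1_config <- do.call(train_config, raw$s1_config)
  if (!is.null(raw$s2_config)) args$s2_config <- do.call(train_config, raw$s2_config)
  if (!is.null(raw$spec_config)) args$spec_config <- do.call(spectrogram_config, raw$spec_config)
  if (!is.null(raw$weights)) args$weights <- do.call(ensemble_weights, raw$weights)
  do.call(pipeline_config, args)
}
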