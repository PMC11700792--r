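#' Read / write an 8-bit grayscale image
#'
#' PNG only. Color or alpha-carrying PNGs are rejected; intensities are
#' returned as integer grey levels in \[0, 255\]. DICOM input is not
#' supported and raises a clear error.
#'
#' @param path image path.
#' @return numeric matrix of intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) {
    stopf("DICOM input is not supported (%s); convert to 8-bit grayscale PNG", path)
  }
  if (ext != "png") stopf("unsupported image format '%s': %s", ext, path)
  img <- tryCatch(png::readPNG(path), error = function(e)
    stopf("cannot read PNG %s: %s", path, conditionMessage(e)))
  if (!is.matrix(img)) {
    stopf("not an 8-bit grayscale image (color or alpha channels present): %s", path)
  }
  round(img * 255)
}

#' @rdname read_image
#' @param image numeric matrix with intensities in \[0, 255\].
#' @export
write_image <- function(image, path) {
  check_gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end run, at desk scale: 52/15/70
#' phantoms (1/8 of the clinical class counts the generator emulates),
#' CLAHE 8x8 tiles at clip 2.0, 3-cluster fuzzy C-means, ROI-based LBP
#' features, a 10-chameleon/15-iteration hyperparameter search over the
#' classical log2 box, and stratified 10-fold evaluation.
#'
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    phantom = list(counts = list(normal = 52L, benign = 15L, malignant = 70L),
                   image_size = 128L, noise_sigma = 4,
                   benign_radius_range = c(4, 7),
                   malignant_radius_range = c(8, 14),
                   spiculation_count = 6L, texture_roughness = 0.5,
                   background_lung_intensity = 60, nodule_intensity = 200,
                   body_intensity = 150, seed = 1L),
    input = list(dir = ""),  # empty: generate phantoms instead of reading
    enhance = list(tile_grid = c(8L, 8L), clip_limit = 2.0),
    segment = list(c = 3L, m = 2.0, tol = 1e-4, max_iter = 200L, seed = 1L),
    features = list(use_roi = TRUE, normalize = TRUE),
    search = list(log2C = c(-5, 15), log2gamma = c(-15, 3), n = 10L, T = 15L,
                  seed = 1L, feature_selection = FALSE),
    eval = list(K = 10L, stratified = TRUE, seed = 1L),
    output = list(dir = "cssvm-output", write_images = FALSE)),
    class = "pipeline_config")
}

validate_config <- function(cfg) {
  def <- default_config()
  for (sec in names(cfg)) {
    if (!(sec %in% names(def))) stopf("unknown config section `%s`", sec)
    for (key in names(cfg[[sec]])) {
      if (!(key %in% names(def[[sec]]))) stopf("unknown config key `%s.%s`", sec, key)
    }
  }
  merged <- def
  for (sec in names(cfg)) merged[[sec]] <- modifyList(def[[sec]], cfg[[sec]])
  chk <- function(cond, key, msg) if (!cond) stopf("invalid value for `%s`: %s", key, msg)
  ph <- merged$phantom
  chk(ph$image_size >= 32, "phantom.image_size", "must be >= 32")
  chk(ph$noise_sigma >= 0, "phantom.noise_sigma", "must be >= 0")
  sg <- merged$segment
  chk(sg$m > 1, "segment.m", "fuzzifier must be > 1")
  chk(sg$c >= 2, "segment.c", "must be >= 2")
  chk(sg$tol > 0, "segment.tol", "must be > 0")
  chk(merged$enhance$clip_limit > 0, "enhance.clip_limit", "must be > 0")
  chk(all(merged$enhance$tile_grid >= 1), "enhance.tile_grid", "must be positive")
  chk(merged$eval$K >= 2, "eval.K", "must be >= 2")
  chk(merged$search$n >= 2, "search.n", "must be >= 2")
  chk(merged$search$T >= 1, "search.T", "must be >= 1")
  structure(merged, class = "pipeline_config")
}

#' Load / dump a pipeline configuration (YAML)
#'
#' Missing keys take their defaults; unknown keys and invalid values are
#' rejected with the offending key path. An empty file yields the all
#' defaults configuration. `load_config(dump_config(x))` is the identity.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  for (sec in names(cfg)) {
    for (key in c("counts", "tile_grid", "benign_radius_range",
                  "malignant_radius_range", "log2C", "log2gamma")) {
      if (!is.null(cfg[[sec]][[key]]) && key != "counts") {
        cfg[[sec]][[key]] <- unlist(cfg[[sec]][[key]])
      }
    }
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param config a `pipeline_config`.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_phantom_params <- function(cfg) {
  ph <- cfg$phantom
  phantom_params(image_size = ph$image_size, noise_sigma = ph$noise_sigma,
                 benign_radius_range = ph$benign_radius_range,
                 malignant_radius_range = ph$malignant_radius_range,
                 spiculation_count = ph$spiculation_count,
                 texture_roughness = ph$texture_roughness,
                 background_lung_intensity = ph$background_lung_intensity,
                 nodule_intensity = ph$nodule_intensity,
                 body_intensity = ph$body_intensity, seed = ph$seed)
}

#' Run the full classification pipeline
#'
#' generate (or read) -> enhance -> segment -> LBP features -> swarm-tuned
#' SVM and untuned baseline on identical folds and features -> evaluation
#' report. All intermediate artifacts (feature CSV, tuning trace, report
#' CSV, run manifest, and optionally enhanced images and ROI masks as PNG)
#' are written under the output directory; the manifest records every seed
#' and parameter needed for exact re-execution.
#'
#' @param config a `pipeline_config` (see [default_config()],
#'   [load_config()]).
#' @param quiet suppress per-stage progress messages.
#' @return `pipeline_result`: list with `report` (an [eval_report()]),
#'   `tuned` (the [tune_cssvm()] result), `accuracy` (named percent
#'   overall CV accuracies), `features`, `labels`, `folds`, `output_dir`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  config <- validate_config(unclass(config))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  out <- config$output$dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: data
  if (!is.null(config$input$dir) && nzchar(config$input$dir)) {
    say("[data] reading dataset from %s", config$input$dir)
    samples <- read_dataset(config$input$dir)
  } else {
    counts <- unlist(config$phantom$counts)
    say("[data] generating %d phantoms (seed %d)", sum(counts), config$phantom$seed)
    samples <- generate_dataset(counts, config_phantom_params(config),
                                seed = config$phantom$seed)
  }
  labels <- vapply(samples, `[[`, "", "label")

  ## stages 2-4: enhance, segment, features
  ecfg <- clahe_config(config$enhance$tile_grid, config$enhance$clip_limit)
  scfg <- fcm_config(config$segment$c, config$segment$m, config$segment$tol,
                     config$segment$max_iter, config$segment$seed)
  say("[features] CLAHE + FCM/ROI + LBP on %d images", length(samples))
  if (config$output$write_images) {
    dir.create(file.path(out, "enhanced"), showWarnings = FALSE)
    dir.create(file.path(out, "masks"), showWarnings = FALSE)
  }
  n <- length(samples)
  feats <- matrix(0, n, 256L)
  roi_empty <- logical(n)
  ids <- vapply(samples, `[[`, "", "sample_id")
  for (i in seq_len(n)) {
    s <- samples[[i]]
    enhanced <- clahe(s$image, ecfg)
    roi <- NULL
    if (config$features$use_roi) {
      ## ROI from the raw image: adaptive equalization redistributes grey
      ## levels per tile and blurs the global strata FCM separates
      roi <- extract_roi(s$image, fcm_cluster(as.numeric(s$image), scfg))
      roi_empty[i] <- roi$empty
    }
    feats[i, ] <- lbp_histogram(lbp_image(enhanced, roi),
                                normalize = config$features$normalize)
    if (config$output$write_images) {
      write_image(enhanced, file.path(out, "enhanced", paste0(s$sample_id, ".png")))
      if (!is.null(roi)) {
        write_image(roi$mask * 255, file.path(out, "masks", paste0(s$sample_id, ".png")))
      }
    }
  }
  rownames(feats) <- ids
  write_features(feats, labels, ids, file.path(out, "features.csv"))

  ## stage 5: folds shared by both techniques
  folds <- kfold_split(labels, K = config$eval$K, stratified = config$eval$stratified,
                       seed = config$eval$seed)

  ## stage 6: baseline SVM and swarm-tuned CS-SVM on identical folds
  space <- search_space(config$search$log2C, config$search$log2gamma)
  say("[tune] chameleon swarm: n=%d, T=%d (seed %d)",
      config$search$n, config$search$T, config$search$seed)
  tuned <- tune_cssvm(feats, labels, folds, space, n = config$search$n,
                      T = config$search$T, seed = config$search$seed,
                      feature_selection = config$search$feature_selection)
  write.csv(data.frame(iteration = seq_along(tuned$fitness_trace) - 1L,
                       best_cv_accuracy = -tuned$fitness_trace),
            file.path(out, "tuning_trace.csv"), row.names = FALSE)

  base_cfg <- baseline_svm_config(ncol(feats))
  t0 <- proc.time()[["elapsed"]]
  pred_base <- cv_predictions(feats, labels, folds, base_cfg)
  t_base <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  pred_tuned <- cv_predictions(feats, labels, folds, tuned$best_config)
  t_tuned <- proc.time()[["elapsed"]] - t0
  say("[eval] recognition pass times: SVM %.2fs, CS-SVM %.2fs", t_base, t_tuned)

  ## stage 7: report + manifest
  report <- eval_report(labels, list(`SVM` = pred_base, `CS-SVM` = pred_tuned),
                        times = c(`SVM` = t_base, `CS-SVM` = t_tuned))
  render_report(report, file.path(out, "report.csv"))
  manifest <- unclass(config)
  manifest$run <- list(package_version = as.character(utils::packageVersion("cssvm")),
                       n_samples = n, roi_empty_count = sum(roi_empty),
                       best_C = tuned$best_config$C,
                       best_gamma = tuned$best_config$gamma,
                       best_cv_accuracy = tuned$best_cv_accuracy)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  structure(list(report = report, tuned = tuned,
                 accuracy = report$overall_accuracy,
                 features = feats, labels = labels, folds = folds,
                 roi_empty = roi_empty, output_dir = out),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("cssvm pipeline result\n")
  cat(sprintf("  samples: %d  (ROI empty: %d)\n", length(x$labels), sum(x$roi_empty)))
  cat(sprintf("  tuned config: C = %.4g, gamma = %.4g\n",
              x$tuned$best_config$C, x$tuned$best_config$gamma))
  for (tech in names(x$accuracy)) {
    cat(sprintf("  %-7s overall %d-fold CV accuracy: %.2f%%\n",
                tech, x$folds$K, x$accuracy[[tech]]))
  }
  invisible(x)
}
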