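#' Stratified K-fold split
#'
#' Deterministic given `seed`. Folds are disjoint, cover all samples and
#' differ in size by at most one; under stratification each fold's
#' per-class count differs from an exact split by at most one sample
#' (classes are shuffled independently and dealt round-robin with a
#' rotating offset that keeps overall fold sizes balanced).
#'
#' @param labels character vector of class labels.
#' @param K number of folds (default 10, the standard protocol for this
#'   pipeline).
#' @param stratified preserve class proportions per fold (default TRUE);
#'   requires every class to have at least K samples.
#' @param seed integer seed.
#' @return `fold_split`: list with `folds` (list of K index vectors), `K`,
#'   `stratified`, `seed`.
#' @export
kfold_split <- function(labels, K = 10, stratified = TRUE, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (K < 2) stopf("K must be >= 2")
  if (n < K) stopf("need at least K = %d samples, got %d", K, n)
  folds <- vector("list", K)
  with_seed(seed, {
    if (stratified) {
      classes <- unique(labels)
      counts <- table(labels)
      short <- names(counts)[counts < K]
      if (length(short)) {
        stopf("class '%s' has fewer than K = %d samples (stratified split impossible)",
              short[1], K)
      }
      offset <- 0L
      assignment <- integer(n)
      for (cl in classes) {
        idx <- sample(which(labels == cl))
        assignment[idx] <- (offset + seq_along(idx) - 1L) %% K + 1L
        offset <- (offset + length(idx)) %% K
      }
      for (k in seq_len(K)) folds[[k]] <- which(assignment == k)
    } else {
      idx <- sample(n)
      for (k in seq_len(K)) folds[[k]] <- sort(idx[seq(k, n, by = K)])
    }
  })
  structure(list(folds = folds, K = as.integer(K), stratified = stratified,
                 seed = as.integer(seed)), class = "fold_split")
}

#' SVM configuration
#'
#' @param C soft-margin penalty (> 0).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF kernel width (> 0); ignored for the linear kernel.
#' @return object of class `svm_config`.
#' @export
svm_config <- function(C = 1, kernel = c("rbf", "linear"), gamma = 1 / 256) {
  kernel <- match.arg(kernel)
  if (C <= 0) stopf("C must be > 0")
  if (gamma <= 0) stopf("gamma must be > 0")
  structure(list(C = C, kernel = kernel, gamma = gamma), class = "svm_config")
}

#' Hyperparameter search space
#'
#' The classical SVM model-selection box on log2 scale.
#'
#' @param log2C range of `log2(C)` (default \[-5, 15\]).
#' @param log2gamma range of `log2(gamma)` (default \[-15, 3\]).
#' @return object of class `search_space`.
#' @export
search_space <- function(log2C = c(-5, 15), log2gamma = c(-15, 3)) {
  for (r in list(log2C, log2gamma)) {
    if (length(r) != 2L || r[1] > r[2]) stopf("search ranges must be ordered pairs")
  }
  structure(list(log2C = as.numeric(log2C), log2gamma = as.numeric(log2gamma)),
            class = "search_space")
}

#' Map an optimizer position to an SVM configuration
#'
#' `C = 2^position[1]`, `gamma = 2^position[2]`; pure and invertible on the
#' box ([encode_config()] is the inverse).
#'
#' @param position numeric vector of length 2 (`log2 C`, `log2 gamma`).
#' @param space a [search_space()].
#' @return an [svm_config()] with RBF kernel.
#' @export
decode_position <- function(position, space = search_space()) {
  stopifnot(inherits(space, "search_space"))
  if (length(position) != 2L) {
    stopf("position must have 2 dimensions (log2C, log2gamma), got %d", length(position))
  }
  svm_config(C = 2^position[1], kernel = "rbf", gamma = 2^position[2])
}

#' @rdname decode_position
#' @param config an [svm_config()] to encode back to log2 coordinates.
#' @export
encode_config <- function(config, space = search_space()) {
  stopifnot(inherits(config, "svm_config"))
  c(log2(config$C), log2(config$gamma))
}

## libsvm's decision-value sign follows the order labels appear in the
## training data, not factor levels: a positive value means the class
## listed first in the model's internal `labels` field.
fit_binary <- function(x, y01, config) {
  yf <- factor(ifelse(y01, "pos", "rest"), levels = c("pos", "rest"))
  fit <- e1071::svm(x, yf, type = "C-classification", scale = FALSE,
                    kernel = if (config$kernel == "rbf") "radial" else "linear",
                    cost = config$C, gamma = config$gamma, fitted = FALSE)
  flip <- if (fit$levels[fit$labels[1]] == "pos") 1 else -1
  list(fit = fit, flip = flip)
}

## column standardization without scale()/apply() overhead
standardize <- function(x, center, scale_) {
  t((t(x) - center) / scale_)
}

#' Train a (possibly multiclass) kernel SVM
#'
#' Features are standardized per dimension with the training data's own
#' mean and standard deviation (stored on the model and re-applied at
#' prediction, so cross-validation never leaks held-out statistics).
#' Multiclass problems are handled one-vs-rest on top of binary soft-margin
#' machines; prediction takes the class with the largest decision value.
#' Deterministic given its inputs.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels character vector (at least two distinct classes).
#' @param config an [svm_config()].
#' @return classifier handle of class `cssvm_svm`.
#' @export
train_svm <- function(features, labels, config = svm_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(inherits(config, "svm_config"))
  if (nrow(features) != length(labels)) stopf("features/labels length mismatch")
  if (anyNA(features) || any(!is.finite(features))) stopf("features must be finite")
  classes <- unique(labels)
  if (length(classes) < 2L) stopf("need at least 2 classes, got: %s", classes[1])
  classes <- if (all(classes %in% CLASS_ORDER)) intersect(CLASS_ORDER, classes) else sort(classes)

  center <- colMeans(features)
  n_r <- nrow(features)
  scale_ <- sqrt(pmax(colSums(features^2) / n_r - center^2, 0) * n_r / max(n_r - 1, 1))
  scale_[scale_ < 1e-12] <- 1
  x <- standardize(features, center, scale_)

  if (length(classes) == 2L) {
    machines <- list(fit_binary(x, labels == classes[1], config))
  } else {
    machines <- lapply(classes, function(cl) fit_binary(x, labels == cl, config))
  }
  structure(list(machines = machines, classes = classes, config = config,
                 center = center, scale = scale_),
            class = "cssvm_svm")
}

#' @export
predict.cssvm_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(character(0))
  if (ncol(newdata) != length(object$center)) {
    stopf("feature dimension mismatch: model expects %d, got %d",
          length(object$center), ncol(newdata))
  }
  x <- standardize(newdata, object$center, object$scale)
  if (length(object$classes) == 2L) {
    m <- object$machines[[1]]
    dv <- attr(predict(m$fit, x, decision.values = TRUE), "decision.values")[, 1] * m$flip
    ifelse(dv >= 0, object$classes[1], object$classes[2])
  } else {
    dvs <- vapply(object$machines, function(m) {
      attr(predict(m$fit, x, decision.values = TRUE), "decision.values")[, 1] * m$flip
    }, numeric(nrow(x)))
    dvs <- matrix(dvs, nrow = nrow(x))
    object$classes[max.col(dvs, ties.method = "first")]
  }
}

#' Cross-validated fitness of an optimizer position
#'
#' Decodes the position, runs K-fold cross-validation (train on K-1 folds,
#' test on the held-out fold) and returns the NEGATIVE mean fold accuracy —
#' negated because the swarm minimizes. Results are cached keyed on the
#' position rounded to 1e-6 and the fold seed.
#'
#' @param position numeric vector (see [decode_position()]).
#' @param features,labels the training data.
#' @param folds a [kfold_split()] built on these labels.
#' @param space a [search_space()].
#' @param cache optional environment used as memo table.
#' @return negative mean cross-validated accuracy (in \[-1, 0\]).
#' @export
cv_fitness <- function(position, features, labels, folds, space = search_space(),
                       cache = NULL) {
  stopifnot(inherits(folds, "fold_split"))
  key <- paste(sprintf("%.6f", position), folds$seed, collapse = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  config <- decode_position(position, space)
  accs <- vapply(folds$folds, function(test_idx) {
    train_idx <- setdiff(seq_along(labels), test_idx)
    model <- train_svm(features[train_idx, , drop = FALSE], labels[train_idx], config)
    mean(predict(model, features[test_idx, , drop = FALSE]) == labels[test_idx])
  }, numeric(1))
  out <- -mean(accs)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' The operational untuned baseline configuration
#'
#' `C = 1`, RBF kernel with `gamma = 1/n_features` — the conventional
#' out-of-the-box SVM against which the swarm-tuned model is compared.
#'
#' @param n_features feature dimension (default 256).
#' @return an [svm_config()].
#' @export
baseline_svm_config <- function(n_features = 256) {
  svm_config(C = 1, kernel = "rbf", gamma = 1 / n_features)
}

#' Tune the SVM with the chameleon swarm
#'
#' Runs [csa_optimize()] over [cv_fitness()] on the given folds (the same
#' folds later used for reporting, mirroring the pipeline's protocol), then
#' refits the final model on all of the data with the best configuration.
#'
#' @param features,labels the training data.
#' @param folds a [kfold_split()] on these labels.
#' @param space a [search_space()].
#' @param n swarm size (default 10).
#' @param T swarm iterations (default 15).
#' @param seed integer seed for the swarm.
#' @param hyperparams a [csa_hyperparams()] set.
#' @param feature_selection also search a per-bin feature mask: the position
#'   gains one dimension per feature, thresholded at 0.5 into an inclusion
#'   mask (excluded bins are zeroed before standardization). Off by
#'   default.
#' @return `cssvm_tuned`: list with `best_config`, `best_cv_fitness`,
#'   `best_cv_accuracy`, `fitness_trace` (non-increasing), `final_model`,
#'   `feature_mask` (logical, when `feature_selection`), `n_evals`.
#' @export
tune_cssvm <- function(features, labels, folds, space = search_space(),
                       n = 10, T = 15, seed = 1,
                       hyperparams = csa_hyperparams(),
                       feature_selection = FALSE) {
  stopifnot(inherits(folds, "fold_split"))
  features <- as.matrix(features)
  p <- ncol(features)
  cache <- new.env(parent = emptyenv())
  lo <- c(space$log2C[1], space$log2gamma[1])
  up <- c(space$log2C[2], space$log2gamma[2])
  if (feature_selection) { lo <- c(lo, rep(0, p)); up <- c(up, rep(1, p)) }
  bounds <- csa_bounds(lo, up)
  mask_from <- function(pos) if (feature_selection) pos[-(1:2)] >= 0.5 else rep(TRUE, p)
  apply_mask <- function(x, mask) { x[, !mask] <- 0; x }
  obj <- function(pos) {
    cv_fitness(pos[1:2], apply_mask(features, mask_from(pos)), labels, folds,
               space, if (feature_selection) NULL else cache)
  }
  res <- csa_optimize(obj, bounds, n = n, T = T, seed = seed,
                      hyperparams = hyperparams)
  best_config <- decode_position(res$best_position[1:2], space)
  best_mask <- mask_from(res$best_position)
  structure(list(best_config = best_config,
                 best_position = res$best_position,
                 best_cv_fitness = res$best_fitness,
                 best_cv_accuracy = -res$best_fitness,
                 fitness_trace = res$trace,
                 final_model = train_svm(apply_mask(features, best_mask), labels,
                                         best_config),
                 feature_mask = best_mask,
                 n_evals = res$n_evals),
            class = "cssvm_tuned")
}

#' @export
predict.cssvm_tuned <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) > 0L && !all(object$feature_mask)) {
    newdata[, !object$feature_mask] <- 0
  }
  predict(object$final_model, newdata, ...)
}

#' Pooled cross-validated predictions for a fixed configuration
#'
#' Trains on K-1 folds and predicts the held-out fold, for every fold;
#' returns the out-of-fold prediction for each sample (the basis of the
#' evaluation report).
#'
#' @param features,labels the data.
#' @param folds a [kfold_split()].
#' @param config an [svm_config()].
#' @return character vector of predictions, aligned with `labels`.
#' @export
cv_predictions <- function(features, labels, folds, config) {
  stopifnot(inherits(folds, "fold_split"))
  preds <- character(length(labels))
  for (test_idx in folds$folds) {
    train_idx <- setdiff(seq_along(labels), test_idx)
    model <- train_svm(features[train_idx, , drop = FALSE], labels[train_idx], config)
    preds[test_idx] <- predict(model, features[test_idx, , drop = FALSE])
  }
  preds
}
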