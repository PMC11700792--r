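# small separable / non-separable toys reused across blocks
toy_separable <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, -3, 0.3), ncol = 2),
             matrix(rnorm(n_per * 2, 3, 0.3), ncol = 2))
  list(x = x, y = rep(c("benign", "malignant"), each = n_per))
}

toy_xor <- function(n_per = 15, seed = 2) {
  set.seed(seed)
  centers <- rbind(c(-2, -2), c(2, 2), c(-2, 2), c(2, -2))
  x <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(n_per * 2, 0, 0.3), ncol = 2), 2, centers[k, ], `+`)))
  list(x = x, y = rep(c("benign", "benign", "malignant", "malignant"), each = n_per))
}

test_that("k-fold splits are disjoint, covering, balanced and stratified", {
  labs <- rep(c("normal", "benign", "malignant"), c(52, 15, 70))
  f <- kfold_split(labs, K = 10, stratified = TRUE, seed = 1)
  all_idx <- sort(unlist(f$folds))
  expect_identical(all_idx, seq_along(labs))
  sizes <- lengths(f$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  # 15 benign into K = 5 folds -> exactly 3 per fold
  f5 <- kfold_split(labs, K = 5, stratified = TRUE, seed = 2)
  benign_per_fold <- vapply(f5$folds, function(ix) sum(labs[ix] == "benign"), 0L)
  expect_true(all(benign_per_fold == 3))
  # per-class proportions within +-1 sample at K = 10
  for (cl in unique(labs)) {
    per <- vapply(f$folds, function(ix) sum(labs[ix] == cl), 0L)
    expect_lte(max(per) - min(per), 1)
  }
  expect_identical(kfold_split(labs, 10, TRUE, 7)$folds,
                   kfold_split(labs, 10, TRUE, 7)$folds)
  expect_error(kfold_split(labs, K = 16, stratified = TRUE), "benign")
  # 100 samples, K = 10, unstratified -> folds of exactly 10
  f100 <- kfold_split(rep(c("a", "b"), 50), K = 10, stratified = FALSE, seed = 3)
  expect_true(all(lengths(f100$folds) == 10))
})

test_that("position decoding is the exact power-of-two map and invertible", {
  expect_equal(decode_position(c(0, 0))$C, 1)
  expect_equal(decode_position(c(0, 0))$gamma, 1)
  lo <- decode_position(c(-5, -15))
  expect_equal(lo$C, 2^-5)
  expect_equal(lo$gamma, 2^-15)
  mid <- decode_position(c(5, -6))
  expect_equal(mid$C, 32)
  expect_equal(mid$gamma, 2^-6)
  expect_equal(encode_config(mid), c(5, -6))
  expect_error(decode_position(c(1, 2, 3)), "2 dimensions")
})

test_that("the SVM wrapper separates separable data and is deterministic", {
  toy <- toy_separable()
  m <- train_svm(toy$x, toy$y, svm_config(C = 10, kernel = "linear"))
  expect_equal(mean(predict(m, toy$x) == toy$y), 1)
  m2 <- train_svm(toy$x, toy$y, svm_config(C = 10, kernel = "linear"))
  set.seed(9); probe <- matrix(rnorm(40), ncol = 2) * 3
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_error(train_svm(toy$x, rep("benign", nrow(toy$x)), svm_config()), "2 classes")
  xx <- toy$x; xx[1, 1] <- NA
  expect_error(train_svm(xx, toy$y, svm_config()), "finite")
})

test_that("XOR data defeats the linear kernel but not a tuned RBF", {
  toy <- toy_xor()
  lin <- train_svm(toy$x, toy$y, svm_config(C = 10, kernel = "linear"))
  expect_lte(mean(predict(lin, toy$x) == toy$y), 0.75)
  rbf <- train_svm(toy$x, toy$y, svm_config(C = 10, kernel = "rbf", gamma = 1))
  expect_equal(mean(predict(rbf, toy$x) == toy$y), 1)
})

test_that("three-class prediction is one-vs-rest, row-stable and shape-safe", {
  set.seed(4)
  centers <- rbind(c(-4, 0), c(4, 0), c(0, 6))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(30, 0, 0.4), ncol = 2), 2, centers[k, ], `+`)))
  y <- rep(c("normal", "benign", "malignant"), each = 15)
  m <- train_svm(x, y, svm_config(C = 10, gamma = 0.5))
  expect_equal(mean(predict(m, x) == y), 1)
  perm <- sample(nrow(x))
  expect_identical(predict(m, x[perm, ]), predict(m, x)[perm])
  expect_identical(predict(m, x[integer(0), , drop = FALSE]), character(0))
  expect_error(predict(m, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("cross-validated fitness is exact on separable data and cached", {
  toy <- toy_separable(n_per = 25)
  folds <- kfold_split(toy$y, K = 5, seed = 1)
  cache <- new.env()
  f1 <- cv_fitness(c(3, 0), toy$x, toy$y, folds, cache = cache)
  expect_equal(f1, -1)
  f2 <- cv_fitness(c(3, 0), toy$x, toy$y, folds, cache = cache)
  expect_identical(f1, f2)
  expect_length(ls(cache), 1)
})

test_that("shuffled labels drive cross-validated accuracy to chance", {
  set.seed(11)
  x <- matrix(rnorm(90 * 8), 90, 8)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    y <- sample(rep(c("normal", "benign", "malignant"), each = 30))
    folds <- kfold_split(y, K = 5, seed = s)
    -cv_fitness(c(0, -3), x, y, folds)
  }, 0)
  expect_gte(mean(accs), 0.20)
  expect_lte(mean(accs), 0.47)
})

test_that("a collapsed search space pins the tuned configuration", {
  toy <- toy_separable(n_per = 15)
  folds <- kfold_split(toy$y, K = 3, seed = 1)
  sp <- search_space(log2C = c(2, 2 + 1e-9), log2gamma = c(-1, -1 + 1e-9))
  tm <- tune_cssvm(toy$x, toy$y, folds, sp, n = 3, T = 2, seed = 1)
  expect_equal(tm$best_config$C, 4, tolerance = 1e-6)
  expect_equal(tm$best_config$gamma, 0.5, tolerance = 1e-6)
  expect_true(all(diff(tm$fitness_trace) <= 0))
  expect_equal(tm$best_cv_accuracy, -tm$best_cv_fitness)
  # refit consistency: re-evaluating the best config on the same folds
  # reproduces the cached best fitness
  expect_equal(cv_fitness(tm$best_position[1:2], toy$x, toy$y, folds, sp),
               tm$best_cv_fitness)
})

test_that("the optional feature-selection mask drops masked columns from the model", {
  toy <- toy_separable(n_per = 15)
  folds <- kfold_split(toy$y, K = 3, seed = 1)
  tm <- tune_cssvm(toy$x, toy$y, folds, search_space(c(0, 4), c(-4, 0)),
                   n = 4, T = 3, seed = 2, feature_selection = TRUE)
  expect_length(tm$feature_mask, 2)
  expect_type(predict(tm, toy$x), "character")
})
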