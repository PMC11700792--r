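test_that("confusion matrices count correctly in the fixed class order", {
  truth <- rep(c("normal", "benign", "malignant"), each = 3)
  cm <- confusion(truth, truth)
  expect_equal(diag(cm), c(normal = 3, benign = 3, malignant = 3))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  all_normal <- confusion(truth, rep("normal", 9))
  expect_equal(unname(all_normal[, "normal"]), c(3, 3, 3))
  expect_equal(sum(all_normal[, c("benign", "malignant")]), 0)
  # 9-sample toy with two specific errors, counted by hand
  pred <- truth; pred[2] <- "benign"; pred[7] <- "normal"
  cm2 <- confusion(truth, pred)
  expect_equal(unname(cm2["normal", "benign"]), 1)
  expect_equal(unname(cm2["malignant", "normal"]), 1)
  expect_equal(sum(diag(cm2)), 7)
  expect_error(confusion(truth, c(truth[-9], "cyst")), "cyst")
  expect_error(confusion(truth, truth[-1]), "length")
})

test_that("one-vs-rest metrics follow the standard definitions", {
  # binary counts TP=8 FN=2 FP=1 TN=9
  cm <- matrix(c(9, 2, 1, 8), 2, 2,
               dimnames = list(true = c("normal", "benign"),
                               predicted = c("normal", "benign")))
  m <- per_class_metrics(cm, "benign")
  expect_equal(m$TP, 8); expect_equal(m$FN, 2)
  expect_equal(m$FP, 1); expect_equal(m$TN, 9)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 90)
  expect_equal(m$fpr, 10)
  expect_equal(m$accuracy, 85)
  perfect <- per_class_metrics(confusion(rep("benign", 4), rep("benign", 4),
                                         c("normal", "benign")), "benign")
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$fpr, NaN)  # no true negatives exist: undefined, no crash
  expect_error(per_class_metrics(cm, "malignant"), "not in matrix")
})

test_that("FPR and specificity always sum to exactly 100", {
  set.seed(5)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 20), 3, 3,
                 dimnames = list(true = CLASS <- c("normal", "benign", "malignant"),
                                 predicted = CLASS))
    for (cl in CLASS) {
      m <- per_class_metrics(cm, cl)
      expect_equal(m$fpr + m$specificity, 100, tolerance = 1e-9)
      expect_true(all(unlist(m[c("fpr", "specificity", "sensitivity", "accuracy")]) >= 0))
      expect_true(all(unlist(m[c("fpr", "specificity", "sensitivity", "accuracy")]) <= 100))
    }
  }
})

test_that("macro averages use half-up rounding to two decimals", {
  expect_equal(macro_average(c(50, 50, 50)), 50)
  expect_equal(macro_average(c(1, 2, 2)), 1.67)
  expect_equal(macro_average(c(0.05, 0.05, 0.005)), 0.04)   # 0.035 rounds up
  expect_error(macro_average(c(1, 2)), "exactly 3")
})

test_that("overall accuracy is invariant under consistent label renaming", {
  set.seed(6)
  truth <- sample(c("normal", "benign", "malignant"), 60, TRUE)
  pred <- truth; pred[sample(60, 12)] <- sample(c("normal", "benign", "malignant"), 12, TRUE)
  acc1 <- sum(diag(confusion(truth, pred))) / 60
  swap <- c(normal = "malignant", benign = "normal", malignant = "benign")
  acc2 <- sum(diag(confusion(swap[truth], swap[pred]))) / 60
  expect_equal(acc1, acc2)
})

test_that("evaluation reports render, round and round-trip through CSV", {
  set.seed(7)
  truth <- rep(c("normal", "benign", "malignant"), c(10, 6, 12))
  p1 <- truth; p1[c(2, 12, 20)] <- c("benign", "malignant", "normal")
  p2 <- truth
  rep_ <- eval_report(truth, list(SVM = p1, `CS-SVM` = p2),
                      times = c(SVM = 1.5, `CS-SVM` = 0.9))
  tab <- render_report(rep_)
  expect_equal(nrow(tab), 8)  # 2 techniques x (3 classes + average)
  avg_rows <- tab[tab$dataset == "average", ]
  for (tech in c("SVM", "CS-SVM")) {
    pc <- tab[tab$technique == tech & tab$dataset != "average", ]
    # internal averages use full precision; re-averaging the 2-dp rendered
    # values must agree to rendering precision
    expect_equal(avg_rows[avg_rows$technique == tech, "accuracy"],
                 macro_average(pc$accuracy), tolerance = 1e-3)
    expect_true(all(abs(pc$fpr + pc$specificity - 100) < 0.015))  # 2-dp rounding slack
  }
  path <- file.path(withr::local_tempdir(), "report.csv")
  render_report(rep_, path)
  expect_equal(read_report(path), tab)
  expect_error(eval_report(truth, list()), "non-empty")
  expect_error(eval_report(truth, list(SVM = p1[-1])), "predictions for")
})
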