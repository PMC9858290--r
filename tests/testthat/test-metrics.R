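test_that("confusion matrix matches the pair-counting oracle", {
  set.seed(51)
  classes <- letters[1:4]
  truth <- sample(classes, 100, replace = TRUE)
  pred <- sample(classes, 100, replace = TRUE)
  cm <- confusion_matrix(truth, pred, classes)
  expect_equal(unclass(cm), oracle_confusion(truth, pred, classes),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 100)
  expect_equal(unname(rowSums(cm)), unname(sapply(classes, function(k)
    sum(truth == k))))
})

test_that("perfect and degenerate predictions give the expected matrices", {
  cm <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"), letters[1:3])
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(overall_accuracy(cm), 1)
  cm2 <- confusion_matrix(c("a", "b", "c"), c("a", "a", "a"), letters[1:3])
  expect_equal(sum(cm2[, 1]), 3)
  expect_error(confusion_matrix("a", "z", "a"), "unknown")
})

test_that("class metrics match a hand count on a 2x2 table", {
  cm <- confusion_matrix(
    c(rep("neg", 10), rep("pos", 10)),
    c(rep("neg", 8), rep("pos", 2), rep("neg", 1), rep("pos", 9)),
    c("neg", "pos"))
  m <- class_metrics(cm)
  expect_equal(m$precision[m$class == "pos"], 9 / 11)
  expect_equal(m$sensitivity[m$class == "pos"], 0.9)
  expect_equal(m$specificity[m$class == "pos"], 0.8)
})

test_that("undefined rates are flagged, never silently zeroed", {
  cm <- confusion_matrix(c("a", "a"), c("b", "b"), c("a", "b"))
  m <- class_metrics(cm)
  expect_true(is.na(m$precision[m$class == "a"]))  # a never predicted
  expect_match(m$undefined[m$class == "a"], "precision")
  expect_equal(m$precision[m$class == "b"], 0)     # predicted but wrong
})

test_that("f_score reproduces printed report-table values and identities", {
  expect_equal(round_half_up(f_score(1.00, 0.94)), 0.9691)
  expect_equal(round_half_up(f_score(0.20, 1.00)), 0.3333)
  for (p in c(0.1, 0.5, 0.9)) expect_equal(f_score(p, p), p)
  expect_true(is.na(f_score(0, 0)))
  set.seed(52)
  for (i in 1:50) {
    p <- runif(1)
    r <- runif(1)
    f <- f_score(p, r)
    expect_gte(f + 1e-12, min(p, r))
    expect_lte(f, max(p, r) + 1e-12)
  }
  expect_equal(f_score(0, 0.5), 0)
})

test_that("overall accuracy equals trace over total", {
  set.seed(53)
  truth <- sample(letters[1:3], 60, replace = TRUE)
  pred <- sample(letters[1:3], 60, replace = TRUE)
  cm <- confusion_matrix(truth, pred, letters[1:3])
  expect_equal(overall_accuracy(cm), mean(truth == pred))
  cm0 <- confusion_matrix(c("a", "b"), c("b", "a"), c("a", "b"))
  expect_equal(overall_accuracy(cm0), 0)
})

test_that("roc_auc equals the exhaustive pairwise oracle on 50 random sets", {
  set.seed(54)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(roc_auc(truth, scores), oracle_auc(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc closed forms: separation, ties, complement symmetry", {
  expect_equal(roc_auc(c(T, T, F, F), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(T, F, T, F), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(TRUE, TRUE), c(0.1, 0.2)), "both positive")
  set.seed(55)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq_len(100), n)  # distinct -> tie-free
    expect_equal(roc_auc(truth, scores) + roc_auc(truth, -scores), 1,
                 tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an established implementation", {
  set.seed(56)
  truth <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
  truth[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(40) + truth
  got <- roc_auc(truth, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("multiclass AUC reduces to per-class binary AUC", {
  set.seed(57)
  classes <- atypical_classes()[1:3]
  truth <- sample(classes, 30, replace = TRUE)
  probs <- matrix(runif(90), 30, 3, dimnames = list(NULL, classes))
  probs <- probs / rowSums(probs)
  got <- multiclass_auc(truth, probs, classes)
  for (k in 1:3)
    expect_equal(got$per_class$auc[k], roc_auc(truth == classes[k], probs[, k]))
  expect_equal(got$macro_auc, mean(got$per_class$auc))
})

test_that("one-hot perfect predictions yield AUC 1, uniform yields 0.5", {
  truth <- rep(c("a", "b"), each = 5)
  onehot <- cbind(a = rep(c(1, 0), each = 5), b = rep(c(0, 1), each = 5))
  res <- multiclass_auc(truth, onehot, c("a", "b"))
  expect_equal(res$per_class$auc, c(1, 1))
  expect_equal(res$macro_auc, 1)
  unif <- matrix(0.5, 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(multiclass_auc(truth, unif, c("a", "b"))$macro_auc, 0.5)
})

test_that("classes absent from truth are flagged and excluded from the macro", {
  truth <- rep(c("a", "b"), each = 4)
  probs <- matrix(runif(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- multiclass_auc(truth, probs, c("a", "b", "c"))
  expect_false(res$per_class$present[3])
  expect_true(is.na(res$per_class$auc[3]))
  expect_equal(res$macro_auc, mean(res$per_class$auc[1:2]))
})

test_that("evaluation_report bundles metrics with tidy/glance support", {
  set.seed(58)
  classes <- atypical_classes()
  truth <- sample(classes, 80, replace = TRUE)
  probs <- matrix(runif(640), 80, 8, dimnames = list(NULL, classes))
  probs <- probs / rowSums(probs)
  pred <- argmax_class(probs)
  rep_ <- evaluation_report(truth, pred, probs, classes)
  td <- tidy(rep_)
  expect_equal(nrow(td), 8)
  expect_true(all(c("precision", "sensitivity", "specificity", "f_score",
                    "auc") %in% names(td)))
  gl <- glance(rep_)
  expect_equal(gl$n, 80)
  expect_equal(gl$overall_accuracy, mean(truth == pred))
  p <- autoplot(rep_)
  expect_s3_class(p, "ggplot")
  dir <- withr::local_tempdir()
  f <- write_report_json(rep_, file.path(dir, "r.json"))
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$overall$accuracy, gl$overall_accuracy)
  expect_length(parsed$per_class, 8)
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.82705, 4), 0.8271)
  expect_equal(round_half_up(0.00005, 4), 0.0001)
})
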