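test_that("confusion matrix tallies pairs and validates labels", {
  truth <- c(1, 1, 2, 2, 3)
  cm <- confusion_matrix(truth, truth, classes = 1:3)
  expect_equal(sum(cm), 5)
  expect_equal(unname(diag(cm)), c(2L, 2L, 1L))
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_error(confusion_matrix(c(1, 9), c(1, 1), classes = 1:2), "outside")
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
})

test_that("tremor-detection table yields the published binary tallies and metrics", {
  t2 <- load_fixture("table2")
  m <- map_labels_by_permutation(t2$predominant_cluster, t2$true_score)
  cm <- confusion_matrix(t2$true_score, m$mapped, classes = c(0, 1))
  b <- binary_metrics(cm, positive = 1)
  # tallied directly from the printed rows
  expect_equal(b$TP, 8)
  expect_equal(b$FP, 0)
  expect_equal(b$TN, 11)
  expect_equal(b$FN, 6)
  expect_equal(b$accuracy, 19 / 25)
  expect_equal(b$precision, 1.0)
  expect_equal(b$recall, 8 / 14, tolerance = 1e-12)
  expect_equal(b$f1, 2 * 1 * (8 / 14) / (1 + 8 / 14), tolerance = 1e-12)
})

test_that("binarised-severity table yields the published tallies and metrics", {
  t4 <- load_fixture("table4")
  m <- map_labels_by_permutation(t4$predominant_cluster, t4$true_score)
  cm <- confusion_matrix(t4$true_score, m$mapped, classes = 1:2)
  b <- binary_metrics(cm, positive = 2)
  expect_equal(b$TP, 2)
  expect_equal(b$FP, 3)
  expect_equal(b$TN, 8)
  expect_equal(b$FN, 1)
  expect_equal(b$accuracy, 10 / 14, tolerance = 1e-12)
  expect_equal(b$precision, 0.4)
  expect_equal(b$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(b$f1, 0.5)
})

test_that("multiclass report reproduces the per-class severity metrics", {
  t3 <- load_fixture("table3")
  m <- map_labels_by_permutation(t3$predominant_cluster, t3$true_score)
  cm <- confusion_matrix(t3$true_score, m$mapped, classes = 1:3)
  r <- multiclass_metrics(cm, task = 2)
  expect_equal(r$accuracy, 8 / 14, tolerance = 1e-12)
  pc <- r$per_class
  expect_equal(pc$precision, c(2 / 3, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(pc$recall, c(2 / 3, 0.6, 1 / 3), tolerance = 1e-12)
  expect_equal(pc$f1, c(2 / 3, 6 / 11, 0.4), tolerance = 1e-12)
  expect_equal(unname(r$macro["precision"]), mean(c(2 / 3, 0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(unname(r$macro["recall"]), mean(c(2 / 3, 0.6, 1 / 3)),
               tolerance = 1e-12)
  expect_equal(unname(r$macro["f1"]), mean(c(2 / 3, 6 / 11, 0.4)),
               tolerance = 1e-12)
  expect_equal(sum(cm), 14)
  expect_equal(sum(diag(cm)) / sum(cm), r$accuracy)
})

test_that("binary metrics agree with the multiclass report restricted to 2 classes", {
  set.seed(17)
  truth <- sample(1:2, 30, replace = TRUE)
  pred <- sample(1:2, 30, replace = TRUE)
  cm <- confusion_matrix(truth, pred, classes = 1:2)
  b <- binary_metrics(cm, positive = 2)
  r <- multiclass_metrics(cm)
  row <- r$per_class[r$per_class$class == "2", ]
  expect_equal(b$precision, row$precision)
  expect_equal(b$recall, row$recall)
  expect_equal(b$f1, row$f1)
  expect_equal(b$accuracy, r$accuracy)
  # accuracy from the trace equals the direct matching fraction
  expect_equal(r$accuracy, mean(truth == pred))
})

test_that("class order permutation leaves accuracy and metric multiset unchanged", {
  set.seed(18)
  truth <- sample(1:3, 40, replace = TRUE)
  pred <- sample(1:3, 40, replace = TRUE)
  r1 <- multiclass_metrics(confusion_matrix(truth, pred, classes = 1:3))
  r2 <- multiclass_metrics(confusion_matrix(truth, pred, classes = c(3, 1, 2)))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(sort(r1$per_class$f1), sort(r2$per_class$f1))
  expect_equal(unname(r1$macro), unname(r2$macro))
})

test_that("degenerate denominators yield flagged zeros, perfect input yields ones", {
  # nothing is ever predicted positive: TP = FP = 0, precision undefined -> 0
  cm <- matrix(c(5L, 3L, 0L, 0L), 2, dimnames = list(true = c("0", "1"),
                                                     predicted = c("0", "1")))
  b <- binary_metrics(cm, positive = 1)
  expect_equal(b$precision, 0)
  expect_true("precision" %in% b$undefined)
  expect_equal(b$f1, 0)

  perfect <- confusion_matrix(c(0, 1, 1), c(0, 1, 1), classes = 0:1)
  bp <- binary_metrics(perfect, positive = 1)
  expect_equal(unlist(bp[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
})
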