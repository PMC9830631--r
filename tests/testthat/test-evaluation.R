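test_that("confusion matrix counts pairs under the predicted-rows convention", {
  cm <- confusion_matrix(c("a", "b", "b"), c("a", "b", "a"),
                         labels = c("a", "b"))
  expect_equal(unname(cm$counts),
               matrix(c(1L, 1L, 0L, 1L), 2, 2))
  # all-correct predictions give a diagonal matrix
  cmd <- confusion_matrix(rep(letters[1:3], 5), rep(letters[1:3], 5))
  expect_equal(sum(cmd$counts) - sum(diag(cmd$counts)), 0)
  expect_error(confusion_matrix("a", c("a", "b")), "equal length")
  expect_error(confusion_matrix("z", "a", labels = c("a", "b")),
               "class set")
})

test_that("a 38-count diagonal cell of a 302-stream fold reads 12.6 %", {
  truth <- c(rep("p4", 38), rep("other", 264))
  pred <- truth                      # all correct
  cm <- confusion_matrix(pred, truth, labels = c("p4", "other"))
  expect_equal(sum(cm$counts), 302)
  expect_equal(round(cm$percent["p4", "p4"], 1), 12.6)
})

test_that("confusion counts match pair enumeration on random labelings", {
  set.seed(77)
  for (rep in 1:50) {
    R <- sample(2:6, 1)
    labs <- paste0("c", seq_len(R))
    n <- sample(20:200, 1)
    pred <- sample(labs, n, replace = TRUE)
    truth <- sample(labs, n, replace = TRUE)
    cm <- confusion_matrix(pred, truth, labels = labs)
    o <- oracle_metrics(pred, truth, labs)
    expect_equal(unname(cm$counts), o$counts)
  }
})

test_that("class_counts decomposes the matrix and conserves the total", {
  cm <- confusion_matrix(c("a", "a", "a", "a", "b", "b"),
                         c("a", "a", "a", "b", "b", "b"),
                         labels = c("a", "b"))
  expect_equal(unname(cm$counts), matrix(c(3L, 0L, 1L, 2L), 2, 2))
  cc <- class_counts(cm, 1)
  expect_equal(unname(cc), c(3, 1, 0, 2))
  for (r in 1:2) {
    expect_equal(sum(class_counts(cm, r)), sum(cm$counts))
  }
  expect_error(class_counts(cm, 3), "range")
})

test_that("metrics reproduce the hand-computed two-class example", {
  cm <- confusion_matrix(c("a", "a", "a", "a", "b", "b"),
                         c("a", "a", "a", "b", "b", "b"),
                         labels = c("a", "b"))
  m <- cm_metrics(cm)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$per_class$precision[1], 0.75)
  expect_equal(m$per_class$recall[1], 1)
  expect_equal(m$per_class$specificity[1], 2 / 3)
  expect_equal(m$per_class$f1[1], 6 / 7)
  # diagonal matrix scores 1 everywhere
  cmd <- confusion_matrix(rep(letters[1:3], 4), rep(letters[1:3], 4))
  md <- cm_metrics(cmd)
  expect_equal(md$accuracy, 1)
  expect_equal(unname(md$macro), rep(1, 4))
})

test_that("metrics agree with the enumeration oracle on random matrices", {
  set.seed(123)
  for (rep in 1:200) {
    R <- sample(2:6, 1)
    labs <- paste0("c", seq_len(R))
    n <- sample(30:150, 1)
    pred <- sample(labs, n, replace = TRUE)
    truth <- sample(labs, n, replace = TRUE)
    cm <- confusion_matrix(pred, truth, labels = labs)
    m <- suppressWarnings(cm_metrics(cm))
    o <- oracle_metrics(pred, truth, labs)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$per_class$precision, unname(o$per[, "precision"]))
    expect_equal(m$per_class$recall, unname(o$per[, "recall"]))
    expect_equal(m$per_class$specificity, unname(o$per[, "specificity"]))
    expect_equal(m$per_class$f1, unname(o$per[, "f1"]))
    expect_equal(unname(m$macro), unname(o$macro))
  }
})

test_that("macro metrics are invariant under class relabelling", {
  set.seed(5)
  labs <- c("a", "b", "c")
  pred <- sample(labs, 120, replace = TRUE)
  truth <- sample(labs, 120, replace = TRUE)
  m1 <- suppressWarnings(cm_metrics(confusion_matrix(pred, truth,
                                                     labels = labs)))
  perm <- c(a = "c", b = "a", c = "b")
  m2 <- suppressWarnings(cm_metrics(confusion_matrix(
    unname(perm[pred]), unname(perm[truth]), labels = labs)))
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(sort(unname(m1$macro)), sort(unname(m2$macro)))
})

test_that("absent classes score zero with a warning", {
  cm <- confusion_matrix(c("a", "a"), c("a", "b"),
                         labels = c("a", "b", "c"))
  expect_warning(m <- cm_metrics(cm), "absent")
  expect_equal(m$per_class$precision[2], 0)
  expect_equal(m$per_class$recall[3], 0)
})

test_that("column-normalized view sums each true class to 100 %", {
  set.seed(6)
  pred <- sample(letters[1:3], 90, replace = TRUE)
  truth <- sample(letters[1:3], 90, replace = TRUE)
  cm <- confusion_matrix(pred, truth)
  cn <- column_normalized(cm)
  expect_equal(unname(colSums(cn)), rep(100, 3))
})

test_that("stratified folds partition the data with balanced classes", {
  set.seed(2)
  labels <- factor(sample(rep(paste0("p", 1:9), each = 336)))
  fold <- make_folds(labels, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- tabulate(fold, 10)
  expect_equal(sum(sizes), 3024)
  expect_equal(min(sizes), 302)   # smallest test fold
  expect_equal(max(sizes), 303)
  # per-class proportions within 2 streams of the global proportion
  for (cl in levels(labels)) {
    per_fold <- tabulate(fold[labels == cl], 10)
    expect_true(all(abs(per_fold - 33.6) <= 2))
  }
  # folds are a disjoint cover by construction of the assignment vector
  expect_length(fold, length(labels))
  # leave-one-out limit
  small <- factor(rep(c("a", "b"), 3))
  loo <- make_folds(small, 6, seed = 1)
  expect_equal(sort(tabulate(loo, 6)), rep(1L, 6))
  expect_error(make_folds(small, 7), "exceed")
  expect_error(make_folds(small, 1), "k must be")
})

test_that("cross-validation tests each sequence exactly once", {
  ds <- toy_dataset(n_per_class = 10, len = 20, seed = 3)
  cv <- suppressWarnings(
    kfold_cross_validate(ds, k = 4, trainer = make_stub_trainer("f0.1"),
                         seed = 9))
  expect_length(cv$fold_metrics, 4)
  expect_equal(sum(cv$pooled$counts), 20)
  # stub always predicts one class: pooled accuracy is the class share
  expect_equal(cv$pooled_accuracy, 0.5)
  expect_true(cv$min_accuracy <= cv$mean_accuracy &&
                cv$mean_accuracy <= cv$max_accuracy)
  expect_length(cv$ci_binomial, 2)
  expect_length(cv$ci_folds, 2)
  expect_error(kfold_cross_validate(ds, k = 50), "exceed")
})
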