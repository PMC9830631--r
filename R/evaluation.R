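#' Confusion matrix (rows = predicted, columns = true)
#'
#' Counts `C[i, j]` = number of streams predicted as class `i` whose true
#' class is `j`. Note the convention: rows index the predicted class and
#' columns the true class, so precision is a row-wise and recall a
#' column-wise quantity. Each cell is also available as a percentage of the
#' total.
#'
#' @param predicted,truth Equal-length label vectors (factors, integers in
#'   `0..R-1`, or values matching `labels`).
#' @param labels Optional character vector fixing the class set and order;
#'   defaults to the union of factor levels / sorted unique values.
#' @return An object of class `confusion_matrix`: integer `counts`,
#'   `percent` (cells as % of total), `labels`.
#' @examples
#' cm <- confusion_matrix(c(0, 1, 1), c(0, 1, 0), labels = c("0", "1"))
#' cm$counts
#' @export
confusion_matrix <- function(predicted, truth, labels = NULL) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (is.factor(predicted) || is.factor(truth)) {
      union(levels(predicted), levels(truth))
    } else {
      sort(unique(c(as.character(predicted), as.character(truth))))
    }
  }
  pf <- factor(as.character(predicted), levels = labels)
  tf <- factor(as.character(truth), levels = labels)
  if (anyNA(pf) || anyNA(tf)) {
    stop("labels outside the declared class set", call. = FALSE)
  }
  counts <- table(predicted = pf, truth = tf)
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(predicted = labels, truth = labels))
  structure(list(counts = counts,
                 percent = 100 * counts / max(sum(counts), 1L),
                 labels = labels),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = predicted, columns = true):\n")
  print(x$counts)
  invisible(x)
}

#' Column-normalized percentage view of a confusion matrix
#'
#' Each column (true class) is normalized to 100 %, the convention used for
#' confusion-matrix heat maps: cell (i, j) is the percentage of class-j
#' streams predicted as class i.
#'
#' @param cm A [confusion_matrix()].
#' @return Numeric matrix of percentages.
#' @export
column_normalized <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cs <- colSums(cm$counts)
  sweep(100 * cm$counts, 2, pmax(cs, 1L), "/")
}

#' Per-class TP / FP / FN / TN counts
#'
#' With rows = predicted and columns = true: `TP_r = C[r, r]`, `FP_r` is
#' the off-diagonal row sum (predicted r but not r), `FN_r` the
#' off-diagonal column sum (true r but missed), and `TN_r` the remainder;
#' the four always sum to the matrix total.
#'
#' @param cm A [confusion_matrix()] (or a plain square count matrix).
#' @param r Class index in `1..R` or class label.
#' @return Named numeric vector `c(TP, FP, FN, TN)`.
#' @export
class_counts <- function(cm, r) {
  C <- if (inherits(cm, "confusion_matrix")) cm$counts else as.matrix(cm)
  if (is.character(r)) r <- match(r, rownames(C))
  if (is.na(r) || r < 1 || r > nrow(C)) {
    stop("class index out of range", call. = FALSE)
  }
  tp <- C[r, r]
  fp <- sum(C[r, ]) - tp
  fn <- sum(C[, r]) - tp
  tn <- sum(C) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy (trace over total) plus per-class precision
#' `C_rr / sum_i C_ri`, recall `C_rr / sum_i C_ir`, specificity (fraction
#' of non-r streams predicted as non-r) and F1
#' (`2 P R / (P + R)`), and their macro averages (arithmetic mean over
#' classes). A class with a zero denominator (never predicted or never
#' present) scores 0 for the affected metric, with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report`: `accuracy`, `per_class`
#'   data frame, `macro` named vector.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  C <- cm$counts
  total <- sum(C)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  R <- nrow(C)
  per <- data.frame(class = cm$labels,
                    TP = numeric(R), FP = numeric(R), FN = numeric(R),
                    TN = numeric(R), precision = numeric(R),
                    recall = numeric(R), specificity = numeric(R),
                    f1 = numeric(R), stringsAsFactors = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  for (r in seq_len(R)) {
    cc <- class_counts(cm, r)
    per$TP[r] <- cc["TP"]; per$FP[r] <- cc["FP"]
    per$FN[r] <- cc["FN"]; per$TN[r] <- cc["TN"]
    per$precision[r] <- safe_div(cc["TP"], cc["TP"] + cc["FP"])
    per$recall[r] <- safe_div(cc["TP"], cc["TP"] + cc["FN"])
    per$specificity[r] <- safe_div(cc["TN"], cc["TN"] + cc["FP"])
    pr <- per$precision[r] + per$recall[r]
    per$f1[r] <- if (pr == 0) 0 else
      2 * per$precision[r] * per$recall[r] / pr
  }
  if (degenerate) {
    warning("class absent from predictions or truth; affected metrics set to 0",
            call. = FALSE)
  }
  structure(list(
    accuracy = sum(diag(C)) / total,
    per_class = per,
    macro = c(precision = mean(per$precision), recall = mean(per$recall),
              specificity = mean(per$specificity), f1 = mean(per$f1)),
    n = total), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f (n = %d)\n", x$accuracy, x$n))
  cat(sprintf("macro: precision %.4f  recall %.4f  specificity %.4f  f1 %.4f\n",
              x$macro["precision"], x$macro["recall"],
              x$macro["specificity"], x$macro["f1"]))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Shuffles each class's members with the seeded RNG and deals them into
#' `k` folds so every fold's class composition is within one stream of the
#' class proportion (stratification). Per-class remainders are spread
#' round-robin with a class-dependent fold offset so overall fold sizes
#' differ by at most one (3024 streams in 10 folds gives folds of 303 and
#' 302).
#'
#' @param labels Factor (or vector) of class labels.
#' @param k Number of folds (2 <= k <= length(labels)).
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the dataset size", call. = FALSE)
  labels <- as.factor(labels)
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      nc <- length(idx)
      base <- nc %/% k
      rem <- nc %% k
      sizes <- rep(base, k)
      if (rem > 0) {
        extra <- ((offset + seq_len(rem) - 1L) %% k) + 1L
        sizes[extra] <- sizes[extra] + 1L
        offset <- (offset + rem) %% k
      }
      fold[idx] <- rep.int(seq_len(k), sizes)
    }
  })
  fold
}

#' k-fold cross-validation
#'
#' Shuffles and partitions the dataset into `k` stratified folds; each
#' sequence is tested exactly once and used for training in the other
#' `k - 1` folds. Reports each fold's metrics, the pooled confusion matrix,
#' and the dispersion of overall accuracy across folds: mean, sample
#' standard deviation, the min--max interval, and two 95 % intervals (a
#' binomial Clopper-Pearson interval on the pooled accuracy and a
#' t-interval on the fold mean) side by side.
#'
#' @param dataset A `csi_dataset`.
#' @param k Number of folds (default 10).
#' @param trainer Function `(train_dataset) -> model`; the model must be
#'   usable with `predict(model, test_dataset)`. Defaults to
#'   [train_bilstm()] with `cfg`.
#' @param seed Seed for the fold shuffle (fold `i`'s trainer receives a
#'   seed derived from it).
#' @param cfg [net_config()] used by the default trainer.
#' @return An object of class `cv_report`: `fold_metrics` (list of
#'   `metrics_report`), `fold_accuracy`, `mean_accuracy`, `sd_accuracy`,
#'   `min_accuracy`, `max_accuracy`, `ci_binomial`, `ci_folds`,
#'   `pooled` (confusion matrix over all test folds), `macro`
#'   (mean of per-fold macro metrics), `fold` assignment.
#' @export
kfold_cross_validate <- function(dataset, k = 10L, trainer = NULL,
                                 seed = 1L, cfg = net_config()) {
  stopifnot(inherits(dataset, "csi_dataset"))
  n <- length(dataset$features)
  if (k > n) stop("k must not exceed the dataset size", call. = FALSE)
  fold <- make_folds(dataset$labels, k, seed)
  labs <- levels(dataset$labels)

  preds <- character(n)
  fold_metrics <- vector("list", k)
  fold_acc <- numeric(k)
  for (i in seq_len(k)) {
    test_idx <- which(fold == i)
    train_idx <- which(fold != i)
    train_ds <- dataset_subset(dataset, train_idx)
    test_ds <- dataset_subset(dataset, test_idx)
    model <- if (is.null(trainer)) {
      fold_cfg <- cfg
      fold_cfg$seed <- derive_seed(seed, 100L + i)
      train_bilstm(train_ds, fold_cfg)
    } else {
      trainer(train_ds)
    }
    p <- predict(model, test_ds)
    preds[test_idx] <- as.character(p)
    cm <- confusion_matrix(as.character(p),
                           as.character(test_ds$labels), labels = labs)
    fold_metrics[[i]] <- cm_metrics(cm)
    fold_acc[i] <- fold_metrics[[i]]$accuracy
  }

  pooled <- confusion_matrix(preds, as.character(dataset$labels),
                             labels = labs)
  pooled_acc <- sum(diag(pooled$counts)) / n
  bt <- stats::binom.test(sum(diag(pooled$counts)), n)
  ci_folds <- if (k >= 2 && stats::sd(fold_acc) > 0) {
    mean(fold_acc) + stats::qt(c(0.025, 0.975), k - 1) *
      stats::sd(fold_acc) / sqrt(k)
  } else c(mean(fold_acc), mean(fold_acc))

  macro <- rowMeans(vapply(fold_metrics, function(m) m$macro, numeric(4)))
  structure(list(fold_metrics = fold_metrics,
                 fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 sd_accuracy = stats::sd(fold_acc),
                 min_accuracy = min(fold_acc),
                 max_accuracy = max(fold_acc),
                 pooled_accuracy = pooled_acc,
                 ci_binomial = as.numeric(bt$conf.int),
                 ci_folds = ci_folds,
                 macro = macro,
                 pooled = pooled,
                 fold = fold, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: accuracy %.4f +/- %.4f (min %.4f, max %.4f)\n",
    x$k, x$mean_accuracy, x$sd_accuracy, x$min_accuracy, x$max_accuracy))
  cat(sprintf("  binomial 95%% CI (%.4f, %.4f); fold-mean 95%% CI (%.4f, %.4f)\n",
              x$ci_binomial[1], x$ci_binomial[2],
              x$ci_folds[1], x$ci_folds[2]))
  invisible(x)
}
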