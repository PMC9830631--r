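# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (per-step recursion, pair enumeration,
# raw FFT argmax) so they never share code with the implementation paths
# they check.

# Brute-force BiLSTM class probabilities: per-step recursion with
# lstm_step(), manual state concatenation, manual softmax.
oracle_bilstm_probs <- function(params, seq_mat) {
  H <- ncol(params$Uf)
  run <- function(W, U, b, steps) {
    h <- numeric(H); c <- numeric(H)
    for (t in steps) {
      st <- lstm_step(seq_mat[t, ], h, c, list(W = W, U = U, b = b))
      h <- st$h; c <- st$c
    }
    h
  }
  Tn <- nrow(seq_mat)
  hf <- run(params$Wf, params$Uf, params$bf, seq_len(Tn))
  hb <- run(params$Wb, params$Ub, params$bb, rev(seq_len(Tn)))
  z <- drop(params$Wfc %*% c(hf, hb)) + params$bfc
  e <- exp(z - max(z))
  e / sum(e)
}

# Random small BiLSTM parameter set (not Glorot; arbitrary scale).
random_params <- function(D, H, R, seed, scale = 0.5) {
  set.seed(seed)
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
  list(Wf = rmat(4 * H, D), Uf = rmat(4 * H, H), bf = stats::rnorm(4 * H, 0, scale),
       Wb = rmat(4 * H, D), Ub = rmat(4 * H, H), bb = stats::rnorm(4 * H, 0, scale),
       Wfc = rmat(R, 2 * H), bfc = stats::rnorm(R, 0, scale))
}

# Wrap raw parameters as a model usable by forward()/predict().
as_model <- function(params, D, labels) {
  structure(list(params = params, label_map = labels,
                 input_channels = D,
                 cfg = net_config(hidden_units = ncol(params$Uf)),
                 loss_history = numeric(), initial_loss = NA_real_,
                 epochs_run = 0L, seed = 0L),
            class = "trained_model")
}

# Pair-enumeration metrics oracle: counts every (predicted, true) pair
# directly, then applies the textbook per-class definitions.
oracle_metrics <- function(pred, truth, labels) {
  R <- length(labels)
  n <- length(pred)
  counts <- matrix(0L, R, R)
  for (i in seq_len(n)) {
    counts[match(pred[i], labels), match(truth[i], labels)] <-
      counts[match(pred[i], labels), match(truth[i], labels)] + 1L
  }
  per <- lapply(seq_len(R), function(r) {
    tp <- sum(pred == labels[r] & truth == labels[r])
    fp <- sum(pred == labels[r] & truth != labels[r])
    fn <- sum(pred != labels[r] & truth == labels[r])
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(tp = tp, fp = fp, fn = fn, tn = tn,
      precision = prec, recall = rec, specificity = spec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(counts = counts,
       accuracy = mean(pred == truth),
       per = per,
       macro = colMeans(per[, c("precision", "recall", "specificity",
                                "f1"), drop = FALSE]))
}

# FFT argmax oracle on a real or complex series (excludes the DC bin).
oracle_fft_peak_hz <- function(x, fs) {
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  half <- floor(length(x) / 2)
  k <- which.max(p[2:(half + 1)])
  k * fs / length(x)
}

# Tiny separable two-class dataset: single-channel sinusoid sequences at
# two distinct frequencies with light noise.
toy_dataset <- function(n_per_class = 20, len = 50, fs = 10,
                        freqs = c(0.1, 0.4), seed = 1) {
  set.seed(seed)
  t <- (seq_len(len) - 1) / fs
  features <- list()
  labels <- character()
  for (ci in seq_along(freqs)) {
    for (j in seq_len(n_per_class)) {
      ph <- stats::runif(1, 0, 2 * pi)
      x <- sin(2 * pi * freqs[ci] * t + ph) + stats::rnorm(len, 0, 0.05)
      features[[length(features) + 1L]] <- matrix(x, ncol = 1)
      labels <- c(labels, sprintf("f%.1f", freqs[ci]))
    }
  }
  structure(list(features = features, labels = factor(labels),
                 frame_rate_hz = fs, duration_s = len / fs,
                 feature_mode = "time"),
            class = "csi_dataset")
}

# Stub model for cross-validation mechanics: predicts the true labels it
# memorized at "training" time is not possible for unseen data, so it
# predicts a fixed class; only the partition bookkeeping is under test.
make_stub_trainer <- function(fixed_label) {
  function(train_ds) {
    structure(list(label = fixed_label,
                   levels = levels(train_ds$labels)),
              class = "stub_model")
  }
}
predict.stub_model <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "csi_dataset")) length(newdata$features)
       else length(newdata)
  factor(rep(object$label, n), levels = object$levels)
}
.S3method("predict", "stub_model", predict.stub_model)
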