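#' Network and training configuration
#'
#' Hyperparameters of the BiLSTM classifier. The defaults are the tuned
#' values used throughout the characterization runs: 50 hidden units per
#' direction, learning rate 0.01 and mini-batch size 64, with an Adam
#' optimizer, a fixed epoch budget and early stopping when the training
#' loss stops improving.
#'
#' @param hidden_units LSTM hidden units per direction (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size (>= 1); the last batch of an epoch may
#'   be smaller.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without the training loss improving by more than
#'   `tol`.
#' @param tol Minimum loss improvement counted as progress.
#' @param seed Seed for weight initialization and shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(hidden_units = 50L, learning_rate = 0.01,
                       batch_size = 64L, max_epochs = 150L,
                       patience = 20L, tol = 1e-4, seed = 1L) {
  if (hidden_units < 1) stop("hidden_units must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 tol = tol, seed = as.integer(seed)),
            class = "net_config")
}

#' One LSTM cell step (reference implementation)
#'
#' The standard LSTM recurrence with input, forget and output gates through
#' the logistic sigmoid and a tanh candidate:
#' `c_t = f * c_prev + i * g`, `h_t = o * tanh(c_t)` (all products
#' element-wise). Gate pre-activations are the stacked rows of
#' `W x_t + U h_prev + b` in the block order input, forget, candidate,
#' output (each `hidden_units` rows). This plain-R step is the reference
#' recursion against which the batched training core is checked.
#'
#' @param x_t Input vector (length D).
#' @param h_prev,c_prev Previous hidden and cell state (length H).
#' @param params List with `W` (4H x D), `U` (4H x H), `b` (4H).
#' @return List with `h` and `c`, each length H.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  H <- length(h_prev)
  if (length(c_prev) != H || nrow(params$W) != 4 * H ||
      ncol(params$W) != length(x_t) || nrow(params$U) != 4 * H ||
      ncol(params$U) != H || length(params$b) != 4 * H) {
    stop("inconsistent shapes in lstm_step", call. = FALSE)
  }
  a <- drop(params$W %*% x_t + params$U %*% h_prev) + params$b
  i <- stats::plogis(a[seq_len(H)])
  f <- stats::plogis(a[H + seq_len(H)])
  g <- tanh(a[2 * H + seq_len(H)])
  o <- stats::plogis(a[3 * H + seq_len(H)])
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

# Glorot-uniform initial parameters for input dimension D and R classes.
init_params <- function(D, H, R, seed) {
  gl <- function(nr, nc, fi, fo) {
    lim <- sqrt(6 / (fi + fo))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    b0 <- rep(0, 4 * H)
    b0[H + seq_len(H)] <- 1          # forget-gate bias starts open
    list(Wf = gl(4 * H, D, D, H), Uf = gl(4 * H, H, H, H), bf = b0,
         Wb = gl(4 * H, D, D, H), Ub = gl(4 * H, H, H, H), bb = b0,
         Wfc = gl(R, 2 * H, 2 * H, R), bfc = rep(0, R))
  })
}

# Stack a list of T x D feature matrices into the (D, N, T) cube layout the
# C++ core expects.
features_to_cube <- function(features) {
  Tlen <- nrow(features[[1]])
  D <- ncol(features[[1]])
  N <- length(features)
  x <- array(0, dim = c(D, N, Tlen))
  for (n in seq_len(N)) x[, n, ] <- t(features[[n]])
  x
}

#' Class probabilities of the BiLSTM for one or more sequences
#'
#' Runs both LSTM directions over the sequence, concatenates the final
#' hidden state of the forward direction with the final hidden state of the
#' backward direction (which has read the sequence reversed), applies the
#' fully connected layer and softmax. Probabilities are nonnegative and sum
#' to one.
#'
#' @param model A `trained_model` (or a bare parameter list plus
#'   `label_map` attribute is not supported — train or construct via
#'   [train_bilstm()]).
#' @param sequences A single `[steps x channels]` feature matrix or a list
#'   of them.
#' @return Matrix `[n_sequences, n_classes]` of probabilities, columns
#'   named by class label.
#' @export
forward <- function(model, sequences) {
  stopifnot(inherits(model, "trained_model"))
  if (is.matrix(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0 || nrow(sequences[[1]]) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  if (ncol(sequences[[1]]) != model$input_channels) {
    stop("sequence channel count does not match the model", call. = FALSE)
  }
  p <- t(cpp_bilstm_probs(model$params, features_to_cube(sequences)))
  colnames(p) <- model$label_map
  p
}

#' Predict class labels
#'
#' Argmax of [forward()] probabilities; exact ties break to the lowest
#' class index.
#'
#' @inheritParams forward
#' @return Factor of predicted labels with the model's class levels.
#' @export
predict_bilstm <- function(model, sequences) {
  p <- forward(model, sequences)
  factor(model$label_map[max.col(p, ties.method = "first")],
         levels = model$label_map)
}

#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (inherits(newdata, "csi_dataset")) newdata <- newdata$features
  predict_bilstm(object, newdata)
}

#' Train the BiLSTM classifier
#'
#' Supervised end-to-end training with softmax cross-entropy loss and the
#' Adam optimizer, in seeded mini-batches (the last batch of an epoch may
#' be smaller). Weights are Glorot-uniform initialized from the seed, the
#' forget-gate bias starts at one, and training stops at the epoch budget
#' or when the training loss plateaus. Identical seeds give identical final
#' weights.
#'
#' @param dataset A `csi_dataset` with at least two classes present.
#' @param cfg A [net_config()].
#' @return An object of class `trained_model`: the BiLSTM and fully
#'   connected parameters, class `label_map`, per-epoch `loss_history`,
#'   `initial_loss` (the loss of the untrained network, about `log(R)` for
#'   `R` balanced classes), and the training provenance.
#' @export
train_bilstm <- function(dataset, cfg = net_config()) {
  stopifnot(inherits(dataset, "csi_dataset"), inherits(cfg, "net_config"))
  labels <- droplevels(dataset$labels)
  if (nlevels(labels) < 2) {
    stop("training requires at least 2 classes", call. = FALSE)
  }
  shapes <- vapply(dataset$features, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("all sequences must share the same shape", call. = FALSE)
  }
  D <- shapes[2, 1]
  R <- nlevels(labels)
  N <- length(dataset$features)
  y <- as.integer(labels) - 1L

  params <- init_params(D, cfg$hidden_units, R, derive_seed(cfg$seed, 11L))
  perms <- with_seed(derive_seed(cfg$seed, 12L), {
    vapply(seq_len(cfg$max_epochs), function(e) sample.int(N) - 1L,
           integer(N))
  })

  fit <- cpp_bilstm_train(params, features_to_cube(dataset$features), y,
                          cfg$learning_rate, cfg$batch_size,
                          cfg$max_epochs, cfg$patience, cfg$tol, perms)

  structure(list(params = fit$params,
                 label_map = levels(labels),
                 input_channels = D,
                 cfg = cfg,
                 loss_history = as.numeric(fit$loss_history),
                 initial_loss = fit$initial_loss,
                 epochs_run = fit$epochs_run,
                 seed = cfg$seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "trained_model: %d classes, %d hidden units/direction, %d epochs (final loss %.4f)\n",
    length(x$label_map), x$cfg$hidden_units, x$epochs_run,
    utils::tail(x$loss_history, 1)))
  invisible(x)
}
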