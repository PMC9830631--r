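test_that("lstm_step honours the gate algebra", {
  H <- 3; D <- 2
  zero <- list(W = matrix(0, 4 * H, D), U = matrix(0, 4 * H, H),
               b = rep(0, 4 * H))
  st <- lstm_step(c(1, -2), rep(0, H), rep(0, H), zero)
  expect_equal(st$h, rep(0, H))      # o = 0.5, tanh(c) = 0
  expect_equal(st$c, rep(0, H))

  set.seed(5)
  p <- list(W = matrix(rnorm(4 * H * D), 4 * H, D),
            U = matrix(rnorm(4 * H * H), 4 * H, H),
            b = rnorm(4 * H))
  st <- lstm_step(rnorm(D), rnorm(H), rnorm(H), p)
  expect_true(all(abs(st$h) < 1))    # h = o * tanh(c), both bounded
  expect_error(lstm_step(rnorm(D + 1), rnorm(H), rnorm(H), p),
               "shapes")
})

test_that("batched forward equals the per-step recursion oracle", {
  for (seed in 1:5) {
    D <- 2; H <- 2; R <- 3; Tn <- 3
    params <- random_params(D, H, R, seed)
    model <- as_model(params, D, c("a", "b", "c"))
    set.seed(seed + 100)
    x <- matrix(rnorm(Tn * D), Tn, D)
    expect_equal(drop(forward(model, x)), oracle_bilstm_probs(params, x),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # and on a longer sequence with a larger cell
  params <- random_params(3, 8, 4, 99)
  model <- as_model(params, 3, letters[1:4])
  set.seed(1); x <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(drop(forward(model, x)), oracle_bilstm_probs(params, x),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("softmax output is a probability vector; zero weights are uniform", {
  set.seed(2)
  params <- random_params(2, 4, 5, 3, scale = 2)
  model <- as_model(params, 2, letters[1:5])
  p <- forward(model, matrix(rnorm(20), 10, 2))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)

  zero <- lapply(params, function(w) w * 0)
  mz <- as_model(zero, 2, letters[1:5])
  expect_equal(drop(forward(mz, matrix(rnorm(20), 10, 2))),
               rep(1 / 5, 5), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(forward(model, matrix(rnorm(9), 3, 3)), "channel")
})

test_that("reversing the input swaps the two directions' roles", {
  params <- random_params(2, 3, 3, 17)
  mirrored <- params
  mirrored[c("Wf", "Uf", "bf", "Wb", "Ub", "bb")] <-
    params[c("Wb", "Ub", "bb", "Wf", "Uf", "bf")]
  H <- 3
  mirrored$Wfc <- params$Wfc[, c(H + 1:H, 1:H)]  # swap the concat halves
  m1 <- as_model(params, 2, c("x", "y", "z"))
  m2 <- as_model(mirrored, 2, c("x", "y", "z"))
  set.seed(3); x <- matrix(rnorm(24), 12, 2)
  expect_equal(forward(m1, x), forward(m2, x[nrow(x):1, ]),
               tolerance = 1e-12)
})

test_that("predictions equal the probability argmax with low-index ties", {
  set.seed(11)
  for (rep in 1:20) {
    params <- random_params(2, 3, 4, rep, scale = 0.8)
    model <- as_model(params, 2, c("c1", "c2", "c3", "c4"))
    x <- matrix(rnorm(16), 8, 2)
    p <- forward(model, x)
    expect_equal(as.character(predict_bilstm(model, x)),
                 model$label_map[which.max(drop(p))])
  }
  # exact tie breaks to the lowest class index: zero weights give a
  # uniform posterior over all classes
  zero <- lapply(random_params(2, 3, 2, 1), function(w) w * 0)
  mz <- as_model(zero, 2, c("first", "second"))
  expect_equal(as.character(predict_bilstm(mz, matrix(rnorm(10), 5, 2))),
               "first")
})

test_that("training separates a two-frequency toy problem completely", {
  ds <- toy_dataset(n_per_class = 20, len = 50, seed = 4)
  cfg <- net_config(hidden_units = 8, batch_size = 16, max_epochs = 200,
                    patience = 200, seed = 21)
  model <- train_bilstm(ds, cfg)
  acc <- mean(predict(model, ds) == ds$labels)
  expect_equal(acc, 1)
  expect_lte(model$epochs_run, 200)
})

test_that("training is deterministic given the seed", {
  ds <- toy_dataset(n_per_class = 6, len = 30, seed = 4)
  cfg <- net_config(hidden_units = 4, batch_size = 8, max_epochs = 5,
                    patience = 5, seed = 33)
  m1 <- train_bilstm(ds, cfg)
  m2 <- train_bilstm(ds, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("untrained cross-entropy sits at log(R) for balanced classes", {
  set.seed(9)
  features <- lapply(1:30, function(i) matrix(rnorm(20), 20, 1))
  labels <- factor(rep(c("a", "b", "c"), each = 10))
  ds <- structure(list(features = features, labels = labels,
                       frame_rate_hz = 10, duration_s = 2,
                       feature_mode = "time"), class = "csi_dataset")
  cfg <- net_config(hidden_units = 6, max_epochs = 1, patience = 1,
                    seed = 2)
  model <- train_bilstm(ds, cfg)
  expect_equal(model$initial_loss, log(3), tolerance = 0.05)
})

test_that("training rejects degenerate datasets", {
  ds <- toy_dataset(n_per_class = 4, len = 20, seed = 1)
  one <- csibreathe:::dataset_subset(ds, 1:4)
  one$labels <- droplevels(one$labels)
  expect_error(train_bilstm(one, net_config()), "2 classes")
})

test_that("analytic gradients match numerical differentiation", {
  D <- 2; H <- 3; R <- 3; Tn <- 4; B <- 3
  params <- random_params(D, H, R, 6, scale = 0.4)
  set.seed(60)
  X <- array(rnorm(D * B * Tn), dim = c(D, B, Tn))
  y <- c(0L, 2L, 1L)
  g <- csibreathe:::cpp_bilstm_grad(params, X, y)
  loss_at <- function(p) csibreathe:::cpp_bilstm_grad(p, X, y)$loss

  h <- 1e-5
  worst <- 0
  set.seed(61)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(6, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      ana <- g$grads[[nm]][i]
      rel <- abs(num - ana) / max(1e-8, abs(num) + abs(ana))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})
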