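test_that("hampel filter removes isolated spikes and nothing else", {
  x <- rep(1, 30)
  expect_equal(hampel_filter(x, 3), x)           # constant: unchanged
  x[15] <- 100
  y <- hampel_filter(x, 3, 3)
  expect_equal(y[15], 1)
  expect_equal(y[-15], rep(1, 29))
  expect_error(hampel_filter(rep(1, 5), 3), "longer")
  expect_error(hampel_filter(x, 0), "half_window")
})

test_that("hampel filter matches a direct rolling-median oracle", {
  set.seed(31)
  x <- sin(seq(0, 6 * pi, length.out = 80))
  x[c(20, 55)] <- c(8, -7)
  k <- 3; t0 <- 3
  y <- hampel_filter(x, k, t0)
  # direct oracle over the interior samples
  expected <- x
  for (i in (k + 1):(length(x) - k)) {
    w <- x[(i - k):(i + k)]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    if (abs(x[i] - m) > t0 * s) expected[i] <- m
  }
  expect_equal(y, expected, tolerance = 1e-12)
})

test_that("hampel filter is idempotent on despiked series", {
  set.seed(8)
  for (rep in 1:5) {
    x <- sin(seq(0, 4 * pi, length.out = 60)) + rnorm(60, 0, 0.02)
    x[sample(10:50, 2)] <- c(5, -4)
    once <- hampel_filter(x, 3, 3)
    expect_equal(hampel_filter(once, 3, 3), once, tolerance = 1e-12)
  }
})

test_that("spectrum of an on-grid tone peaks exactly on its bin", {
  t <- (0:599) / 10
  s <- exp(2i * pi * 0.25 * t)
  sp <- spectrum_features(s, 10)
  expect_equal(sp$peak_hz, 0.25)
  expect_equal(sp$bin_width_hz, 1 / 60)
})

test_that("one-sided band power satisfies Parseval's identity", {
  set.seed(12)
  for (n in c(600, 601)) {    # even and odd lengths
    s <- complex(real = rnorm(n), imaginary = rnorm(n))
    fs <- 10
    sp <- spectrum_features(s, fs, band_hz = c(fs / n, fs / 2))
    expect_equal(sum(sp$power), sp$total_power, tolerance = 1e-10)
    expect_equal(sp$total_power, mean(Mod(s - mean(s))^2),
                 tolerance = 1e-10)
  }
})

test_that("spectrum band validation catches empty and invalid bands", {
  s <- complex(real = rnorm(100), imaginary = rnorm(100))
  expect_error(spectrum_features(s, 10, band_hz = c(0.5, 0.4)),
               "increasing")
  expect_error(spectrum_features(s, 10, band_hz = c(0.2, 6)), "band_hz")
  expect_error(spectrum_features(s[1], 10), "samples")
})

test_that("standardize gives zero mean, unit sd, and is idempotent", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  x <- matrix(rnorm(200), 50, 4)
  z1 <- standardize(x)
  expect_equal(standardize(z1), z1, tolerance = 1e-9)
  expect_equal(unname(colMeans(z1)), rep(0, 4), tolerance = 1e-12)
  # constant channels map to zeros rather than NaN
  expect_equal(standardize(matrix(c(5, 5, 5), ncol = 1)),
               matrix(0, 3, 1))
  expect_error(standardize(numeric()), "empty")
  expect_error(standardize(matrix(1, 1, 1)), "samples")
})

test_that("build_dataset preserves counts, labels and ordering", {
  cc <- channel_config(n_subcarriers = 4, duration_s = 15)
  t1 <- simulate_csi(breathing_pattern(2), cc, noise_config(seed = 1),
                     label = "slow")
  t2 <- simulate_csi(breathing_pattern(7), cc, noise_config(seed = 2),
                     label = "fast")
  ds <- build_dataset(list(t1, t2), feature_mode = "spectrum")
  expect_s3_class(ds, "csi_dataset")
  expect_length(ds$features, 2 * 6 * 4)
  expect_equal(as.vector(table(ds$labels)), c(24, 24))
  # one sequence per stream, in stream order, labels matching the source
  expect_equal(as.character(ds$labels),
               rep(c("slow", "fast"), each = 24))
  # deterministic: rebuilding gives identical features
  ds2 <- build_dataset(list(t1, t2), feature_mode = "spectrum")
  expect_identical(ds$features, ds2$features)
  # every sequence standardized per channel
  mus <- vapply(ds$features, function(f) mean(f[, 1]), numeric(1))
  sds <- vapply(ds$features, function(f) sd(f[, 1]), numeric(1))
  expect_true(all(abs(mus) < 1e-9))
  expect_true(all(abs(sds - 1) < 1e-6))
})

test_that("feature modes produce the documented shapes", {
  cc <- channel_config(n_subcarriers = 2, duration_s = 15)
  tens <- simulate_csi(breathing_pattern(6), cc, noise_config(seed = 3))
  n_frames <- 150
  ds_t <- build_dataset(list(tens), feature_mode = "time")
  expect_equal(dim(ds_t$features[[1]]), c(n_frames, 2))
  ds_s <- build_dataset(list(tens), feature_mode = "spectrum",
                        band_hz = c(0.03, 1.05))
  n_bins <- nrow(ds_s$features[[1]])
  expect_equal(ncol(ds_s$features[[1]]), 1)
  ds_h <- build_dataset(list(tens), feature_mode = "hybrid",
                        band_hz = c(0.03, 1.05))
  expect_equal(dim(ds_h$features[[1]]), c(n_frames + n_bins, 3))
})

test_that("build_dataset validates its inputs", {
  expect_length(build_dataset(list())$features, 0)
  cc1 <- channel_config(n_subcarriers = 2, duration_s = 15)
  cc2 <- channel_config(n_subcarriers = 2, duration_s = 30)
  t1 <- simulate_csi(breathing_pattern(1), cc1, noise_config(seed = 1))
  t2 <- simulate_csi(breathing_pattern(1), cc2, noise_config(seed = 1))
  expect_error(build_dataset(list(t1, t2)), "share")
})
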