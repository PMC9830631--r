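#' Hampel outlier filter
#'
#' Replaces samples that deviate from the rolling median by more than
#' `n_sigmas` scaled median absolute deviations with the rolling median,
#' leaving all other samples untouched. A standard despiking step for CSI
#' amplitude; it is exposed as an optional operator and is off by default in
#' the main pipeline, which works on complex values in the frequency
#' domain. Delegates to [pracma::hampel()]; the first and last
#' `half_window` samples are outside any full window and are returned
#' unchanged.
#'
#' @param series Real-valued numeric vector.
#' @param half_window Half-width of the rolling window, samples (>= 1).
#' @param n_sigmas Rejection threshold in scaled MADs (default 3).
#' @return Filtered numeric vector, same length as `series`.
#' @examples
#' x <- rep(1, 20); x[10] <- 100
#' hampel_filter(x, half_window = 3)[10]  # 1
#' @export
hampel_filter <- function(series, half_window, n_sigmas = 3) {
  if (!is.numeric(series)) stop("series must be numeric", call. = FALSE)
  if (half_window < 1) stop("half_window must be >= 1", call. = FALSE)
  if (length(series) <= 2 * half_window) {
    stop("series must be longer than 2 * half_window", call. = FALSE)
  }
  pracma::hampel(series, k = as.integer(half_window), t0 = n_sigmas)$y
}

#' Band-limited power spectrum and peak frequency of a CSI stream
#'
#' Demeans the (complex) stream, takes a full-length FFT with a rectangular
#' window (no zero padding: the bin width `frame_rate / n` is the frequency
#' resolution the acquisition length buys), folds the two-sided spectrum
#' into one-sided power, and reports the bins inside the requested band plus
#' the in-band peak frequency. For a breathing-modulated stream the peak
#' sits at the respiratory rate in Hz (`BPM / 60`).
#'
#' @param stream Complex (or real) vector: one CSI stream across frames.
#' @param frame_rate_hz Sampling rate, Hz.
#' @param band_hz Length-2 numeric `(low, high)` inside
#'   `(0, frame_rate_hz / 2]`; default `c(0.03, 0.7)` covers 3--30 breaths
#'   per minute with margin.
#' @return A list: `freq_hz` and `power` (in-band bins), `peak_hz` (argmax
#'   bin frequency), `bin_width_hz`, and `total_power` (variance of the
#'   demeaned stream, for Parseval checks).
#' @export
spectrum_features <- function(stream, frame_rate_hz,
                              band_hz = c(0.03, 0.7)) {
  n <- length(stream)
  if (n < 2) stop("stream must have at least 2 samples", call. = FALSE)
  if (length(band_hz) != 2 || band_hz[1] >= band_hz[2] ||
      band_hz[1] < 0 || band_hz[2] > frame_rate_hz / 2 + 1e-12) {
    stop("band_hz must be an increasing pair inside (0, frame_rate/2]",
         call. = FALSE)
  }
  x <- stream - mean(stream)
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2                      # two-sided power per bin
  half <- n %/% 2
  k <- seq_len(half)                        # positive-frequency bins
  power <- p2[k + 1L] + ifelse(k < n - k, p2[n - k + 1L], 0)
  if (n %% 2 == 0) power[half] <- p2[half + 1L]   # Nyquist bin, unpaired
  freq <- k * frame_rate_hz / n
  in_band <- freq >= band_hz[1] - 1e-12 & freq <= band_hz[2] + 1e-12
  if (!any(in_band)) {
    stop("band contains no FFT bins at this resolution", call. = FALSE)
  }
  fb <- freq[in_band]
  pb <- power[in_band]
  list(freq_hz = fb, power = pb,
       peak_hz = fb[which.max(pb)],
       bin_width_hz = frame_rate_hz / n,
       total_power = sum(p2) )
}

#' Standardize feature channels to zero mean and unit standard deviation
#'
#' Column-wise standardization of a feature matrix. Constant channels (zero
#' standard deviation) are mapped to all-zeros rather than dividing by zero.
#' The operation is idempotent to numerical precision.
#'
#' @param features Numeric matrix `[n_steps, n_channels]` or vector.
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(features) {
  if (length(features) == 0) stop("empty input", call. = FALSE)
  x <- as.matrix(features)
  if (nrow(x) < 2) stop("need at least 2 samples per channel", call. = FALSE)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  out <- sweep(x, 2, mu)
  keep <- sdv > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2, sdv[keep], "/")
  out[, !keep] <- 0
  out
}

# Feature matrix for one complex stream. Modes:
#   time:     [n_frames x 2]  standardized Re / Im channels
#   spectrum: [n_bins  x 1]   standardized log-power bins in the band
#   hybrid:   [(n_frames + n_bins) x 3] block-stacked: time rows carry
#             (Re, Im, 0), spectrum rows carry (0, 0, log-power)
# Log compression of the power bins bounds their dynamic range (a breathing
# peak can sit orders of magnitude above the noise floor); the floor is a
# fixed fraction of the per-stream median so the transform is invariant to
# the overall signal scale, and standardization then removes the offset.
.stream_features <- function(stream, frame_rate_hz, feature_mode, band_hz) {
  if (feature_mode %in% c("spectrum", "hybrid")) {
    sp <- spectrum_features(stream, frame_rate_hz, band_hz)
    floor_p <- 1e-3 * stats::median(sp$power)
    lp <- if (floor_p > 0) log(sp$power + floor_p) else sp$power
    spec <- standardize(matrix(lp, ncol = 1))
  }
  if (feature_mode %in% c("time", "hybrid")) {
    tim <- standardize(cbind(Re(stream), Im(stream)))
  }
  switch(feature_mode,
    time = tim,
    spectrum = spec,
    hybrid = rbind(cbind(tim, 0),
                   cbind(0, 0, spec)),
    stop("unknown feature_mode: ", feature_mode, call. = FALSE))
}

#' Assemble a labelled feature dataset from CSI tensors
#'
#' Flattens every tensor into its CSI streams (in the fixed stream order)
#' and converts each stream into one feature sequence, preserving per-class
#' stream counts and a deterministic ordering. Three feature modes are
#' supported: `"time"` (2-channel Re/Im time series), `"spectrum"`
#' (band-limited power-spectrum bins) and `"hybrid"` (both, block-stacked
#' into a 3-channel sequence). Every sequence is standardized per channel.
#'
#' @param tensors List of `csi_tensor` objects sharing frame rate and
#'   duration; each contributes `n_rx * n_tx * n_subcarriers` sequences
#'   labelled with the tensor's label.
#' @param feature_mode `"hybrid"` (default), `"time"` or `"spectrum"`.
#' @param band_hz Spectral feature band, Hz. The default `c(0.03, 1.05)`
#'   keeps the fundamental of every 3--30 BPM rate and the second harmonic
#'   of the fastest pattern, which carries the waveform-shape signature that
#'   separates patterns sharing a rate.
#' @return An object of class `csi_dataset`: list with `features` (list of
#'   matrices, equal dimensions), `labels` (factor), `frame_rate_hz`,
#'   `duration_s`, `feature_mode`.
#' @export
build_dataset <- function(tensors, feature_mode = c("hybrid", "time",
                                                    "spectrum"),
                          band_hz = c(0.03, 1.05)) {
  feature_mode <- match.arg(feature_mode)
  if (length(tensors) == 0) {
    return(structure(list(features = list(), labels = factor(character()),
                          frame_rate_hz = NA_real_, duration_s = NA_real_,
                          feature_mode = feature_mode),
                     class = "csi_dataset"))
  }
  stopifnot(all(vapply(tensors, inherits, logical(1), "csi_tensor")))
  frs <- vapply(tensors, function(x) x$meta$channel$frame_rate_hz, numeric(1))
  durs <- vapply(tensors, function(x) x$meta$channel$duration_s, numeric(1))
  if (length(unique(frs)) != 1 || length(unique(durs)) != 1) {
    stop("all tensors must share frame rate and duration", call. = FALSE)
  }
  features <- list()
  labels <- character()
  for (tensor in tensors) {
    h <- csi_streams(tensor)
    lab <- format(tensor$meta$label)
    for (m in seq_len(nrow(h))) {
      features[[length(features) + 1L]] <-
        .stream_features(h[m, ], frs[1], feature_mode, band_hz)
    }
    labels <- c(labels, rep(lab, nrow(h)))
  }
  structure(list(features = features, labels = factor(labels),
                 frame_rate_hz = frs[1], duration_s = durs[1],
                 feature_mode = feature_mode),
            class = "csi_dataset")
}

#' @export
print.csi_dataset <- function(x, ...) {
  cat(sprintf("csi_dataset: %d sequences, %d classes, mode '%s'\n",
              length(x$features), nlevels(x$labels), x$feature_mode))
  if (length(x$features)) {
    d <- dim(x$features[[1]])
    cat(sprintf("  sequence shape: %d steps x %d channels\n", d[1], d[2]))
  }
  invisible(x)
}

# Subset a csi_dataset by sequence indices.
dataset_subset <- function(dataset, idx) {
  structure(list(features = dataset$features[idx],
                 labels = factor(dataset$labels[idx],
                                 levels = levels(dataset$labels)),
                 frame_rate_hz = dataset$frame_rate_hz,
                 duration_s = dataset$duration_s,
                 feature_mode = dataset$feature_mode),
            class = "csi_dataset")
}
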