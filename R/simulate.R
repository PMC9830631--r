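#' Simulate a breathing-modulated CSI tensor
#'
#' Generates the complex 4-D CSI tensor `[n_rx, n_tx, n_subcarriers,
#' n_frames]` of a MIMO-OFDM link observing a breathing subject. For every
#' antenna pair the channel is a sum of multipath components: a unit-scale
#' line-of-sight path, optional static clutter reflections, and one
#' reflection off the chest whose delay is modulated by the round-trip
#' displacement, `tau(t) = tau0 + 2 d(t) / c`. The transmitted pilot is
#' taken as 1 on every subcarrier, so the reported CSI equals the channel
#' gain plus receiver noise. Path gains and delays are drawn per antenna
#' pair from the seeded RNG, and the result is bit-reproducible given
#' (pattern, configs, seed).
#'
#' @param pattern A [breathing_pattern()].
#' @param channel_cfg A [channel_config()].
#' @param noise_cfg A [noise_config()]; its `seed` drives the waveform
#'   jitter, the multipath draws and the noise.
#' @param label Class label stored with the tensor (defaults to the pattern
#'   id).
#' @return An object of class `csi_tensor`: complex array `values` plus the
#'   generating configuration in `meta`.
#' @examples
#' tens <- simulate_csi(breathing_pattern("normal"),
#'                      channel_config(n_subcarriers = 8, duration_s = 15),
#'                      noise_config(seed = 7))
#' dim(tens$values)  # 3 x 2 x 8 x 150
#' @export
simulate_csi <- function(pattern, channel_cfg = channel_config(),
                         noise_cfg = noise_config(), label = NULL) {
  stopifnot(inherits(pattern, "breathing_pattern"),
            inherits(channel_cfg, "channel_config"),
            inherits(noise_cfg, "noise_config"))
  fr <- channel_cfg$frame_rate_hz
  dur <- channel_cfg$duration_s
  n_frames <- as.integer(round(fr * dur))
  seed <- noise_cfg$seed

  disp_mm <- breathing_waveform(pattern, fr, dur,
                                seed = derive_seed(seed, 1L))
  # round-trip extra delay of the chest reflection, seconds
  dtau <- 2 * (disp_mm / 1000) / SPEED_OF_LIGHT

  f_sc <- subcarrier_frequencies(channel_cfg)
  n_rx <- channel_cfg$n_rx
  n_tx <- channel_cfg$n_tx
  n_sc <- channel_cfg$n_subcarriers
  tau_base <- channel_cfg$baseline_distance_m / SPEED_OF_LIGHT

  values <- with_seed(derive_seed(seed, 2L), {
    vals <- array(0i, dim = c(n_rx, n_tx, n_sc, n_frames))
    for (tx in seq_len(n_tx)) for (rx in seq_len(n_rx)) {
      # static components: line of sight plus clutter
      static_h <- complex(n_sc)
      for (l in seq_len(channel_cfg$n_static_paths)) {
        if (l == 1L) {        # line of sight
          g <- stats::runif(1, 0.9, 1.1) *
            exp(2i * pi * stats::runif(1))
          d <- tau_base
        } else {              # clutter reflection
          g <- 0.2 * stats::runif(1, 0.5, 1.5) *
            exp(2i * pi * stats::runif(1))
          d <- tau_base + stats::runif(1, 10e-9, 50e-9)
        }
        static_h <- static_h + g * exp(-2i * pi * f_sc * d)
      }
      # breathing-modulated reflection
      gb <- channel_cfg$breathing_gain * stats::runif(1, 0.8, 1.2) *
        exp(2i * pi * stats::runif(1))
      tau_b <- tau_base + stats::runif(1, 5e-9, 20e-9) + dtau  # length n_frames
      # n_sc x n_frames phase matrix of the moving path
      breathing_h <- gb * exp(-2i * pi * outer(f_sc, tau_b))
      vals[rx, tx, , ] <- static_h + breathing_h
    }
    vals
  })

  tensor <- structure(list(
    values = values,
    meta = list(pattern = pattern, channel = channel_cfg, noise = noise_cfg,
                label = label %||% pattern$pattern_id, seed = seed)
  ), class = "csi_tensor")

  apply_noise_and_agc(tensor, noise_cfg, channel_cfg$added_attenuation_db)
}

#' @export
print.csi_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "csi_tensor: %d rx x %d tx x %d subcarriers x %d frames (label %s)\n",
    d[1], d[2], d[3], d[4], format(x$meta$label)))
  invisible(x)
}

#' Attenuate a CSI tensor, add receiver noise and optionally emulate AGC
#'
#' Scales the signal by `10^(-att / 20)` against a fixed complex Gaussian
#' noise floor, so added attenuation lowers the SNR one-for-one. If AGC is
#' enabled, each stream is rescaled so its mean amplitude equals the AGC
#' target, reproducing the receiver behaviour in which reported CSI
#' amplitude is independent of attenuation (and which masks the absence of
#' motion).
#'
#' @param tensor A `csi_tensor`.
#' @param noise_cfg A [noise_config()].
#' @param added_attenuation_db Added attenuation in dB; either a scalar or a
#'   vector with one value per stream (rx fastest, then tx, then
#'   subcarrier) for mixed-attenuation datasets.
#' @return The modified `csi_tensor`.
#' @export
apply_noise_and_agc <- function(tensor, noise_cfg,
                                added_attenuation_db = 0) {
  stopifnot(inherits(tensor, "csi_tensor"), inherits(noise_cfg, "noise_config"))
  if (noise_cfg$noise_power < 0) {
    stop("noise_power must be >= 0", call. = FALSE)
  }
  if (any(added_attenuation_db < 0)) {
    stop("added_attenuation_db must be >= 0", call. = FALSE)
  }
  d <- dim(tensor$values)
  n_streams <- prod(d[1:3])
  n_frames <- d[4]
  att <- added_attenuation_db
  if (!length(att) %in% c(1L, n_streams)) {
    stop("added_attenuation_db must have length 1 or one value per stream",
         call. = FALSE)
  }

  h <- matrix(tensor$values, nrow = n_streams)   # streams x frames
  h <- h * 10^(-att / 20)                        # recycles per stream
  if (noise_cfg$noise_power > 0) {
    sd1 <- sqrt(noise_cfg$noise_power / 2)
    noise <- with_seed(derive_seed(noise_cfg$seed, 3L), {
      matrix(complex(real = stats::rnorm(n_streams * n_frames, 0, sd1),
                     imaginary = stats::rnorm(n_streams * n_frames, 0, sd1)),
             nrow = n_streams)
    })
    h <- h + noise
  }
  if (noise_cfg$agc_enabled) {
    mean_amp <- rowMeans(Mod(h))
    scl <- ifelse(mean_amp > 0, noise_cfg$agc_target_amplitude / mean_amp, 1)
    h <- h * scl
  }
  tensor$values <- array(h, dim = d)
  tensor$meta$noise <- noise_cfg
  tensor$meta$applied_attenuation_db <- att
  tensor
}

#' Flatten a CSI tensor into its labelled streams
#'
#' Returns the stream matrix `H = [h_1, ..., h_M]` with one row per CSI data
#' stream and one column per frame. The stream index `m` enumerates
#' (rx, tx, subcarrier) triples with the receive antenna varying fastest,
#' then the transmit antenna, then the subcarrier — a fixed, documented
#' order, so the default 3 rx x 2 tx x 56 subcarrier plan yields 336
#' streams.
#'
#' @param tensor A `csi_tensor`.
#' @return Complex matrix `[n_streams, n_frames]` with attribute `label`.
#' @export
csi_streams <- function(tensor) {
  stopifnot(inherits(tensor, "csi_tensor"))
  d <- dim(tensor$values)
  m <- matrix(tensor$values, nrow = prod(d[1:3]))
  attr(m, "label") <- tensor$meta$label
  m
}
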