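SPEED_OF_LIGHT <- 299792458

#' MIMO-OFDM channel configuration
#'
#' Geometry and sampling plan of the simulated Wi-Fi link: a 20 MHz
#' 802.11n-style channel with 56 subcarriers at 312.5 kHz spacing placed
#' symmetrically about the centre frequency (DC tone skipped), a small set of
#' static multipath components plus one breathing-modulated reflection, and
#' the frame rate / acquisition duration that sample each CSI stream.
#'
#' @param center_freq_hz Carrier centre frequency in Hz (default 5280 MHz).
#' @param n_subcarriers Number of OFDM subcarriers (default 56).
#' @param subcarrier_spacing_hz Tone spacing in Hz (default 312 500).
#' @param n_tx,n_rx Transmit / receive antenna counts (defaults 2 and 3; the
#'   third transmit chain is supported but off by default).
#' @param n_static_paths Static multipath components per antenna pair in
#'   addition to the breathing reflection (default 2: a line-of-sight path
#'   and one clutter reflection).
#' @param breathing_gain Nominal complex-gain magnitude of the
#'   breathing-modulated reflection relative to the unit line-of-sight path.
#' @param added_attenuation_db Extra path attenuation inserted on the link,
#'   dB (0--33 in the characterization sweeps).
#' @param frame_rate_hz Wi-Fi frame (CSI sampling) rate, Hz.
#' @param duration_s Acquisition length, s; `frame_rate_hz * duration_s`
#'   must be an integer.
#' @param baseline_distance_m Physical transmitter--receiver distance at
#'   0 dB added attenuation (default 2.30 m).
#' @return An object of class `channel_config`.
#' @export
channel_config <- function(center_freq_hz = 5.28e9,
                           n_subcarriers = 56L,
                           subcarrier_spacing_hz = 312500,
                           n_tx = 2L, n_rx = 3L,
                           n_static_paths = 2L,
                           breathing_gain = 0.3,
                           added_attenuation_db = 0,
                           frame_rate_hz = 10,
                           duration_s = 60,
                           baseline_distance_m = 2.30) {
  if (n_subcarriers < 1) stop("n_subcarriers must be >= 1", call. = FALSE)
  if (added_attenuation_db < 0) {
    stop("added_attenuation_db must be >= 0", call. = FALSE)
  }
  n_frames <- frame_rate_hz * duration_s
  if (n_frames <= 0 || abs(n_frames - round(n_frames)) > 1e-8) {
    stop("frame_rate_hz * duration_s must be a positive integer",
         call. = FALSE)
  }
  structure(list(
    center_freq_hz = center_freq_hz,
    n_subcarriers = as.integer(n_subcarriers),
    subcarrier_spacing_hz = subcarrier_spacing_hz,
    n_tx = as.integer(n_tx), n_rx = as.integer(n_rx),
    n_static_paths = as.integer(n_static_paths),
    breathing_gain = breathing_gain,
    added_attenuation_db = added_attenuation_db,
    frame_rate_hz = frame_rate_hz,
    duration_s = duration_s,
    baseline_distance_m = baseline_distance_m
  ), class = "channel_config")
}

#' Receiver noise and gain-control configuration
#'
#' @param noise_power Linear variance of the complex additive white Gaussian
#'   noise per CSI sample. The default `1.13e-3` places the clean link
#'   (0 dB added attenuation, total mean signal power about 1.13 with the
#'   default path gains) at roughly 30 dB SNR; added attenuation scales the
#'   signal down against this fixed noise floor.
#' @param agc_enabled Emulate receiver automatic gain control: every stream
#'   is rescaled so its mean amplitude equals `agc_target_amplitude`,
#'   making the reported amplitude independent of attenuation.
#' @param agc_target_amplitude Amplitude the emulated AGC normalizes to.
#' @param seed RNG seed for multipath draws and noise.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(noise_power = 1.13e-3,
                         agc_enabled = FALSE,
                         agc_target_amplitude = 1,
                         seed = 1L) {
  if (noise_power < 0) stop("noise_power must be >= 0", call. = FALSE)
  structure(list(noise_power = noise_power,
                 agc_enabled = isTRUE(agc_enabled),
                 agc_target_amplitude = agc_target_amplitude,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Subcarrier centre frequencies of a channel plan
#'
#' 56 tones at the configured spacing, symmetric about the centre frequency
#' with the DC tone skipped (indices -28..-1, 1..28 for the default plan).
#'
#' @param cfg A [channel_config()].
#' @return Numeric vector of length `cfg$n_subcarriers`, Hz.
#' @export
subcarrier_frequencies <- function(cfg) {
  n <- cfg$n_subcarriers
  half <- ceiling(n / 2)
  k <- setdiff(seq.int(-half, half), 0L)[seq_len(n)]
  cfg$center_freq_hz + k * cfg$subcarrier_spacing_hz
}

#' Multipath channel gain at one frequency and time
#'
#' Sums the complex contributions of all propagation paths,
#' `h(f, t) = sum_l xi_l exp(-1i 2 pi f tau_l)`: each path is a complex gain
#' and a delay whose phase rotates with frequency. With constant gains and
#' delays the channel is time-invariant; time variation enters through
#' time-varying delays (the breathing reflection).
#'
#' @param f Subcarrier frequency, Hz (vectorized).
#' @param t Time, s (accepted for interface symmetry; constant paths do not
#'   depend on it).
#' @param paths List of paths, each `list(gain = <complex>, delay = <s>)`.
#' @return Complex gain(s), one per element of `f`.
#' @examples
#' channel_gain(5.28e9, 0, list(list(gain = 1 + 0i, delay = 0)))  # 1+0i
#' @export
channel_gain <- function(f, t = 0, paths) {
  if (length(paths) == 0) stop("paths must be non-empty", call. = FALSE)
  delays <- vapply(paths, function(p) p$delay, numeric(1))
  if (any(delays < 0)) stop("path delays must be >= 0", call. = FALSE)
  gains <- vapply(paths, function(p) as.complex(p$gain), complex(1))
  h <- complex(length(f))
  for (l in seq_along(paths)) {
    h <- h + gains[l] * exp(-2i * pi * f * delays[l])
  }
  h
}

#' Free-space path loss
#'
#' `FSPL(d, f) = (4 pi d f / c)^2`, returned in dB:
#' `20 log10(4 pi d f / c)`. Monotone increasing in both distance and
#' frequency; +20 dB per decade of distance.
#'
#' @param distance_m Transmitter--receiver distance, m (> 0).
#' @param freq_hz Signal frequency, Hz (> 0).
#' @return Path loss in dB.
#' @examples
#' round(fspl_db(2.30, 5.28e9))   # 54
#' round(fspl_db(23.00, 5.28e9))  # 74
#' @export
fspl_db <- function(distance_m, freq_hz = 5.28e9) {
  if (any(distance_m <= 0) || any(freq_hz <= 0)) {
    stop("distance_m and freq_hz must be positive", call. = FALSE)
  }
  20 * log10(4 * pi * distance_m * freq_hz / SPEED_OF_LIGHT)
}

#' Equivalent distance of an added attenuation
#'
#' Under free-space propagation, adding `A` dB of path loss is equivalent to
#' multiplying the distance by `10^(A / 20)`; with the 2.30 m baseline, 20 dB
#' corresponds to 23.00 m and 30 dB to about 72.7 m.
#'
#' @param added_att_db Added attenuation, dB.
#' @param baseline_m Baseline distance at 0 dB, m (> 0).
#' @return Equivalent distance, m.
#' @export
attenuation_to_distance <- function(added_att_db, baseline_m = 2.30) {
  if (any(baseline_m <= 0)) stop("baseline_m must be positive", call. = FALSE)
  baseline_m * 10^(added_att_db / 20)
}
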