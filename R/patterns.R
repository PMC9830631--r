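#' Catalog of respiratory motion patterns
#'
#' Nine parametric breathing patterns spanning bradypnea (6 BPM) to tachypnea
#' (28 BPM) and shallow (171 mL) to deep (705 mL) tidal volumes, as produced
#' by a calibrated breathing simulator. Each pattern couples a printed
#' (rate, tidal volume) pair with a waveform shape: an asymmetric
#' inspiration/expiration pulse plus up to three harmonics, and small
#' per-breath amplitude/period jitter. Pattern #6 (15 BPM, 587 mL) lies in
#' the eupnea band (12--20 BPM) and is the "normal" pattern; the other eight
#' are the abnormal class in the binary task.
#'
#' @format A list of 9 [breathing_pattern()] objects, indexed by pattern id.
#' @keywords internal
#' @noRd
.pattern_table <- list(
  list(id = 1L, bpm = 25L, tv = 319, insp = 0.40, harm = c(0.10, 0.02, 0.00),
       ajit = 0.05, rjit = 0.03),
  list(id = 2L, bpm = 6L,  tv = 705, insp = 0.30, harm = c(0.30, 0.12, 0.05),
       ajit = 0.06, rjit = 0.04),
  list(id = 3L, bpm = 18L, tv = 488, insp = 0.35, harm = c(0.30, 0.08, 0.00),
       ajit = 0.05, rjit = 0.03),
  list(id = 4L, bpm = 18L, tv = 171, insp = 0.50, harm = c(0.05, 0.00, 0.00),
       ajit = 0.04, rjit = 0.02),
  list(id = 5L, bpm = 22L, tv = 651, insp = 0.45, harm = c(0.18, 0.25, 0.00),
       ajit = 0.06, rjit = 0.03),
  list(id = 6L, bpm = 15L, tv = 587, insp = 0.40, harm = c(0.15, 0.05, 0.00),
       ajit = 0.04, rjit = 0.03),
  list(id = 7L, bpm = 28L, tv = 442, insp = 0.50, harm = c(0.25, 0.00, 0.10),
       ajit = 0.07, rjit = 0.04),
  list(id = 8L, bpm = 19L, tv = 513, insp = 0.40, harm = c(0.10, 0.25, 0.08),
       ajit = 0.05, rjit = 0.03),
  list(id = 9L, bpm = 25L, tv = 463, insp = 0.55, harm = c(0.30, 0.15, 0.10),
       ajit = 0.06, rjit = 0.04)
)

#' Construct a breathing pattern
#'
#' A `breathing_pattern` describes one periodic respiratory motion: its rate
#' in breaths per minute, maximum tidal volume in millilitres (which sets the
#' chest-wall excursion), the fraction of each cycle spent on inspiration,
#' relative amplitudes of waveform harmonics (the pattern "shape"), and
#' relative per-breath amplitude/period jitter.
#'
#' @param pattern_id Integer 1--9 selecting a catalogued pattern, or the
#'   string `"normal"` (an alias for pattern #6, the eupnea pattern at
#'   15 BPM). Catalogued fields can be overridden with the other arguments.
#' @param rate_bpm Breathing rate, breaths per minute (3--30).
#' @param max_tidal_volume_ml Maximum tidal volume in mL (> 0).
#' @param inspiration_fraction Fraction of the breath cycle spent inhaling,
#'   in (0, 1).
#' @param harmonic_weights Numeric vector of relative amplitudes of harmonics
#'   2, 3, ... of the fundamental; the asymmetric base pulse carries the
#'   fundamental.
#' @param amplitude_jitter Relative standard deviation of per-breath
#'   amplitude (>= 0).
#' @param rate_jitter Relative standard deviation of per-breath period
#'   (>= 0).
#' @return An object of class `breathing_pattern`.
#' @examples
#' breathing_pattern(2)                      # 6 BPM, 705 mL
#' breathing_pattern("normal")               # pattern #6, 15 BPM
#' breathing_pattern("normal", rate_bpm = 12, rate_jitter = 0)
#' @export
breathing_pattern <- function(pattern_id = "normal",
                              rate_bpm = NULL,
                              max_tidal_volume_ml = NULL,
                              inspiration_fraction = NULL,
                              harmonic_weights = NULL,
                              amplitude_jitter = NULL,
                              rate_jitter = NULL) {
  if (identical(pattern_id, "normal")) pattern_id <- 6L
  if (!is.numeric(pattern_id) || length(pattern_id) != 1L ||
      !(pattern_id %in% 1:9)) {
    stop("`pattern_id` must be an integer 1-9 or \"normal\"",
         call. = FALSE)
  }
  base <- .pattern_table[[as.integer(pattern_id)]]
  p <- structure(list(
    pattern_id = base$id,
    rate_bpm = if (is.null(rate_bpm)) base$bpm else as.integer(rate_bpm),
    max_tidal_volume_ml =
      if (is.null(max_tidal_volume_ml)) base$tv else max_tidal_volume_ml,
    inspiration_fraction =
      if (is.null(inspiration_fraction)) base$insp else inspiration_fraction,
    harmonic_weights =
      if (is.null(harmonic_weights)) base$harm else harmonic_weights,
    amplitude_jitter =
      if (is.null(amplitude_jitter)) base$ajit else amplitude_jitter,
    rate_jitter = if (is.null(rate_jitter)) base$rjit else rate_jitter
  ), class = "breathing_pattern")
  validate_breathing_pattern(p)
}

validate_breathing_pattern <- function(p) {
  stopifnot(inherits(p, "breathing_pattern"))
  if (p$rate_bpm < 3 || p$rate_bpm > 30) {
    stop("rate_bpm must lie in [3, 30]", call. = FALSE)
  }
  if (p$max_tidal_volume_ml < 0) {
    stop("max_tidal_volume_ml must be >= 0", call. = FALSE)
  }
  if (p$inspiration_fraction <= 0 || p$inspiration_fraction >= 1) {
    stop("inspiration_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (p$amplitude_jitter < 0 || p$rate_jitter < 0) {
    stop("jitter parameters must be >= 0", call. = FALSE)
  }
  p
}

#' @export
print.breathing_pattern <- function(x, ...) {
  cat(sprintf(
    "breathing_pattern #%d: %d BPM, %.0f mL, inspiration fraction %.2f\n",
    x$pattern_id, x$rate_bpm, x$max_tidal_volume_ml, x$inspiration_fraction))
  invisible(x)
}

# Asymmetric unit breath pulse on cycle phase u in [0, 1): rises 0 -> 1 over
# the inspiration fraction, falls 1 -> 0 over expiration. Raised-cosine in
# each segment so the motion is smooth at the turning points.
.breath_pulse <- function(u, insp) {
  ifelse(u < insp,
         0.5 * (1 - cos(pi * u / insp)),
         0.5 * (1 + cos(pi * (u - insp) / (1 - insp))))
}

# Shape on cycle phase u: base pulse (fundamental + its natural harmonics)
# plus explicit extra harmonics. Not normalized.
.breath_shape <- function(u, insp, harm) {
  s <- .breath_pulse(u, insp)
  for (k in seq_along(harm)) {
    if (harm[k] != 0) s <- s + harm[k] * cos(2 * pi * (k + 1) * u)
  }
  s
}

#' Chest displacement time series for a breathing pattern
#'
#' Generates the chest-wall displacement (mm) sampled at the Wi-Fi frame
#' rate. The waveform is periodic at `rate_bpm / 60` Hz (up to per-breath
#' period jitter) and its peak-to-peak excursion is proportional to the
#' maximum tidal volume through a documented linear gain: by default 1 mm of
#' peak-to-peak chest displacement per 100 mL of tidal volume (705 mL is
#' about 7 mm), the physiological order of magnitude of chest-wall motion.
#'
#' @param pattern A [breathing_pattern()].
#' @param frame_rate_hz Sampling (Wi-Fi frame) rate in Hz (> 0).
#' @param duration_s Acquisition length in seconds (> 0);
#'   `frame_rate_hz * duration_s` must be a whole number of samples.
#' @param seed RNG seed for the per-breath jitters.
#' @param mm_per_100ml Volume-to-displacement gain, mm peak-to-peak per
#'   100 mL (default 1).
#' @return Numeric vector of length `frame_rate_hz * duration_s`:
#'   displacement in mm, zero at end-expiration.
#' @examples
#' d <- breathing_waveform(breathing_pattern(2), 10, 60, seed = 1)
#' length(d)  # 600 samples, 6 breath cycles
#' @export
breathing_waveform <- function(pattern, frame_rate_hz = 10, duration_s = 60,
                               seed = 1L, mm_per_100ml = 1) {
  stopifnot(inherits(pattern, "breathing_pattern"))
  if (frame_rate_hz <= 0 || duration_s <= 0) {
    stop("frame_rate_hz and duration_s must be positive", call. = FALSE)
  }
  n <- frame_rate_hz * duration_s
  if (abs(n - round(n)) > 1e-8) {
    stop("frame_rate_hz * duration_s must be an integer number of samples",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  t <- (seq_len(n) - 1L) / frame_rate_hz

  pp_mm <- pattern$max_tidal_volume_ml / 100 * mm_per_100ml
  if (pp_mm == 0) return(numeric(n))

  period0 <- 60 / pattern$rate_bpm
  jitter_free <- pattern$rate_jitter == 0 && pattern$amplitude_jitter == 0

  if (jitter_free) {
    u <- (t / period0) %% 1
    amp <- rep(1, n)
  } else {
    jit <- with_seed(seed, {
      # enough jittered cycles to cover the acquisition
      n_cyc <- as.integer(ceiling(duration_s / period0 * 2) + 4L)
      list(periods = period0 *
             pmax(0.2, 1 + stats::rnorm(n_cyc, 0, pattern$rate_jitter)),
           amps = pmax(0, 1 + stats::rnorm(n_cyc, 0,
                                           pattern$amplitude_jitter)))
    })
    starts <- c(0, cumsum(jit$periods))
    idx <- findInterval(t, starts)          # cycle index per sample
    u <- (t - starts[idx]) / jit$periods[idx]
    amp <- jit$amps[idx]
  }

  # normalize the jitter-free shape to unit peak-to-peak on a fine grid
  ug <- seq(0, 1, length.out = 2048)
  sg <- .breath_shape(ug, pattern$inspiration_fraction,
                      pattern$harmonic_weights)
  scl <- pp_mm / (max(sg) - min(sg))
  s <- .breath_shape(u, pattern$inspiration_fraction,
                     pattern$harmonic_weights)
  (s - min(sg)) * scl * amp
}
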