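#' Specification of a characterization experiment
#'
#' Describes one study: the classification task, the variable being swept,
#' the dataset scale, and the network configuration. Tasks:
#'
#' * `"pattern-9"` — the nine respiratory patterns as classes;
#' * `"normal-vs-abnormal"` — binary task, the eight non-normal patterns
#'   pooled against an equally sized normal class;
#' * `"rate-28"` — integer rates 3..30 BPM as 28 classes (normal waveform
#'   shape at each rate);
#' * `"rate-3-band"` — the same streams relabelled into the clinical bands
#'   bradypnea (<= 11 BPM), eupnea (12--20) and tachypnea (>= 21).
#'
#' At full scale each class holds 336 streams (3 rx x 2 tx x 56
#' subcarriers from one acquisition), giving 3024 / 5376 / 9408 streams
#' for the pattern / binary / rate datasets. The scaled profile
#' (`scale = "reduced"`) uses 8 subcarriers and 56 streams per class
#' (336 / 6), drawing a second fresh-seed acquisition for the 8 streams
#' beyond the 48 an 8-subcarrier acquisition provides.
#'
#' @param task One of `"pattern-9"`, `"normal-vs-abnormal"`, `"rate-28"`,
#'   `"rate-3-band"`.
#' @param sweep_variable `"none"`, `"attenuation_db"`, `"duration_s"` or
#'   `"frame_rate_hz"`.
#' @param sweep_values Numeric vector of sweep values (ignored for
#'   `"none"`).
#' @param scale `"full"` or `"reduced"`.
#' @param attenuation_db Added attenuation used when it is not the sweep
#'   variable.
#' @param duration_s,frame_rate_hz Acquisition length and frame rate used
#'   when not swept.
#' @param k Cross-validation folds.
#' @param seed Master seed; all stage seeds derive from it.
#' @param cfg A [net_config()] for the classifier.
#' @param feature_mode,band_hz Passed to [build_dataset()]; `band_hz`
#'   defaults to (0.03, 1.05) Hz for pattern tasks (keeps the second
#'   harmonic shape signature) and (0.03, 0.7) Hz for rate tasks (the
#'   3--30 BPM fundamental band).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(task = c("pattern-9", "normal-vs-abnormal",
                                     "rate-28", "rate-3-band"),
                            sweep_variable = c("none", "attenuation_db",
                                               "duration_s",
                                               "frame_rate_hz"),
                            sweep_values = numeric(),
                            scale = c("reduced", "full"),
                            attenuation_db = 0,
                            duration_s = 60, frame_rate_hz = 10,
                            k = 3L, seed = 1L,
                            cfg = net_config(max_epochs = 60L,
                                             patience = 8L),
                            feature_mode = "spectrum",
                            band_hz = NULL) {
  task <- match.arg(task)
  sweep_variable <- match.arg(sweep_variable)
  scale <- match.arg(scale)
  if (sweep_variable != "none" && length(sweep_values) == 0) {
    stop("sweep_values must be non-empty", call. = FALSE)
  }
  if (is.null(band_hz)) {
    band_hz <- if (task %in% c("rate-28", "rate-3-band")) {
      c(0.03, 0.7)
    } else {
      c(0.03, 1.05)
    }
  }
  structure(list(task = task, sweep_variable = sweep_variable,
                 sweep_values = sweep_values, scale = scale,
                 attenuation_db = attenuation_db,
                 duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 k = as.integer(k), seed = as.integer(seed), cfg = cfg,
                 feature_mode = feature_mode, band_hz = band_hz),
            class = "experiment_spec")
}

# Class recipes: list of (pattern constructor args, label) per class, plus
# how many acquisitions per class the scale demands.
.task_classes <- function(task) {
  switch(task,
    "pattern-9" = lapply(1:9, function(i) {
      list(pattern = breathing_pattern(i), label = sprintf("pattern-%d", i))
    }),
    "normal-vs-abnormal" = c(
      lapply(setdiff(1:9, 6L), function(i) {
        list(pattern = breathing_pattern(i), label = "abnormal")
      }),
      lapply(1:8, function(i) {   # 8 fresh-seed normal acquisitions
        list(pattern = breathing_pattern("normal"), label = "normal")
      })),
    "rate-28" = ,
    "rate-3-band" = lapply(3:30, function(bpm) {
      label <- if (task == "rate-28") sprintf("%02d-bpm", bpm) else {
        if (bpm <= 11) "bradypnea" else if (bpm <= 20) "eupnea"
        else "tachypnea"
      }
      list(pattern = breathing_pattern("normal", rate_bpm = bpm),
           label = label)
    }),
    stop("unknown task: ", task, call. = FALSE))
}

# Streams per recipe entry at each scale. normal-vs-abnormal keeps class
# balance: 8 abnormal recipe entries and 8 normal entries, equal streams.
.scale_profile <- function(scale) {
  if (scale == "full") {
    list(n_subcarriers = 56L, streams_per_entry = 336L)
  } else {
    list(n_subcarriers = 8L, streams_per_entry = 56L)
  }
}

#' Dimensions of a study dataset without simulating it
#'
#' Returns the stream bookkeeping a study implies: total streams, streams
#' per class, the label vector, and the smallest test fold of a
#' stratified 10-fold split. At full scale the pattern / binary / rate
#' tasks hold 3024 / 5376 / 9408 streams and the smallest 10-fold test
#' fold of the pattern task has 302.
#'
#' @param spec An [experiment_spec()].
#' @param k Folds used for the fold-size report (default 10).
#' @return List with `n_streams`, `streams_per_class` (named table),
#'   `labels`, `min_fold_size`, `max_fold_size`.
#' @export
study_dimensions <- function(spec, k = 10L) {
  stopifnot(inherits(spec, "experiment_spec"))
  classes <- .task_classes(spec$task)
  prof <- .scale_profile(spec$scale)
  labels <- factor(unlist(lapply(classes, function(cl) {
    rep(cl$label, prof$streams_per_entry)
  })))
  fold <- make_folds(labels, k, seed = spec$seed)
  list(n_streams = length(labels),
       streams_per_class = table(labels),
       labels = labels,
       min_fold_size = min(tabulate(fold, k)),
       max_fold_size = max(tabulate(fold, k)))
}

#' Build the labelled dataset for a study
#'
#' Simulates the CSI tensors each task requires and assembles the feature
#' dataset. Full-scale counts match the published recipes: 3024 streams
#' for the pattern task, 5376 (class-balanced) for the binary task, 9408
#' for the 28-rate task. The frame rate must satisfy the Nyquist guard:
#' at least twice the fastest class's breathing frequency.
#'
#' @param spec An [experiment_spec()].
#' @param attenuation_db,duration_s,frame_rate_hz Optional overrides of
#'   the spec's operating point (used by [run_sweep()]).
#' @return A `csi_dataset`.
#' @export
build_study_dataset <- function(spec,
                                attenuation_db = NULL,
                                duration_s = NULL,
                                frame_rate_hz = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  att <- attenuation_db %||% spec$attenuation_db
  dur <- duration_s %||% spec$duration_s
  fr <- frame_rate_hz %||% spec$frame_rate_hz

  classes <- .task_classes(spec$task)
  max_rate_hz <- max(vapply(classes,
                            function(cl) cl$pattern$rate_bpm, numeric(1))) / 60
  if (fr < 2 * max_rate_hz) {
    stop(sprintf(
      "frame rate %.3g Hz is below the Nyquist rate for the fastest class (%.3g Hz breathing); need >= %.3g Hz",
      fr, max_rate_hz, 2 * max_rate_hz), call. = FALSE)
  }

  prof <- .scale_profile(spec$scale)
  per_acq <- 6L * prof$n_subcarriers           # 3 rx x 2 tx x n_sc streams
  n_acq <- ceiling(prof$streams_per_entry / per_acq)

  tensors <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    for (a in seq_len(n_acq)) {
      ccfg <- channel_config(n_subcarriers = prof$n_subcarriers,
                             added_attenuation_db = att,
                             frame_rate_hz = fr, duration_s = dur)
      ncfg <- noise_config(seed = derive_seed(spec$seed,
                                              1000L * ci + a))
      tensors[[length(tensors) + 1L]] <-
        simulate_csi(cl$pattern, ccfg, ncfg, label = cl$label)
    }
  }
  dataset <- build_dataset(tensors, feature_mode = spec$feature_mode,
                           band_hz = spec$band_hz)
  if (prof$streams_per_entry < per_acq * n_acq) {
    # trim each recipe entry to the exact stream budget, deterministically
    keep <- unlist(lapply(seq_along(classes) - 1L, function(ci) {
      ci * per_acq * n_acq + seq_len(prof$streams_per_entry)
    }))
    dataset <- dataset_subset(dataset, keep)
  }
  dataset$labels <- droplevels(dataset$labels)
  dataset
}

#' Run a characterization sweep
#'
#' Cross-validates the classifier at every value of the swept variable
#' (added attenuation, acquisition length, or frame rate) and returns one
#' metrics row per value: overall accuracy with its dispersion across
#' folds and the macro precision/recall/specificity/F1.
#'
#' @param spec An [experiment_spec()] with a sweep variable.
#' @return A data frame (one row per sweep value) with the per-level
#'   `cv_report`s attached as attribute `"reports"` and the spec as
#'   attribute `"spec"`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  values <- if (spec$sweep_variable == "none") NA_real_ else
    spec$sweep_values
  reports <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (v in seq_along(values)) {
    dataset <- switch(spec$sweep_variable,
      none = build_study_dataset(spec),
      attenuation_db = build_study_dataset(spec,
                                           attenuation_db = values[v]),
      duration_s = build_study_dataset(spec, duration_s = values[v]),
      frame_rate_hz = build_study_dataset(spec,
                                          frame_rate_hz = values[v]))
    cv <- kfold_cross_validate(dataset, k = spec$k,
                               seed = derive_seed(spec$seed, 7L + v),
                               cfg = spec$cfg)
    reports[[v]] <- cv
    rows[[v]] <- data.frame(
      sweep_variable = spec$sweep_variable,
      value = values[v],
      accuracy = cv$mean_accuracy,
      sd = cv$sd_accuracy,
      min = cv$min_accuracy, max = cv$max_accuracy,
      precision = cv$macro["precision"], recall = cv$macro["recall"],
      specificity = cv$macro["specificity"], f1 = cv$macro["f1"],
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  attr(out, "spec") <- spec
  out
}

#' Mixed-attenuation robustness study
#'
#' Builds a single pooled dataset in which every CSI stream is degraded by
#' its own attenuation level drawn uniformly from `levels`, emulating
#' subjects at varying distances, then cross-validates. The pooled
#' accuracy lies between the best and worst fixed-level accuracies.
#'
#' @param spec An [experiment_spec()].
#' @param levels Attenuation levels in dB (>= 2 values unless all equal).
#' @return A `cv_report` with the per-stream levels attached as attribute
#'   `"stream_attenuation_db"`.
#' @export
mixed_attenuation_study <- function(spec, levels = c(0, 10, 20, 30)) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (length(levels) < 1) {
    stop("need at least one attenuation level", call. = FALSE)
  }
  classes <- .task_classes(spec$task)
  prof <- .scale_profile(spec$scale)
  per_acq <- 6L * prof$n_subcarriers
  n_acq <- ceiling(prof$streams_per_entry / per_acq)

  tensors <- list()
  atts <- numeric()
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    for (a in seq_len(n_acq)) {
      ccfg <- channel_config(n_subcarriers = prof$n_subcarriers,
                             added_attenuation_db = 0,
                             frame_rate_hz = spec$frame_rate_hz,
                             duration_s = spec$duration_s)
      ncfg <- noise_config(noise_power = 0,
                           seed = derive_seed(spec$seed, 1000L * ci + a))
      clean <- simulate_csi(cl$pattern, ccfg, ncfg, label = cl$label)
      # per-stream attenuation, then the configured noise floor
      stream_att <- with_seed(derive_seed(spec$seed, 5000L + 1000L * ci + a),
                              sample(levels, per_acq, replace = TRUE))
      noisy_cfg <- noise_config(seed = derive_seed(spec$seed,
                                                   9000L + 1000L * ci + a))
      tensors[[length(tensors) + 1L]] <-
        apply_noise_and_agc(clean, noisy_cfg, stream_att)
      atts <- c(atts, stream_att)
    }
  }
  dataset <- build_dataset(tensors, feature_mode = spec$feature_mode,
                           band_hz = spec$band_hz)
  if (prof$streams_per_entry < per_acq * n_acq) {
    keep <- unlist(lapply(seq_along(classes) - 1L, function(ci) {
      ci * per_acq * n_acq + seq_len(prof$streams_per_entry)
    }))
    dataset <- dataset_subset(dataset, keep)
    atts <- atts[keep]
  }
  dataset$labels <- droplevels(dataset$labels)
  cv <- kfold_cross_validate(dataset, k = spec$k,
                             seed = derive_seed(spec$seed, 77L),
                             cfg = spec$cfg)
  attr(cv, "stream_attenuation_db") <- atts
  cv
}
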