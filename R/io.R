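CONTAINER_MAGIC <- "CSIC"
CONTAINER_VERSION <- 1L

container_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "container_error")))
}

# header list + double payload for each supported object
.container_encode <- function(x) {
  if (inherits(x, "csi_tensor")) {
    m <- x$meta
    header <- list(
      type = "csi_tensor", dim = dim(x$values),
      label = as.character(m$label), seed = m$seed,
      pattern = unclass(m$pattern), channel = unclass(m$channel),
      noise = unclass(m$noise),
      applied_attenuation_db = m$applied_attenuation_db)
    payload <- c(Re(x$values), Im(x$values))
  } else if (inherits(x, "csi_dataset")) {
    if (length(x$features) == 0) {
      container_error("cannot serialize an empty dataset",
                      "container_shape_error")
    }
    header <- list(
      type = "csi_dataset", n_seq = length(x$features),
      seq_dim = dim(x$features[[1]]),
      labels = as.character(x$labels), levels = levels(x$labels),
      frame_rate_hz = x$frame_rate_hz, duration_s = x$duration_s,
      feature_mode = x$feature_mode)
    payload <- unlist(x$features, use.names = FALSE)
  } else if (inherits(x, "trained_model")) {
    shapes <- lapply(x$params, function(p) {
      if (is.matrix(p)) dim(p) else length(p)
    })
    header <- list(
      type = "trained_model", param_names = names(x$params),
      param_shapes = shapes, label_map = x$label_map,
      input_channels = x$input_channels, cfg = unclass(x$cfg),
      loss_history = x$loss_history, initial_loss = x$initial_loss,
      epochs_run = x$epochs_run, seed = x$seed)
    payload <- unlist(lapply(x$params, as.numeric), use.names = FALSE)
  } else {
    container_error(paste0("unsupported object of class ",
                           paste(class(x), collapse = "/")),
                    "container_type_error")
  }
  header$payload_length <- length(payload)
  list(header = header, payload = payload)
}

#' Write a CSI object to a container file
#'
#' Serializes a `csi_tensor`, `csi_dataset` or `trained_model` to a single
#' binary file: a magic tag and format version, a length-prefixed JSON
#' header carrying every metadata field (shape, frame rate, labels,
#' configuration, seed), and a payload of IEEE doubles (complex data as
#' paired real/imaginary arrays). The write is atomic (temporary file plus
#' rename) and the round trip through [read_container()] is bit-exact.
#'
#' @param x Object to write.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  enc <- .container_encode(x)
  hdr_raw <- charToRaw(jsonlite::toJSON(enc$header, auto_unbox = TRUE,
                                        digits = NA, null = "null"))
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, "wb")
  open_flag <- TRUE
  on.exit({
    if (open_flag) close(con)
    if (file.exists(tmp)) unlink(tmp)
  })
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  writeBin(CONTAINER_VERSION, con, size = 4L)
  writeBin(length(hdr_raw), con, size = 4L)
  writeBin(hdr_raw, con)
  writeBin(enc$payload, con, size = 8L)
  close(con)
  open_flag <- FALSE
  file.rename(tmp, path)
  invisible(path)
}

.rebuild_pattern <- function(p) {
  breathing_pattern(p$pattern_id, rate_bpm = p$rate_bpm,
                    max_tidal_volume_ml = p$max_tidal_volume_ml,
                    inspiration_fraction = p$inspiration_fraction,
                    harmonic_weights = as.numeric(p$harmonic_weights),
                    amplitude_jitter = p$amplitude_jitter,
                    rate_jitter = p$rate_jitter)
}

#' Read a container file
#'
#' Validates the magic tag, format version, header and payload length
#' (each failure raises a distinct classed condition) and reconstructs the
#' stored object with metadata field-for-field.
#'
#' @param path Container file written by [write_container()].
#' @return The stored `csi_tensor`, `csi_dataset` or `trained_model`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) {
    container_error(paste0("no such file: ", path), "container_parse_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, CONTAINER_MAGIC)) {
    container_error("not a CSI container (bad magic bytes)",
                    "container_parse_error")
  }
  version <- readBin(con, "integer", 1L, size = 4L)
  if (!identical(version, CONTAINER_VERSION)) {
    container_error(sprintf("container version %d not supported (expected %d)",
                            version, CONTAINER_VERSION),
                    "container_version_error")
  }
  hdr_len <- readBin(con, "integer", 1L, size = 4L)
  if (length(hdr_len) != 1L || is.na(hdr_len) || hdr_len <= 0) {
    container_error("corrupted header length", "container_parse_error")
  }
  hdr_raw <- readBin(con, "raw", hdr_len)
  if (length(hdr_raw) != hdr_len) {
    container_error("truncated header", "container_parse_error")
  }
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(hdr_raw), simplifyVector = TRUE),
    error = function(e) {
      container_error("unparseable header JSON", "container_parse_error")
    })
  payload <- readBin(con, "double", header$payload_length, size = 8L)
  if (length(payload) != header$payload_length) {
    container_error("truncated payload", "container_shape_error")
  }

  if (identical(header$type, "csi_tensor")) {
    d <- as.integer(header$dim)
    n <- prod(d)
    if (header$payload_length != 2 * n) {
      container_error("payload does not match the declared tensor shape",
                      "container_shape_error")
    }
    values <- array(complex(real = payload[seq_len(n)],
                            imaginary = payload[n + seq_len(n)]), dim = d)
    ch <- header$channel
    channel <- channel_config(
      center_freq_hz = ch$center_freq_hz, n_subcarriers = ch$n_subcarriers,
      subcarrier_spacing_hz = ch$subcarrier_spacing_hz,
      n_tx = ch$n_tx, n_rx = ch$n_rx,
      n_static_paths = ch$n_static_paths,
      breathing_gain = ch$breathing_gain,
      added_attenuation_db = ch$added_attenuation_db,
      frame_rate_hz = ch$frame_rate_hz, duration_s = ch$duration_s,
      baseline_distance_m = ch$baseline_distance_m)
    no <- header$noise
    noise <- noise_config(noise_power = no$noise_power,
                          agc_enabled = no$agc_enabled,
                          agc_target_amplitude = no$agc_target_amplitude,
                          seed = no$seed)
    structure(list(values = values,
                   meta = list(pattern = .rebuild_pattern(header$pattern),
                               channel = channel, noise = noise,
                               label = header$label, seed = header$seed,
                               applied_attenuation_db =
                                 header$applied_attenuation_db)),
              class = "csi_tensor")
  } else if (identical(header$type, "csi_dataset")) {
    sd <- as.integer(header$seq_dim)
    n_seq <- header$n_seq
    if (header$payload_length != n_seq * prod(sd)) {
      container_error("payload does not match the declared dataset shape",
                      "container_shape_error")
    }
    per <- prod(sd)
    features <- lapply(seq_len(n_seq), function(i) {
      matrix(payload[(i - 1) * per + seq_len(per)], sd[1], sd[2])
    })
    structure(list(features = features,
                   labels = factor(header$labels,
                                   levels = header$levels),
                   frame_rate_hz = header$frame_rate_hz,
                   duration_s = header$duration_s,
                   feature_mode = header$feature_mode),
              class = "csi_dataset")
  } else if (identical(header$type, "trained_model")) {
    shapes <- header$param_shapes
    params <- list()
    off <- 0L
    for (nm in header$param_names) {
      sh <- as.integer(shapes[[nm]])
      len <- prod(sh)
      vals <- payload[off + seq_len(len)]
      params[[nm]] <- if (length(sh) == 2) matrix(vals, sh[1], sh[2]) else vals
      off <- off + len
    }
    cfg <- header$cfg
    structure(list(params = params,
                   label_map = header$label_map,
                   input_channels = header$input_channels,
                   cfg = structure(cfg, class = "net_config"),
                   loss_history = header$loss_history,
                   initial_loss = header$initial_loss,
                   epochs_run = header$epochs_run,
                   seed = header$seed),
              class = "trained_model")
  } else {
    container_error(paste0("unknown container type: ", header$type),
                    "container_parse_error")
  }
}
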