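#' Generate the bundled test fixtures
#'
#' Writes deterministic miniature assets used by the test-suite and by CLI
#' smoke runs: a two-class dataset (patterns #2 and #6, 20 streams each,
#' from 8-subcarrier, 15 s acquisitions), the corresponding raw tensors,
#' and the toy confusion matrix `[[3, 1], [0, 2]]` as CSV. Identical seeds
#' produce byte-identical files.
#'
#' @param seed Master seed.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written file paths, invisibly.
#' @export
generate_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()

  tensors <- list()
  for (i in seq_along(c(2L, 6L))) {
    pid <- c(2L, 6L)[i]
    tens <- simulate_csi(
      breathing_pattern(pid),
      channel_config(n_subcarriers = 8L, duration_s = 15),
      noise_config(seed = derive_seed(seed, i)),
      label = sprintf("pattern-%d", pid))
    p <- file.path(dir, sprintf("fixture_tensor_pattern%d.csic", pid))
    write_container(tens, p)
    paths[sprintf("tensor_%d", pid)] <- p
    tensors[[i]] <- tens
  }

  dataset <- build_dataset(tensors, feature_mode = "spectrum")
  dataset <- dataset_subset(dataset, c(1:20, 48 + 1:20))  # 20 streams/class
  dataset$labels <- droplevels(dataset$labels)
  p <- file.path(dir, "fixture_dataset.csic")
  write_container(dataset, p)
  paths["dataset"] <- p

  cmat <- matrix(c(3L, 0L, 1L, 2L), 2, 2)  # rows predicted, columns true
  p <- file.path(dir, "fixture_confusion.csv")
  utils::write.csv(cmat, p, row.names = FALSE)
  paths["confusion"] <- p

  invisible(paths)
}
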