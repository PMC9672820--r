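# Plain-text trial I/O: one delimited file per trial (rows = channels), a
# labels file (trial_id,label) and a JSON manifest carrying the sampling
# rate and generator parameters.

#' Write a trial set to a directory of delimited text files
#'
#' Writes `trial_0001.csv`, ... (comma-separated, rows = channels),
#' `labels.csv` with columns `trial_id,label`, and `manifest.json` with the
#' sampling rate, seed and generator parameters.
#'
#' @param trials A `trial_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_set"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_trials() needs the jsonlite package for the manifest.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(trials$trials)) {
    utils::write.table(trials$trials[[i]],
                       file.path(dir, sprintf("trial_%04d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(trial_id = seq_along(trials$trials),
                              label = trials$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- trials$meta
  meta$class_effect <- as.data.frame(meta$class_effect)
  jsonlite::write_json(list(fs = trials$fs, meta = meta),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial set written by [write_trials()]
#'
#' @param dir Directory containing `trial_*.csv`, `labels.csv` and
#'   `manifest.json`.
#' @param fs Sampling rate override; taken from the manifest when `NULL`.
#' @return A `trial_set`.
#' @export
read_trials <- function(dir, fs = NULL) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  files <- file.path(dir, sprintf("trial_%04d.csv", labels$trial_id))
  trials <- lapply(files, function(f) {
    as.matrix(utils::read.table(f, sep = ","))
  })
  trials <- lapply(trials, unname)
  if (is.null(fs)) {
    manifest_path <- file.path(dir, "manifest.json")
    if (file.exists(manifest_path) &&
        requireNamespace("jsonlite", quietly = TRUE)) {
      fs <- jsonlite::read_json(manifest_path)$fs
    } else {
      stop("no manifest found; supply `fs` explicitly.")
    }
  }
  meta <- list(n_classes = length(unique(labels$label)),
               n_channels = nrow(trials[[1]]), fs = fs)
  structure(list(trials = trials, labels = as.integer(labels$label),
                 fs = as.numeric(fs), meta = meta),
            class = "trial_set")
}
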