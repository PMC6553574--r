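# Multichannel recording container and plain-text I/O.

#' Construct a multichannel EEG recording
#'
#' A recording bundles a channels-by-samples numeric matrix with its sampling
#' rate, channel labels, artifact intervals (half-open sample intervals
#' flagged for rejection) and any bad-channel labels. All analysis functions
#' in the package consume this object.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel labels (10-20 convention
#'   where applicable), one per row of `data`.
#' @param artifact_intervals intervals flagged for rejection; see
#'   [normalize_intervals()].
#' @param bad_channels labels of channels excluded from referencing and
#'   analysis.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, labels,
                          artifact_intervals = NULL,
                          bad_channels = character()) {
  data <- as.matrix(data)
  labels <- as.character(labels)
  if (nrow(data) != length(labels)) {
    cs_abort("number of labels must equal number of channel rows", "parameter")
  }
  if (anyDuplicated(labels)) cs_abort("channel labels must be unique", "parameter")
  if (!all(bad_channels %in% labels)) {
    cs_abort("bad_channels must be a subset of labels", "parameter")
  }
  if (!is.numeric(fs) || fs <= 0) cs_abort("fs must be positive", "parameter")
  rownames(data) <- labels
  structure(
    list(
      data = data,
      fs = fs,
      labels = labels,
      artifact_intervals = normalize_intervals(artifact_intervals, ncol(data)),
      bad_channels = bad_channels
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  if (length(x$bad_channels)) {
    cat("  bad:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  cat(sprintf("  artifact intervals: %d (%.2f s flagged)\n",
              nrow(x$artifact_intervals),
              sum(x$artifact_intervals[, 2] - x$artifact_intervals[, 1]) / x$fs))
  invisible(x)
}

good_channels <- function(rec) setdiff(rec$labels, rec$bad_channels)

channel_signal <- function(rec, label) {
  if (!label %in% rec$labels) {
    cs_abort(paste0("channel '", label, "' not found"), "lookup")
  }
  rec$data[label, ]
}

#' Write / read a recording as delimited matrix plus JSON sidecar
#'
#' The signal matrix goes to `<prefix>.tsv` (samples in rows, one named
#' column per channel); sampling rate, labels, artifact intervals and bad
#' channels go to `<prefix>.json`. A round trip reproduces the recording up
#' to the text precision of the TSV (15 significant digits).
#'
#' @param rec an [new_recording()] object.
#' @param prefix file path without extension.
#' @return `write_recording()` returns `prefix` invisibly; `read_recording()`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  mat <- t(rec$data)
  colnames(mat) <- rec$labels
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = TRUE),
                     paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    fs = rec$fs,
    labels = rec$labels,
    artifact_intervals = unname(apply(rec$artifact_intervals, 1, identity,
                                      simplify = FALSE)),
    bad_channels = rec$bad_channels
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  mat <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), header = TRUE,
                                     sep = "\t", check.names = FALSE))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  intervals <- meta$artifact_intervals
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  new_recording(
    t(mat), fs = meta$fs, labels = meta$labels,
    artifact_intervals = intervals,
    bad_channels = as.character(unlist(meta$bad_channels))
  )
}
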