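# Preprocessing chain: demean + common average reference (or bipolar
# derivation), zero-phase FIR high-pass, channel compositing.

#' Demean channels and apply a common average reference
#'
#' Each good channel first has its own mean removed; the per-sample mean
#' across good channels is then subtracted from every good channel. Bad
#' channels are excluded from the average and passed through unchanged. The
#' operation is idempotent on good channels.
#'
#' @param rec an [new_recording()] object with at least two good channels.
#' @return A re-referenced `eeg_recording`.
#' @export
reference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  good <- good_channels(rec)
  if (length(good) < 2L) {
    cs_abort("average reference needs at least two good channels", "reference")
  }
  data <- rec$data
  data[good, ] <- data[good, , drop = FALSE] -
    rowMeans(data[good, , drop = FALSE])
  data[good, ] <- sweep(data[good, , drop = FALSE], 2,
                        colMeans(data[good, , drop = FALSE]))
  new_recording(data, rec$fs, rec$labels, rec$artifact_intervals,
                rec$bad_channels)
}

#' Derive bipolar channels
#'
#' Builds one derived channel per anode-cathode pair (`anode - cathode`,
#' labelled `"anode-cathode"`), e.g. the clinical scheme C3-CP1 / C4-CP2.
#'
#' @param rec an [new_recording()] object.
#' @param pairs list of length-2 character vectors `c(anode, cathode)`; both
#'   labels must be present and good.
#' @return An `eeg_recording` containing only the derived channels.
#' @export
reference_bipolar <- function(rec, pairs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(pairs) && length(pairs) == 2L) pairs <- list(pairs)
  good <- good_channels(rec)
  data <- matrix(0, nrow = length(pairs), ncol = ncol(rec$data))
  labels <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!all(p %in% good)) {
      cs_abort(paste0("bipolar pair ", p[1], "-", p[2],
                      " needs both channels present and good"), "lookup")
    }
    data[i, ] <- rec$data[p[1], ] - rec$data[p[2], ]
    labels[i] <- paste0(p[1], "-", p[2])
  }
  new_recording(data, rec$fs, labels, rec$artifact_intervals)
}

#' Zero-phase FIR high-pass filter
#'
#' Removes slow drift with a linear-phase window-method FIR filter applied
#' forward and backward, so the net phase shift is zero. The filter length
#' follows the heuristic 3 x round(fs / cutoff) taps, forced odd and capped
#' at a third of the recording length (with a warning when the cap binds).
#' Filtering is applied to the continuous data; artifact intervals are kept
#' for masking afterwards.
#'
#' @param rec an [new_recording()] object.
#' @param cutoff high-pass cutoff in Hz (default 0.5).
#' @return A filtered `eeg_recording`.
#' @export
filter_highpass <- function(rec, cutoff = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff <= 0 || cutoff >= rec$fs / 2) {
    cs_abort("cutoff must lie in (0, fs/2)", "parameter")
  }
  n <- ncol(rec$data)
  taps <- 3L * as.integer(round(rec$fs / cutoff))
  if (taps %% 2L == 0L) taps <- taps + 1L
  cap <- floor(n / 3)
  if (taps > cap) {
    taps <- as.integer(cap)
    if (taps %% 2L == 0L) taps <- taps - 1L
    warn(sprintf("high-pass filter length capped at %d taps for a %d-sample recording",
                 taps, n))
  }
  if (n <= 3L * taps) cs_abort("signal too short for the high-pass filter",
                               "filtering")
  d <- design_fir(taps, cutoff / (rec$fs / 2), "high")
  # force an exact spectral null at DC (window-method designs leave a
  # residual DC gain of ~1e-3 at this length)
  if (abs(sum(d$h)) > 0) {
    d <- list(h = d$h - mean(d$h), key = paste0(d$key, "_dc0"))
  }
  data <- rec$data
  for (i in seq_len(nrow(data))) {
    data[i, ] <- fir_apply_twoway(data[i, ], d$h, d$key)
  }
  new_recording(data, rec$fs, rec$labels, rec$artifact_intervals,
                rec$bad_channels)
}

#' Composite a per-channel metric into one value per subject
#'
#' Averages a metric over the channels of a group (by default the
#' sensorimotor pair C3/C4). Channels with an undefined value are dropped; a
#' single available channel contributes its own value; if no channel has a
#' defined value the composite is `NA`.
#'
#' @param values named numeric vector of per-channel metric values (`NA` for
#'   undefined).
#' @param channels channel labels making up the composite.
#' @return A single numeric value (or `NA`).
#' @export
#' @examples
#' composite_channels(c(C3 = 0.4, C4 = 0.6))
#' composite_channels(c(C3 = 0.4, C4 = NA))
composite_channels <- function(values, channels = c("C3", "C4")) {
  present <- intersect(channels, names(values))
  if (length(present) == 0L) return(NA_real_)
  v <- values[present]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}
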