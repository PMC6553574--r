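# Phase-amplitude coupling: FIR band extraction, Hilbert phase/amplitude,
# and the normalized modulation index (KL divergence of the phase-binned
# amplitude distribution from uniform, scaled by log bin count).

filter_for_band <- function(x, fs, band) {
  if (band$f_hi >= fs / 2) cs_abort("band must lie below Nyquist", "parameter")
  taps <- taps_from_ms(band$order_ms, fs)
  if (length(x) <= 3L * taps) {
    cs_abort("signal must be longer than three filter lengths", "filtering")
  }
  d <- design_fir(taps, c(band$f_lo, band$f_hi) / (fs / 2), "pass")
  list(y = fir_apply(x, d$h, d$key), taps = taps)
}

edge_mask <- function(n, taps) {
  usable <- rep(TRUE, n)
  k <- min(taps, n)
  usable[seq_len(k)] <- FALSE
  usable[seq.int(n - k + 1L, n)] <- FALSE
  usable
}

#' Extract instantaneous band phase
#'
#' FIR band-pass (Hamming window, group delay compensated) followed by the
#' angle of the analytic signal. One filter length at each end is flagged
#' unusable in the attribute `"usable"`.
#'
#' @param x raw signal.
#' @param fs sampling rate in Hz.
#' @param band a [band_spec()]; default beta 13-30 Hz, 231 ms order.
#' @return Phase series in radians in `(-pi, pi]`, with attribute `usable`.
#' @export
extract_phase <- function(x, fs, band = band_spec(13, 30, 231)) {
  f <- filter_for_band(x, fs, band)
  out <- Arg(analytic_signal(f$y))
  attr(out, "usable") <- edge_mask(length(x), f$taps)
  out
}

#' Extract instantaneous band amplitude
#'
#' As [extract_phase()] but returns the magnitude of the analytic signal.
#'
#' @inheritParams extract_phase
#' @param band a [band_spec()]; default broadband gamma 50-150 Hz, 240 ms
#'   order.
#' @return Nonnegative amplitude series with attribute `usable`.
#' @export
extract_amplitude <- function(x, fs, band = band_spec(50, 150, 240)) {
  f <- filter_for_band(x, fs, band)
  out <- Mod(analytic_signal(f$y))
  attr(out, "usable") <- edge_mask(length(x), f$taps)
  out
}

new_pac_result <- function(mi, n_bins, n_used, bin_centers, bin_means,
                           phase_band = NULL, amp_band = NULL) {
  structure(
    list(mi = mi, n_bins = n_bins, n_samples_used = n_used,
         bin_centers = bin_centers, bin_means = bin_means,
         phase_band = phase_band, amp_band = amp_band),
    class = "pac_result"
  )
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> normalized modulation index = %.4g (%d bins, %d samples)\n",
              x$mi, x$n_bins, x$n_samples_used))
  invisible(x)
}

#' Normalized modulation index
#'
#' Bins amplitude by phase into `n_bins` equal-width bins over `(-pi, pi]`,
#' normalizes the bin-mean amplitudes to a distribution P, and returns
#' `KL(P || uniform) / log(n_bins)`, which lies in `[0, 1]`: 0 for a flat
#' phase-amplitude profile, 1 when all amplitude mass falls in one bin.
#'
#' @param phase phase series in radians.
#' @param amplitude amplitude series, same length.
#' @param n_bins number of phase bins (default 18).
#' @param usable optional logical mask of samples to keep.
#' @return A `pac_result` object.
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18L, usable = NULL) {
  if (length(phase) != length(amplitude)) {
    cs_abort("phase and amplitude must have equal length", "parameter")
  }
  if (!is.null(usable)) {
    phase <- phase[usable]
    amplitude <- amplitude[usable]
  }
  if (length(phase) == 0L) cs_abort("no usable samples", "insufficient_data")
  w <- 2 * pi / n_bins
  bin <- pmin(pmax(ceiling((as.numeric(phase) + pi) / w), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  if (any(counts == 0L)) {
    cs_abort("every phase bin needs at least one usable sample",
             "insufficient_data")
  }
  sums <- vapply(seq_len(n_bins), function(j) sum(amplitude[bin == j]),
                 numeric(1))
  means <- sums / counts
  if (sum(means) <= 0) cs_abort("amplitude is zero everywhere",
                                "undefined_metric")
  p <- means / sum(means)
  if (all(means == means[1L])) {
    mi <- 0 # flat profile: KL from uniform is identically zero
  } else {
    terms <- ifelse(p > 0, p * log(p * n_bins), 0)
    mi <- sum(terms) / log(n_bins)
  }
  new_pac_result(mi, as.integer(n_bins), length(phase),
                 bin_centers = -pi + (seq_len(n_bins) - 0.5) * w,
                 bin_means = means)
}

# Usable-sample mask: outside artifact intervals and at least `trim` samples
# from each end of every continuous artifact-free run.
usable_run_mask <- function(n, intervals, trim) {
  keep <- !intervals_to_mask(intervals, n)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  usable <- logical(n)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i] + trim
    e <- ends[i] - trim
    if (s <= e) usable[s:e] <- TRUE
  }
  usable
}

#' Phase-amplitude coupling of one channel
#'
#' Filters the signal in the phase band (beta) and amplitude band (gamma),
#' removes artifact-flagged regions, takes Hilbert phase and amplitude, and
#' computes the normalized modulation index. The default processing order
#' filters, then removes flagged regions, then applies the Hilbert
#' transform to the concatenated remainder; `order =
#' "filter_hilbert_remove"` instead transforms the continuous filtered
#' signal and drops flagged samples before binning, avoiding concatenation
#' discontinuities. One combined filter length is discarded at each end of
#' every continuous segment either way.
#'
#' @param x raw signal.
#' @param fs sampling rate in Hz.
#' @param phase_band,amp_band [band_spec()] objects; defaults 13-30 Hz /
#'   231 ms and 50-150 Hz / 240 ms.
#' @param n_bins number of phase bins (default 18).
#' @param artifact_intervals half-open sample intervals to exclude.
#' @param order processing order, see Details.
#' @return A `pac_result` object.
#' @export
pac_mi <- function(x, fs, phase_band = band_spec(13, 30, 231),
                   amp_band = band_spec(50, 150, 240), n_bins = 18L,
                   artifact_intervals = NULL,
                   order = c("filter_remove_hilbert",
                             "filter_hilbert_remove")) {
  order <- match.arg(order)
  fp <- filter_for_band(x, fs, phase_band)
  fa <- filter_for_band(x, fs, amp_band)
  trim <- max(fp$taps, fa$taps)
  usable <- usable_run_mask(length(x), artifact_intervals, trim)
  if (!any(usable)) cs_abort("no usable samples after masking",
                             "insufficient_data")
  if (order == "filter_remove_hilbert") {
    keep <- !intervals_to_mask(artifact_intervals, length(x))
    phase <- Arg(analytic_signal(fp$y[keep]))
    amp <- Mod(analytic_signal(fa$y[keep]))
    sub <- usable[keep]
    res <- modulation_index(phase[sub], amp[sub], n_bins)
  } else {
    phase <- Arg(analytic_signal(fp$y))
    amp <- Mod(analytic_signal(fa$y))
    res <- modulation_index(phase, amp, n_bins, usable = usable)
  }
  res$phase_band <- phase_band
  res$amp_band <- amp_band
  res
}

#' @export
tidy.pac_result <- function(x, ...) {
  tibble(bin = seq_len(x$n_bins), phase = x$bin_centers,
         mean_amplitude = x$bin_means,
         p = x$bin_means / sum(x$bin_means))
}

#' @export
glance.pac_result <- function(x, ...) {
  tibble(mi = x$mi, n_bins = x$n_bins, n_samples_used = x$n_samples_used)
}
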