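# Cycle-by-cycle waveform shape analysis. Zerocrossings of a band-pass
# filtered copy delimit cycles; peaks, troughs, sharpness and steepness are
# then measured on the raw (unfiltered) signal, and summarised as four
# logged ratios plus a quadrant label.

#' Specify a frequency band and FIR filter order
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @param order_ms FIR filter order expressed in milliseconds; the tap count
#'   is `round(order_ms * fs / 1000)` forced odd. Defaults give the beta
#'   band, 13-30 Hz with a 231 ms filter (119 taps at 512 Hz); use
#'   `band_spec(8, 12, 231)` for the alpha/mu band.
#' @return A `band_spec` object.
#' @export
band_spec <- function(f_lo = 13, f_hi = 30, order_ms = 231) {
  if (!(f_lo > 0 && f_hi > f_lo)) {
    cs_abort("band edges must satisfy 0 < f_lo < f_hi", "parameter")
  }
  structure(list(f_lo = f_lo, f_hi = f_hi, order_ms = order_ms),
            class = "band_spec")
}

#' One-pass linear-phase FIR band-pass filter
#'
#' Window-method (Hamming) FIR band-pass whose group delay is compensated,
#' so the filtered trace is index-aligned with the raw signal: a
#' zerocrossing index found in the output addresses the same instant in the
#' input.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band a [band_spec()]; `f_hi` must be below the Nyquist frequency.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_fir <- function(x, fs, band = band_spec()) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f_hi >= fs / 2) cs_abort("band must lie below Nyquist", "parameter")
  taps <- taps_from_ms(band$order_ms, fs)
  if (length(x) <= 3L * taps) {
    cs_abort("signal must be longer than three filter lengths", "filtering")
  }
  d <- design_fir(taps, c(band$f_lo, band$f_hi) / (fs / 2), "pass")
  fir_apply(x, d$h, d$key)
}

#' Find rising and falling zerocrossings
#'
#' Rising crossing at index `i` where `x[i] < 0` and `x[i+1] >= 0`; falling
#' where `x[i] >= 0` and `x[i+1] < 0` (a sample exactly at zero counts as
#' nonnegative). Crossings alternate strictly by construction.
#'
#' @param x numeric signal (normally the band-pass filtered trace).
#' @return List with integer vectors `rising` and `falling`.
#' @export
find_zerocrossings <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(rising = integer(0), falling = integer(0)))
  neg <- x < 0
  list(rising = which(neg[-n] & !neg[-1L]),
       falling = which(!neg[-n] & neg[-1L]))
}

#' Locate peaks and troughs between zerocrossings
#'
#' Each peak is the index of the raw-signal maximum over the half-open
#' window from a rising crossing to the next falling crossing; each trough
#' the minimum from a falling crossing to the next rising crossing. The
#' first index wins on ties.
#'
#' @param x raw signal (extrema are read from the unfiltered trace).
#' @param rising,falling crossing indices from [find_zerocrossings()].
#' @return List with integer vectors `peaks` and `troughs` and matching
#'   window matrices `peak_windows`, `trough_windows` (columns start, end).
#' @export
locate_extrema <- function(x, rising, falling) {
  pair <- function(starts, others) {
    pos <- findInterval(starts, others) + 1L
    keep <- pos <= length(others)
    cbind(start = starts[keep], end = others[pos[keep]])
  }
  pw <- pair(rising, falling)
  tw <- pair(falling, rising)
  list(
    peaks = window_argmax(x, pw[, 1L], pw[, 2L], TRUE),
    troughs = window_argmax(x, tw[, 1L], tw[, 2L], FALSE),
    peak_windows = pw,
    trough_windows = tw
  )
}

#' Extremum sharpness
#'
#' Mean of the two voltage differences between the extremum and the samples
#' `width` points before and after it: for a peak
#' `((x[p] - x[p-width]) + (x[p] - x[p+width])) / 2`, and the mirror image
#' for a trough. At 512 Hz the default width of 3 samples spans about
#' 5.9 ms. Extrema closer than `width` to either end give `NA`.
#'
#' @param x raw signal.
#' @param idx extremum indices.
#' @param width half-window in samples (>= 1).
#' @param type `"peak"` or `"trough"`.
#' @return Numeric vector of sharpness values (>= 0 at true local extrema).
#' @export
extrema_sharpness <- function(x, idx, width = 3L, type = c("peak", "trough")) {
  type <- match.arg(type)
  if (width < 1L) cs_abort("width must be >= 1", "parameter")
  n <- length(x)
  ok <- !is.na(idx) & idx > width & idx + width <= n
  out <- rep(NA_real_, length(idx))
  i <- idx[ok]
  if (type == "peak") {
    out[ok] <- ((x[i] - x[i - width]) + (x[i] - x[i + width])) / 2
  } else {
    out[ok] <- ((x[i - width] - x[i]) + (x[i + width] - x[i])) / 2
  }
  out
}

#' Segment steepness
#'
#' Rise steepness is the maximum one-sample forward difference between a
#' trough and the subsequent peak; decay steepness the maximum magnitude of
#' the downward slope between a peak and the subsequent trough.
#'
#' @param x raw signal.
#' @param starts,ends segment boundaries (start extremum, end extremum); the
#'   slope is maximised over the half-open index window `[start, end)` of
#'   the forward difference.
#' @param type `"rise"` or `"decay"`.
#' @return Numeric vector of steepness values (signal units per sample).
#' @export
segment_steepness <- function(x, starts, ends, type = c("rise", "decay")) {
  type <- match.arg(type)
  d <- diff(x)
  if (type == "decay") d <- -d
  bad <- is.na(starts) | is.na(ends) | (!is.na(starts) & !is.na(ends) & starts >= ends)
  s <- ifelse(bad, 1L, starts)
  e <- ifelse(bad, 1L, ends)
  out <- window_max(d, as.integer(s), as.integer(e))
  out[bad] <- NA_real_
  out
}

#' Extract the per-cycle feature table
#'
#' Runs the full cycle decomposition for one channel: band-pass filter,
#' zerocrossings, raw-signal extrema, sharpness and steepness. One row per
#' cycle, anchored on a peak (`rise_zc < peak_idx < fall_zc < trough_idx`);
#' a leading trough without a preceding peak contributes a trough-only row
#' so that every extremum enters the channel means. Features are `NA` (and
#' the cycle invalid) when the extremum lies in an artifact interval, a
#' steepness segment overlaps one, or the extremum sits within `width`
#' samples of the recording boundary.
#'
#' @param x raw signal for one channel.
#' @param fs sampling rate in Hz.
#' @param band [band_spec()] delimiting cycles (default beta, 13-30 Hz).
#' @param artifact_intervals half-open sample intervals to exclude.
#' @param width sharpness half-window in samples (default 3).
#' @return A tibble with columns `rise_zc`, `peak_idx`, `fall_zc`,
#'   `trough_idx`, `peak_sharp`, `trough_sharp`, `rise_steep`,
#'   `decay_steep`, `valid`.
#' @export
cycle_features <- function(x, fs, band = band_spec(),
                           artifact_intervals = NULL, width = 3L) {
  xf <- bandpass_fir(x, fs, band)
  zc <- find_zerocrossings(xf)
  ex <- locate_extrema(x, zc$rising, zc$falling)
  peaks <- ex$peaks
  troughs <- ex$troughs
  K <- length(peaks)
  M <- length(troughs)
  n <- length(x)
  mask <- intervals_to_mask(artifact_intervals, n)

  starts_with_trough <- M > 0L && (K == 0L || troughs[1L] < peaks[1L])
  at <- function(v, i) {
    out <- rep(NA_integer_, length(i))
    ok <- !is.na(i) & i >= 1L & i <= length(v)
    out[ok] <- v[i[ok]]
    out
  }
  k <- seq_len(K)
  if (starts_with_trough) {
    prev_trough <- at(troughs, k)
    next_trough <- at(troughs, k + 1L)
  } else {
    prev_trough <- at(troughs, k - 1L)
    next_trough <- at(troughs, k)
  }
  rise_zc <- if (K) ex$peak_windows[, 1L] else integer(0)
  fall_zc <- if (K) ex$peak_windows[, 2L] else integer(0)

  peak_sharp <- extrema_sharpness(x, peaks, width, "peak")
  trough_sharp_all <- extrema_sharpness(x, troughs, width, "trough")
  trough_sharp <- {
    i <- if (starts_with_trough) k + 1L else k
    at_num <- function(v, i) {
      out <- rep(NA_real_, length(i))
      ok <- !is.na(i) & i >= 1L & i <= length(v)
      out[ok] <- v[i[ok]]
      out
    }
    at_num(trough_sharp_all, i)
  }
  rise_steep <- segment_steepness(x, prev_trough, peaks, "rise")
  decay_steep <- segment_steepness(x, peaks, next_trough, "decay")

  # artifact exclusion: extremum inside a flagged region, or a steepness
  # segment touching one
  masked_at <- function(i) !is.na(i) & mask[pmax(i, 1L)]
  seg_masked <- function(s, e) {
    out <- logical(length(s))
    for (j in seq_along(s)) {
      if (!is.na(s[j]) && !is.na(e[j])) out[j] <- any(mask[s[j]:e[j]])
    }
    out
  }
  if (any(mask)) {
    peak_sharp[masked_at(peaks)] <- NA_real_
    trough_bad_all <- masked_at(troughs)
    idx <- if (starts_with_trough) k + 1L else k
    bad <- !is.na(idx) & idx >= 1L & idx <= M & trough_bad_all[pmax(idx, 1L)]
    trough_sharp[bad] <- NA_real_
    rise_steep[seg_masked(prev_trough, peaks) | masked_at(peaks)] <- NA_real_
    decay_steep[seg_masked(peaks, next_trough) | masked_at(peaks)] <- NA_real_
  }

  tbl <- tibble(
    rise_zc = as.integer(rise_zc),
    peak_idx = as.integer(peaks),
    fall_zc = as.integer(fall_zc),
    trough_idx = as.integer(next_trough),
    peak_sharp = peak_sharp,
    trough_sharp = trough_sharp,
    rise_steep = rise_steep,
    decay_steep = decay_steep
  )
  if (starts_with_trough) {
    t1 <- troughs[1L]
    s1 <- trough_sharp_all[1L]
    if (any(mask) && mask[t1]) s1 <- NA_real_
    lead <- tibble(rise_zc = NA_integer_, peak_idx = NA_integer_,
                   fall_zc = NA_integer_, trough_idx = as.integer(t1),
                   peak_sharp = NA_real_, trough_sharp = s1,
                   rise_steep = NA_real_, decay_steep = NA_real_)
    tbl <- dplyr::bind_rows(lead, tbl)
  }
  tbl$valid <- !is.na(tbl$peak_sharp) & !is.na(tbl$trough_sharp) &
    !is.na(tbl$rise_steep) & !is.na(tbl$decay_steep)
  attr(tbl, "fs") <- fs
  attr(tbl, "band") <- band
  attr(tbl, "width") <- width
  tbl
}

#' Summarise a cycle table as channel-level shape metrics
#'
#' The peak-to-trough ratio is the natural log of mean peak sharpness over
#' mean trough sharpness (positive means sharper peaks); the rise-to-fall
#' ratio the log of mean rise steepness over mean decay steepness (negative
#' means steeper decays). The sharpness and steepness ratios are their
#' absolute values, so they are always nonnegative. The sign pair places the
#' waveform in one of four quadrants; Q4 (sharp peaks, steep decays) is the
#' canonical sensorimotor shape.
#'
#' @param cycles a tibble from [cycle_features()].
#' @param min_cycles minimum number of fully valid cycles for a defined
#'   metric (default 5); fewer yields `NA` metrics with a warning.
#' @return A one-row tibble: `peak_trough_ratio`, `rise_fall_ratio`,
#'   `sharpness_ratio`, `steepness_ratio`, `quadrant`, `n_valid_cycles`.
#' @export
shape_metrics <- function(cycles, min_cycles = 5L) {
  n_valid <- sum(cycles$valid)
  undefined <- function(reason) {
    warn(paste0("shape metrics undefined: ", reason),
         class = "cycleshape_warning_undefined_metric")
    tibble(peak_trough_ratio = NA_real_, rise_fall_ratio = NA_real_,
           sharpness_ratio = NA_real_, steepness_ratio = NA_real_,
           quadrant = NA_character_, n_valid_cycles = n_valid)
  }
  if (n_valid < min_cycles) {
    return(undefined(sprintf("%d valid cycles (< %d)", n_valid, min_cycles)))
  }
  mpk <- mean(cycles$peak_sharp, na.rm = TRUE)
  mtr <- mean(cycles$trough_sharp, na.rm = TRUE)
  mrise <- mean(cycles$rise_steep, na.rm = TRUE)
  mdecay <- mean(cycles$decay_steep, na.rm = TRUE)
  if (!all(is.finite(c(mpk, mtr, mrise, mdecay))) ||
      min(mpk, mtr, mrise, mdecay) <= 0) {
    return(undefined("nonpositive mean sharpness or steepness"))
  }
  ptr <- log(mpk / mtr)
  rtf <- log(mrise / mdecay)
  quadrant <- if (ptr == 0 || rtf == 0) {
    "boundary"
  } else if (ptr > 0 && rtf > 0) {
    "Q1"
  } else if (ptr < 0 && rtf > 0) {
    "Q2"
  } else if (ptr < 0 && rtf < 0) {
    "Q3"
  } else {
    "Q4"
  }
  tibble(peak_trough_ratio = ptr, rise_fall_ratio = rtf,
         sharpness_ratio = abs(ptr), steepness_ratio = abs(rtf),
         quadrant = quadrant, n_valid_cycles = n_valid)
}

#' Full waveform-shape chain for one channel
#'
#' Convenience wrapper: [cycle_features()] then [shape_metrics()].
#'
#' @inheritParams cycle_features
#' @inheritParams shape_metrics
#' @return A one-row tibble as from [shape_metrics()].
#' @export
waveform_shape <- function(x, fs, band = band_spec(),
                           artifact_intervals = NULL, width = 3L,
                           min_cycles = 5L) {
  shape_metrics(cycle_features(x, fs, band, artifact_intervals, width),
                min_cycles)
}
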