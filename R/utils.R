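# Shared numeric helpers: FIR application, analytic signal, interval masks.

cs_abort <- function(msg, class) {
  abort(msg, class = c(paste0("cycleshape_error_", class), "cycleshape_error"))
}

#' Convert a sample count to milliseconds
#'
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @return Duration in milliseconds. For example, 3 samples at 512 Hz span
#'   about 5.9 ms, the window over which extremum sharpness is measured by
#'   default.
#' @export
#' @examples
#' samples_to_ms(3, 512)
samples_to_ms <- function(n_samples, fs) {
  stopifnot(fs > 0)
  1000 * n_samples / fs
}

# Cache of FIR kernel FFTs: repeated filtering with the same design and
# signal length (simulation studies) re-uses the transformed kernel.
.fft_cache <- new.env(parent = emptyenv())

kernel_fft <- function(h, m, key = NULL) {
  if (is.null(key)) return(fft(c(h, numeric(m - length(h)))))
  full_key <- paste0(key, "_m", m)
  H <- .fft_cache[[full_key]]
  if (is.null(H)) {
    H <- fft(c(h, numeric(m - length(h))))
    .fft_cache[[full_key]] <- H
  }
  H
}

# FFT-based linear convolution of a signal with an FIR kernel, with the group
# delay of a symmetric odd-length kernel compensated so that y[i] lines up
# with x[i]. Zero padding outside the signal; edges are therefore attenuated
# over roughly half the kernel length at each end.
fir_apply <- function(x, h, key = NULL) {
  n <- length(x)
  taps <- length(h)
  if (taps %% 2L != 1L) cs_abort("FIR kernel must have odd length", "parameter")
  delay <- (taps - 1L) %/% 2L
  m <- stats::nextn(n + taps - 1L, c(2L, 3L, 5L))
  y <- Re(fft(fft(c(x, numeric(m - n))) * kernel_fft(h, m, key),
              inverse = TRUE)) / m
  y[(delay + 1L):(delay + n)]
}

# Two-way (forward and backward) application of a symmetric FIR kernel:
# zero net phase shift, squared magnitude response.
fir_apply_twoway <- function(x, h, key = NULL) {
  rev(fir_apply(rev(fir_apply(x, h, key)), h, key))
}

# Cached FIR design (window method, Hamming) keyed by the design parameters.
design_fir <- function(taps, w, type) {
  key <- paste0(type, "_", taps, "_", paste(signif(w, 12), collapse = "_"))
  h <- .fft_cache[[key]]
  if (is.null(h)) {
    h <- signal::fir1(taps - 1L, w, type = type)
    .fft_cache[[key]] <- h
  }
  list(h = h, key = key)
}

# Odd tap count from a filter order expressed in milliseconds.
taps_from_ms <- function(order_ms, fs) {
  taps <- as.integer(round(order_ms * fs / 1000))
  if (taps %% 2L == 0L) taps <- taps + 1L
  taps
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) cs_abort("signal too short for analytic transform", "parameter")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# ---- artifact intervals ----------------------------------------------------
# Intervals are half-open [start, end): they cover samples start .. end - 1
# in R's 1-based indexing. Stored as a two-column integer matrix.

as_interval_matrix <- function(intervals) {
  if (is.null(intervals) || length(intervals) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (is.list(intervals)) intervals <- do.call(rbind, lapply(intervals, as.integer))
  if (is.vector(intervals) && length(intervals) == 2L) {
    intervals <- matrix(as.integer(intervals), ncol = 2L)
  }
  intervals <- matrix(as.integer(intervals), ncol = 2L)
  colnames(intervals) <- c("start", "end")
  if (any(intervals[, 1L] > intervals[, 2L])) {
    cs_abort("interval start must not exceed end", "interval")
  }
  intervals
}

#' Normalize artifact intervals
#'
#' Sorts, merges overlapping or touching intervals, drops empty ones, and
#' optionally clips to the recording length. Intervals are half-open
#' `[start, end)` in samples (1-based start, exclusive end), so `c(10, 30)`
#' flags samples 10 through 29. The operation is idempotent and
#' order-invariant.
#'
#' @param intervals a two-column matrix, a list of length-2 vectors, or NULL.
#' @param n_samples optional recording length used to clip intervals.
#' @return A two-column integer matrix with columns `start` and `end`.
#' @export
#' @examples
#' normalize_intervals(list(c(10, 20), c(15, 30)))
normalize_intervals <- function(intervals, n_samples = NULL) {
  iv <- as_interval_matrix(intervals)
  if (!is.null(n_samples)) {
    iv[, 1L] <- pmax(iv[, 1L], 1L)
    iv[, 2L] <- pmin(iv[, 2L], as.integer(n_samples) + 1L)
  }
  iv <- iv[iv[, 1L] < iv[, 2L], , drop = FALSE]
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- list(iv[1L, ])
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- out[[length(out)]]
    if (iv[i, 1L] <= last[2L]) {
      out[[length(out)]][2L] <- max(last[2L], iv[i, 2L])
    } else {
      out[[length(out) + 1L]] <- iv[i, ]
    }
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("start", "end")
  res
}

# Logical mask of flagged samples.
intervals_to_mask <- function(intervals, n_samples) {
  mask <- logical(n_samples)
  iv <- normalize_intervals(intervals, n_samples)
  for (i in seq_len(nrow(iv))) mask[iv[i, 1L]:(iv[i, 2L] - 1L)] <- TRUE
  mask
}

# Convert annotation times in seconds to a sample interval. Conservative:
# floors the onset and ceils the offset so the flagged region is never
# shorter than the annotation.
seconds_to_interval <- function(onset_s, offset_s, fs) {
  c(floor(onset_s * fs) + 1L, ceiling(offset_s * fs) + 1L)
}
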