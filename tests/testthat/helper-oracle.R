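# Deliberately naive reference implementation of the cycle decomposition:
# explicit loops, direct-form convolution, no vectorization. Used as an
# independent oracle for the pipeline's cycle tables.

oracle_fir_bandpass <- function(x, fs, f_lo, f_hi, order_ms) {
  taps <- as.integer(round(order_ms * fs / 1000))
  if (taps %% 2L == 0L) taps <- taps + 1L
  h <- signal::fir1(taps - 1L, c(f_lo, f_hi) / (fs / 2), type = "pass")
  n <- length(x)
  delay <- (taps - 1L) %/% 2L
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(taps)) {
      j <- i + delay - (k - 1L)
      if (j >= 1L && j <= n) acc <- acc + h[k] * x[j]
    }
    y[i] <- acc
  }
  y
}

oracle_cycle_table <- function(x, fs, f_lo = 13, f_hi = 30, order_ms = 231,
                               width = 3L) {
  xf <- oracle_fir_bandpass(x, fs, f_lo, f_hi, order_ms)
  n <- length(x)
  rising <- integer(0)
  falling <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (xf[i] < 0 && xf[i + 1L] >= 0) rising <- c(rising, i)
    if (xf[i] >= 0 && xf[i + 1L] < 0) falling <- c(falling, i)
  }
  argbest <- function(s, e, max) { # over [s, e)
    best <- s
    for (j in seq.int(s, e - 1L)) {
      if (max && x[j] > x[best]) best <- j
      if (!max && x[j] < x[best]) best <- j
    }
    best
  }
  peaks <- integer(0); pw_s <- integer(0); pw_e <- integer(0)
  for (r in rising) {
    nxt <- NA_integer_
    for (f in falling) if (f > r) { nxt <- f; break }
    if (!is.na(nxt)) {
      peaks <- c(peaks, argbest(r, nxt, TRUE))
      pw_s <- c(pw_s, r); pw_e <- c(pw_e, nxt)
    }
  }
  troughs <- integer(0)
  for (f in falling) {
    nxt <- NA_integer_
    for (r in rising) if (r > f) { nxt <- r; break }
    if (!is.na(nxt)) troughs <- c(troughs, argbest(f, nxt, FALSE))
  }
  sharp <- function(i, peak) {
    if (is.na(i) || i <= width || i + width > n) return(NA_real_)
    if (peak) ((x[i] - x[i - width]) + (x[i] - x[i + width])) / 2
    else ((x[i - width] - x[i]) + (x[i + width] - x[i])) / 2
  }
  steep <- function(s, e, rise) { # max slope over [s, e) of the diff
    if (is.na(s) || is.na(e) || s >= e) return(NA_real_)
    best <- -Inf
    for (j in seq.int(s, e - 1L)) {
      d <- x[j + 1L] - x[j]
      if (!rise) d <- -d
      if (d > best) best <- d
    }
    best
  }
  K <- length(peaks); M <- length(troughs)
  swt <- M > 0L && (K == 0L || troughs[1L] < peaks[1L])
  rows <- list()
  if (swt) {
    rows[[1]] <- data.frame(rise_zc = NA_integer_, peak_idx = NA_integer_,
                            fall_zc = NA_integer_,
                            trough_idx = troughs[1L],
                            peak_sharp = NA_real_,
                            trough_sharp = sharp(troughs[1L], FALSE),
                            rise_steep = NA_real_, decay_steep = NA_real_)
  }
  for (k in seq_len(K)) {
    prev_t <- if (swt) troughs[k] else if (k > 1L) troughs[k - 1L] else NA_integer_
    next_t <- if (swt) {
      if (k + 1L <= M) troughs[k + 1L] else NA_integer_
    } else {
      if (k <= M) troughs[k] else NA_integer_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      rise_zc = pw_s[k], peak_idx = peaks[k], fall_zc = pw_e[k],
      trough_idx = next_t,
      peak_sharp = sharp(peaks[k], TRUE),
      trough_sharp = sharp(next_t, FALSE),
      rise_steep = steep(prev_t, peaks[k], TRUE),
      decay_steep = steep(peaks[k], next_t, FALSE)
    )
  }
  out <- do.call(rbind, rows)
  out$valid <- !is.na(out$peak_sharp) & !is.na(out$trough_sharp) &
    !is.na(out$rise_steep) & !is.na(out$decay_steep)
  out
}

# Independent numerical-integration oracle for the normalized modulation
# index of amplitude = 1 + cos(phase) under uniform phase.
oracle_mi_one_plus_cos <- function(n_bins = 18L) {
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  means <- vapply(seq_len(n_bins), function(j) {
    stats::integrate(function(th) 1 + cos(th), edges[j], edges[j + 1L],
                     rel.tol = 1e-12)$value / (edges[j + 1L] - edges[j])
  }, numeric(1))
  p <- means / sum(means)
  sum(p * log(p * n_bins)) / log(n_bins)
}
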