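# Synthetic EEG generator: non-sinusoidal oscillations over a 1/f background,
# with optional phase-locked gamma and paired two-state cohorts. Ground truth
# (rise-decay asymmetry, extremum sharpness, coupling depth) is set by the
# parameters, so every downstream stage can be validated.

#' Parameters for one synthetic sensorimotor recording
#'
#' The generated signal is the sum of a non-sinusoidal beta oscillation, an
#' alpha/mu sinusoid, spectrally shaped 1/f noise, and (optionally) a gamma
#' carrier whose amplitude is modulated by beta phase. Waveform shape is
#' controlled by two independent knobs:
#'
#' * `rdsym` — the fraction of each cycle occupied by the rise
#'   (trough to peak). 0.5 is symmetric; smaller values give a short, steep
#'   rise and a long, shallow decay.
#' * `peak_exp`, `trough_exp` — extremum-sharpening exponents applied to the
#'   normalized half-cosine arcs of the positive and negative half-cycles.
#'   1 leaves sinusoidal curvature; larger values sharpen the extremum while
#'   preserving its amplitude, so sharpness and amplitude stay decoupled.
#'
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz; must exceed twice `gamma_freq`.
#' @param osc_freq oscillation frequency in Hz (beta by default).
#' @param rdsym rise fraction of the cycle, strictly in (0, 1).
#' @param peak_exp,trough_exp sharpening exponents, `>= 1`.
#' @param osc_amp oscillation amplitude (signal units; extrema at
#'   `+/- osc_amp` before the zero-mean correction).
#' @param alpha_freq,alpha_amp frequency and amplitude of the sinusoidal
#'   alpha/mu component (amplitude 0 disables it).
#' @param aperiodic_exp exponent chi of the 1/f^chi background, `>= 0`.
#' @param noise_amp standard deviation of the aperiodic background.
#' @param pac_depth modulation fraction m in `[0, 1]` of the beta-phase-locked
#'   gamma amplitude; 0 gives a constant-amplitude gamma.
#' @param gamma_freq gamma carrier frequency in Hz.
#' @param gamma_amp gamma carrier peak amplitude (0 disables the carrier).
#' @param artifact_intervals half-open sample intervals where high-amplitude
#'   broadband bursts are inserted (and reported as ground truth).
#' @param seed integer seed; identical parameter sets (including the seed)
#'   reproduce bit-identical recordings.
#' @return A `synth_params` object (a validated list).
#' @export
synth_params <- function(duration = 180, fs = 512, osc_freq = 20,
                         rdsym = 0.5, peak_exp = 1, trough_exp = 1,
                         osc_amp = 1, alpha_freq = 10, alpha_amp = 0.5,
                         aperiodic_exp = 2, noise_amp = 1,
                         pac_depth = 0, gamma_freq = 80, gamma_amp = 0.3,
                         artifact_intervals = NULL, seed = NULL) {
  if (!is.numeric(rdsym) || rdsym <= 0 || rdsym >= 1) {
    cs_abort("rdsym must lie strictly in (0, 1)", "parameter")
  }
  if (peak_exp < 1 || trough_exp < 1) {
    cs_abort("sharpening exponents must be >= 1", "parameter")
  }
  if (pac_depth < 0 || pac_depth > 1) {
    cs_abort("pac_depth must lie in [0, 1]", "parameter")
  }
  if (aperiodic_exp < 0) cs_abort("aperiodic_exp must be >= 0", "parameter")
  if (gamma_amp > 0 && fs <= 2 * gamma_freq) {
    cs_abort("fs must exceed twice gamma_freq", "parameter")
  }
  if (duration <= 0 || fs <= 0 || osc_freq <= 0) {
    cs_abort("duration, fs and osc_freq must be positive", "parameter")
  }
  structure(
    list(duration = duration, fs = fs, osc_freq = osc_freq, rdsym = rdsym,
         peak_exp = peak_exp, trough_exp = trough_exp, osc_amp = osc_amp,
         alpha_freq = alpha_freq, alpha_amp = alpha_amp,
         aperiodic_exp = aperiodic_exp, noise_amp = noise_amp,
         pac_depth = pac_depth, gamma_freq = gamma_freq,
         gamma_amp = gamma_amp,
         artifact_intervals = normalize_intervals(
           artifact_intervals, floor(duration * fs)),
         seed = seed),
    class = "synth_params"
  )
}

# Shape template evaluated at cycle positions s in [0, 1): trough at s = 0,
# peak at s = rdsym. Returns the sharpened, amplitude-normalized waveform.
shape_template <- function(s, rdsym, peak_exp, trough_exp) {
  rising <- s < rdsym
  u <- ifelse(rising, s / rdsym, (s - rdsym) / (1 - rdsym))
  base <- ifelse(rising, -cos(pi * u), cos(pi * u))
  pos <- base > 0
  out <- base
  out[pos] <- base[pos]^peak_exp
  out[!pos] <- -((-base[!pos])^trough_exp)
  out
}

# Mean of the sharpened template over one cycle (midpoint rule on a fine
# grid); subtracted so the oscillation has zero mean over whole cycles.
template_cycle_mean <- function(rdsym, peak_exp, trough_exp, k = 100000L) {
  s <- (seq_len(k) - 0.5) / k
  mean(shape_template(s, rdsym, peak_exp, trough_exp))
}

#' Simulate a non-sinusoidal oscillation
#'
#' Builds the oscillation sample-by-sample from half-cosine arcs: the rise
#' (trough to peak) occupies `rdsym / osc_freq` seconds of each cycle and the
#' decay the remaining `(1 - rdsym) / osc_freq`; positive and negative
#' half-cycles are raised to `peak_exp` and `trough_exp`. With `rdsym = 0.5`
#' and both exponents 1 the result is exactly a sinusoid at `osc_freq`. The
#' instantaneous phase implied by the construction (0 at each peak, +/- pi at
#' troughs) is attached as attribute `"phase"`.
#'
#' @param params a [synth_params()] object.
#' @return Numeric vector of `duration * fs` samples, zero mean over whole
#'   cycles, with attribute `phase`.
#' @export
simulate_oscillation <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- floor(params$duration * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  s <- (t * params$osc_freq) %% 1
  x <- shape_template(s, params$rdsym, params$peak_exp, params$trough_exp)
  x <- x - template_cycle_mean(params$rdsym, params$peak_exp, params$trough_exp)
  rising <- s < params$rdsym
  u <- ifelse(rising, s / params$rdsym,
              (s - params$rdsym) / (1 - params$rdsym))
  phase <- ifelse(rising, pi * u - pi, pi * u)
  out <- params$osc_amp * x
  attr(out, "phase") <- phase
  out
}

#' Simulate 1/f aperiodic background noise
#'
#' Spectrally shapes Gaussian white noise so that power falls as
#' `1/f^exponent`; the DC bin is zeroed and the result is standardized to
#' zero mean and unit variance.
#'
#' @param n number of samples (> 1).
#' @param fs sampling rate in Hz.
#' @param exponent spectral exponent chi `>= 0`; 0 returns white noise.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return Numeric vector of length `n`.
#' @export
simulate_aperiodic <- function(n, fs, exponent = 2, seed = NULL) {
  if (n <= 1) cs_abort("n must exceed 1", "parameter")
  if (exponent < 0) cs_abort("exponent must be >= 0", "parameter")
  if (!is.null(seed)) withr::local_seed(seed)
  w <- rnorm(n)
  freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  scale <- c(0, freqs[-1]^(-exponent / 2))
  x <- Re(fft(fft(w) * scale, inverse = TRUE)) / n
  as.numeric((x - mean(x)) / sd(x))
}

#' Inject beta-phase-locked gamma amplitude modulation
#'
#' Returns a gamma carrier whose instantaneous amplitude is proportional to
#' `1 + depth * cos(beta_phase)`, so the gamma envelope peaks at the beta
#' peak (phase 0). The envelope min/max ratio is `(1 - depth)/(1 + depth)`.
#'
#' @param beta_phase phase series in radians (0 at the beta peak).
#' @param gamma_freq carrier frequency in Hz.
#' @param depth modulation fraction m in `[0, 1]`; 0 gives constant
#'   amplitude.
#' @param fs sampling rate in Hz.
#' @param gamma_amp peak envelope amplitude.
#' @return Numeric vector the length of `beta_phase`.
#' @export
inject_pac <- function(beta_phase, gamma_freq, depth, fs, gamma_amp = 1) {
  if (depth < 0 || depth > 1) cs_abort("depth must lie in [0, 1]", "parameter")
  n <- length(beta_phase)
  t <- (seq_len(n) - 1) / fs
  env <- gamma_amp * (1 + depth * cos(beta_phase)) / (1 + depth)
  env * sin(2 * pi * gamma_freq * t)
}

#' Simulate a multichannel recording
#'
#' Each channel carries the same oscillation parameters with an independent
#' noise realization and an independent alpha phase; artifact segments are
#' inserted as high-amplitude broadband bursts at the intervals given in
#' `params$artifact_intervals`, which are also recorded in the returned
#' object as ground truth for masking.
#'
#' @param params a [synth_params()] object.
#' @param channels character vector of channel labels.
#' @param seed integer seed; defaults to `params$seed`.
#' @return An [new_recording()] object.
#' @export
simulate_recording <- function(params, channels = c("C3", "C4"),
                               seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- floor(params$duration * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  osc <- simulate_oscillation(params)
  phase <- attr(osc, "phase")
  mask <- intervals_to_mask(params$artifact_intervals, n)
  data <- matrix(0, nrow = length(channels), ncol = n)
  for (i in seq_along(channels)) {
    x <- as.numeric(osc)
    if (params$alpha_amp > 0) {
      x <- x + params$alpha_amp *
        sin(2 * pi * params$alpha_freq * t + runif(1, 0, 2 * pi))
    }
    if (params$noise_amp > 0) {
      x <- x + params$noise_amp *
        simulate_aperiodic(n, params$fs, params$aperiodic_exp)
    }
    if (params$gamma_amp > 0) {
      x <- x + inject_pac(phase, params$gamma_freq, params$pac_depth,
                          params$fs, params$gamma_amp)
    }
    if (any(mask)) {
      x[mask] <- x[mask] + 10 * params$osc_amp * rnorm(sum(mask))
    }
    data[i, ] <- x
  }
  new_recording(data, fs = params$fs, labels = channels,
                artifact_intervals = params$artifact_intervals)
}

#' Specify a paired two-state synthetic cohort
#'
#' Mirrors a within-subject medication design: every subject is generated in
#' both conditions. Subject-level shape offsets (on `rdsym` and on the
#' sharpening exponents) are drawn once per subject and shared across
#' conditions, so the only systematic off/on difference is the one encoded
#' in the two parameter sets.
#'
#' @param n_subjects number of subjects (>= 2); default 15.
#' @param channels channel labels generated per recording.
#' @param off,on [synth_params()] for the two conditions.
#' @param between_subject_sd standard deviation of the per-subject `rdsym`
#'   offset (also applied, on the log scale, to `peak_exp - 1` and
#'   `trough_exp - 1`).
#' @param seed integer seed; fixed seed reproduces the cohort bit-exactly.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 15, channels = c("C3", "C4"),
                        off = synth_params(), on = synth_params(),
                        between_subject_sd = 0.02, seed = 1) {
  if (n_subjects < 2) cs_abort("n_subjects must be >= 2", "parameter")
  if (!inherits(off, "synth_params") || !inherits(on, "synth_params")) {
    cs_abort("both condition parameter sets must be synth_params objects",
             "configuration")
  }
  structure(
    list(n_subjects = n_subjects, channels = channels,
         state_params = list(off = off, on = on),
         between_subject_sd = between_subject_sd, seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate a paired cohort
#'
#' @param spec a [cohort_spec()] object.
#' @return A tibble with one row per subject-condition: columns `subject`,
#'   `condition` (factor off/on) and `recording` (list column of
#'   `eeg_recording` objects).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)
  rows <- vector("list", spec$n_subjects * 2L)
  k <- 0L
  for (i in seq_len(spec$n_subjects)) {
    d_rdsym <- rnorm(1, 0, spec$between_subject_sd)
    d_exp <- rnorm(2, 0, spec$between_subject_sd)
    for (cond in c("off", "on")) {
      p <- spec$state_params[[cond]]
      p$rdsym <- min(max(p$rdsym + d_rdsym, 0.05), 0.95)
      p$peak_exp <- 1 + (p$peak_exp - 1) * exp(d_exp[1])
      p$trough_exp <- 1 + (p$trough_exp - 1) * exp(d_exp[2])
      rec_seed <- sample.int(.Machine$integer.max, 1)
      k <- k + 1L
      rows[[k]] <- tibble(
        subject = sprintf("S%02d", i),
        condition = cond,
        recording = list(simulate_recording(p, spec$channels, seed = rec_seed))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$condition <- factor(out$condition, levels = c("off", "on"))
  out
}

#' Read generator settings from a YAML configuration file
#'
#' Top-level keys map 1:1 onto [cohort_spec()] arguments; the `off` and `on`
#' blocks map onto [synth_params()]. A file without `n_subjects` is read as a
#' single [synth_params()] block.
#'
#' @param path path to a YAML file.
#' @return A `cohort_spec` or `synth_params` object.
#' @export
read_synth_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses bare `on`/`off` keys as booleans; map them back
  nm <- names(cfg)
  nm[nm == "TRUE"] <- "on"
  nm[nm == "FALSE"] <- "off"
  names(cfg) <- nm
  if (!is.null(cfg$n_subjects)) {
    off <- do.call(synth_params, as.list(cfg$off %||% list()))
    on <- do.call(synth_params, as.list(cfg$on %||% list()))
    args <- cfg[setdiff(names(cfg), c("off", "on"))]
    do.call(cohort_spec, c(args, list(off = off, on = on)))
  } else {
    do.call(synth_params, as.list(cfg))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
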