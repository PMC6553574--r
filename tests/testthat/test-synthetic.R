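test_that("symmetric parameters reproduce a pure sinusoid", {
  p <- noiseless_params(duration = 2)
  x <- simulate_oscillation(p)
  t <- (seq_along(x) - 1) / 512
  expect_lt(max(abs(x - (-cos(2 * pi * 20 * t)))), 1e-9)
})

test_that("rise-decay asymmetry and extremum sharpening have the expected sign", {
  # longer rise (rdsym = 0.7) => shallower rise => rise-to-fall ratio < 0
  sm_rd <- waveform_shape(as.numeric(simulate_oscillation(
    noiseless_params(rdsym = 0.7))), 512)
  expect_lt(sm_rd$rise_fall_ratio, 0)
  # sharpened peaks (peak_exp = 3) => peak-to-trough ratio > 0
  sm_pk <- waveform_shape(as.numeric(simulate_oscillation(
    noiseless_params(peak_exp = 3))), 512)
  expect_gt(sm_pk$peak_trough_ratio, 0)
})

test_that("parameter validation rejects out-of-range shapes", {
  expect_error(synth_params(rdsym = 0), class = "cycleshape_error_parameter")
  expect_error(synth_params(rdsym = 1), class = "cycleshape_error_parameter")
  expect_error(synth_params(peak_exp = 0.5), class = "cycleshape_error_parameter")
  expect_error(synth_params(pac_depth = 1.2), class = "cycleshape_error_parameter")
  expect_error(synth_params(fs = 100, gamma_freq = 80),
               class = "cycleshape_error_parameter")
  expect_error(simulate_aperiodic(1, 512), class = "cycleshape_error_parameter")
  expect_error(inject_pac(runif(10), 80, depth = -0.1, fs = 512),
               class = "cycleshape_error_parameter")
})

test_that("aperiodic noise has the requested spectral exponent", {
  n <- 65536
  white <- simulate_aperiodic(n, 512, exponent = 0, seed = 11)
  r1 <- cor(white[-1], white[-n])
  expect_lt(abs(r1), 0.05)
  pink <- simulate_aperiodic(n, 512, exponent = 2, seed = 11)
  expect_equal(mean(pink), 0, tolerance = 1e-12)
  expect_equal(sd(pink), 1, tolerance = 1e-12)
  psd <- welch_psd(pink, 512)
  sel <- psd$freq >= 1 & psd$freq <= 100
  slope <- coef(lm(log(power) ~ log(freq), data = psd[sel, ]))[2]
  expect_lt(abs(slope - (-2)), 0.2)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(simulate_aperiodic(1024, 512, 1.5, seed = 3),
                   simulate_aperiodic(1024, 512, 1.5, seed = 3))
  p <- synth_params(duration = 4, seed = 9)
  r1 <- simulate_recording(p)
  r2 <- simulate_recording(p)
  expect_identical(r1$data, r2$data)
  spec <- cohort_spec(n_subjects = 2,
                      off = synth_params(duration = 4, rdsym = 0.45),
                      on = synth_params(duration = 4), seed = 5)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$recording[[1]]$data, c2$recording[[1]]$data)
  expect_identical(c1$recording[[4]]$data, c2$recording[[4]]$data)
})

test_that("gamma envelope follows the requested modulation depth", {
  phase <- seq(-pi, pi, length.out = 4097)[-1]
  for (m in c(0.2, 0.5, 1)) {
    env <- (1 + m * cos(phase)) / (1 + m)
    y <- inject_pac(phase, gamma_freq = 80, depth = m, fs = 512)
    expect_equal(min(env) / max(env), (1 - m) / (1 + m), tolerance = 1e-12)
    expect_lte(max(abs(y)), max(env) + 1e-12)
  }
})

test_that("modulation index increases with injected coupling depth", {
  p0 <- synth_params(duration = 40, pac_depth = 0, alpha_amp = 0,
                     noise_amp = 0, gamma_amp = 0.4, seed = 2)
  mk <- function(depth) {
    p <- p0
    p$pac_depth <- depth
    osc <- simulate_oscillation(p)
    x <- as.numeric(osc) + inject_pac(attr(osc, "phase"), p$gamma_freq,
                                      depth, p$fs, p$gamma_amp)
    pac_mi(x, p$fs)$mi
  }
  mis <- vapply(c(0, 0.3, 0.6, 1), mk, numeric(1))
  expect_true(all(diff(mis) > 0))
  expect_lt(mis[1], 0.01)
})

test_that("steepness ratio grows with rise-decay asymmetry (monotone grid)", {
  grid <- seq(0.50, 0.20, by = -0.05)
  str <- vapply(grid, function(rd) {
    waveform_shape(as.numeric(simulate_oscillation(
      noiseless_params(duration = 8, rdsym = rd))), 512)$steepness_ratio
  }, numeric(1))
  expect_gt(cor(abs(grid - 0.5), str, method = "spearman"), 0.9)
})

test_that("cohorts are paired and carry the state effect", {
  spec <- cohort_spec(n_subjects = 3,
                      off = synth_params(duration = 4, rdsym = 0.42),
                      on = synth_params(duration = 4, rdsym = 0.48),
                      seed = 8)
  ch <- simulate_cohort(spec)
  expect_equal(nrow(ch), 6)
  expect_true(all(table(ch$subject) == 2))
  expect_s3_class(ch$recording[[1]], "eeg_recording")
  expect_error(cohort_spec(n_subjects = 1), class = "cycleshape_error_parameter")
  expect_error(cohort_spec(off = list()),
               class = "cycleshape_error_configuration")
})

test_that("artifact bursts are inserted at the ground-truth intervals", {
  p <- synth_params(duration = 4, noise_amp = 0.1, alpha_amp = 0,
                    gamma_amp = 0, artifact_intervals = list(c(500, 700)),
                    seed = 4)
  rec <- simulate_recording(p, channels = "C3")
  x <- rec$data[1, ]
  expect_gt(sd(x[500:699]), 3 * sd(x[900:1099]))
  expect_equal(unname(rec$artifact_intervals[1, ]), c(500L, 700L))
})

test_that("YAML configuration maps onto generator parameters", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_subjects: 4",
    "between_subject_sd: 0.01",
    "seed: 3",
    "off:",
    "  duration: 6",
    "  rdsym: 0.42",
    "on:",
    "  duration: 6",
    "  rdsym: 0.48"
  ), cfg)
  spec <- read_synth_config(cfg)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_subjects, 4)
  expect_equal(spec$state_params$off$rdsym, 0.42)
  expect_equal(spec$state_params$on$rdsym, 0.48)
})
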