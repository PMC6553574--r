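test_that("band-pass tap count follows the millisecond order rule", {
  expect_equal(cycleshape:::taps_from_ms(231, 512), 119L)  # round(118.272) -> odd
  expect_equal(cycleshape:::taps_from_ms(240, 512), 123L)  # round(122.88) -> odd
})

test_that("band-pass frequency response passes beta and rejects out-of-band", {
  fs <- 512
  t <- (seq_len(10 * fs) - 1) / fs
  mid <- seq.int(2 * fs, 8 * fs)
  y20 <- bandpass_fir(sin(2 * pi * 20 * t), fs)
  expect_lt(abs(max(abs(y20[mid])) - 1), 0.05)
  y5 <- bandpass_fir(sin(2 * pi * 5 * t), fs)
  expect_lt(max(abs(y5[mid])), 0.05)
  expect_error(bandpass_fir(sin(t), fs, band_spec(13, 300)),
               class = "cycleshape_error_parameter")
})

test_that("zerocrossing detection follows the sign-change rule", {
  zc <- find_zerocrossings(c(-1, 1, -1))
  expect_equal(zc$rising, 1L)
  expect_equal(zc$falling, 2L)
  none <- find_zerocrossings(c(1, 1, 1))
  expect_length(none$rising, 0)
  expect_length(none$falling, 0)
  # exact zero counts as nonnegative
  zc0 <- find_zerocrossings(c(-1, 0, -1))
  expect_equal(zc0$rising, 1L)
  expect_equal(zc0$falling, 2L)
  # one full cycle starting at the trough: one rising, one falling crossing
  xs <- -cos(2 * pi * (0:63) / 64)
  zs <- find_zerocrossings(xs)
  expect_length(zs$rising, 1)
  expect_length(zs$falling, 1)
})

test_that("extrema are located in the raw signal with first-wins ties", {
  x <- c(0, 1, 3, 1, 0)
  ex <- locate_extrema(x, rising = 1L, falling = 5L)
  expect_equal(ex$peaks, 3L)
  xp <- c(0, 2, 2, 0)
  exp_ <- locate_extrema(xp, rising = 1L, falling = 4L)
  expect_equal(exp_$peaks, 2L)  # first index wins
  # noiseless 20 Hz sine, 10 s: ~200 peaks and troughs
  fs <- 512
  s <- as.numeric(simulate_oscillation(noiseless_params(duration = 10)))
  sf <- bandpass_fir(s, fs)
  zc <- find_zerocrossings(sf)
  ex2 <- locate_extrema(s, zc$rising, zc$falling)
  expect_true(abs(length(ex2$peaks) - 200) <= 1)
  expect_true(abs(length(ex2$troughs) - 200) <= 1)
})

test_that("sharpness and steepness match closed-form values", {
  tri <- c(0, 1, 2, 3, 2, 1, 0)
  expect_equal(extrema_sharpness(tri, 4L, 3L, "peak"), 3)
  expect_equal(extrema_sharpness(-tri, 4L, 3L, "trough"), 3)
  expect_true(is.na(extrema_sharpness(tri, 2L, 3L, "peak")))  # too near edge
  expect_equal(segment_steepness(c(0, 1, 3, 4), 1L, 4L, "rise"), 2)
  expect_equal(segment_steepness(c(4, 1, 0), 1L, 3L, "decay"), 3)
  ramp <- seq(0, 10, by = 0.25)
  expect_equal(segment_steepness(ramp, 5L, 30L, "rise"), 0.25)
  expect_true(is.na(segment_steepness(ramp, 5L, 5L, "rise")))
})

test_that("shape metric arithmetic and quadrant labels are correct", {
  tbl <- tibble::tibble(
    rise_zc = 1:6, peak_idx = 1:6, fall_zc = 1:6, trough_idx = 1:6,
    peak_sharp = rep(2, 6), trough_sharp = rep(1, 6),
    rise_steep = rep(1, 6), decay_steep = rep(1, 6), valid = TRUE
  )
  sm <- shape_metrics(tbl)
  expect_equal(sm$peak_trough_ratio, log(2))
  expect_equal(sm$sharpness_ratio, log(2))
  expect_equal(sm$rise_fall_ratio, 0)
  expect_equal(sm$steepness_ratio, 0)
  expect_equal(sm$quadrant, "boundary")
  # quadrant from the sign pair
  q4 <- shape_metrics(dplyr::mutate(tbl, decay_steep = 2))
  expect_equal(q4$quadrant, "Q4")
  q2 <- shape_metrics(dplyr::mutate(tbl, peak_sharp = 0.5, decay_steep = 0.5))
  expect_equal(q2$quadrant, "Q2")
  # too few cycles -> undefined with a classed warning
  expect_warning(out <- shape_metrics(tbl[1:3, ]),
                 class = "cycleshape_warning_undefined_metric")
  expect_true(is.na(out$sharpness_ratio))
})

test_that("naive loop-based oracle reproduces the pipeline cycle table", {
  x <- asym_noisy_signal(duration = 10, seed = 21)
  got <- cycle_features(x, 512)
  want <- oracle_cycle_table(x, 512)
  expect_identical(got$peak_idx, want$peak_idx)
  expect_identical(got$trough_idx, want$trough_idx)
  expect_identical(got$rise_zc, want$rise_zc)
  expect_identical(got$fall_zc, want$fall_zc)
  for (col in c("peak_sharp", "trough_sharp", "rise_steep", "decay_steep")) {
    expect_equal(got[[col]], want[[col]], tolerance = 1e-12)
  }
  expect_identical(got$valid, want$valid)
})

test_that("shape ratios obey negation, reversal and scaling symmetries", {
  for (seed in c(3, 17)) {
    x <- asym_noisy_signal(duration = 10, seed = seed)
    base <- waveform_shape(x, 512)
    neg <- waveform_shape(-x, 512)
    expect_equal(neg$peak_trough_ratio, -base$peak_trough_ratio,
                 tolerance = 1e-9)
    expect_equal(neg$rise_fall_ratio, -base$rise_fall_ratio,
                 tolerance = 1e-9)
    expect_equal(neg$sharpness_ratio, base$sharpness_ratio, tolerance = 1e-9)
    expect_equal(neg$steepness_ratio, base$steepness_ratio, tolerance = 1e-9)
    revd <- waveform_shape(rev(x), 512)
    expect_equal(revd$rise_fall_ratio, -base$rise_fall_ratio,
                 tolerance = 1e-9)
    expect_equal(revd$peak_trough_ratio, base$peak_trough_ratio,
                 tolerance = 1e-9)
    scaled <- waveform_shape(3.7 * x, 512)
    for (col in c("peak_trough_ratio", "rise_fall_ratio", "sharpness_ratio",
                  "steepness_ratio")) {
      expect_equal(scaled[[col]], base[[col]], tolerance = 1e-9)
    }
  }
})

test_that("sharpness ratio is robust to the width parameter (rank order)", {
  grid <- seq(1, 2.5, by = 0.25)
  srs <- sapply(c(2L, 3L, 4L), function(w) {
    vapply(grid, function(pe) {
      waveform_shape(as.numeric(simulate_oscillation(
        noiseless_params(duration = 6, peak_exp = pe))), 512,
        width = w)$sharpness_ratio
    }, numeric(1))
  })
  expect_gt(cor(srs[, 1], srs[, 2], method = "spearman"), 0.9)
  expect_gt(cor(srs[, 2], srs[, 3], method = "spearman"), 0.9)
})

test_that("cycles touching artifact intervals are invalidated, others not", {
  x <- asym_noisy_signal(duration = 10, seed = 5)
  iv <- list(c(2000, 2400))
  clean <- cycle_features(x, 512)
  masked <- cycle_features(x, 512, artifact_intervals = iv)
  expect_equal(nrow(clean), nrow(masked))
  in_iv <- !is.na(masked$peak_idx) &
    masked$peak_idx >= 2000 & masked$peak_idx < 2400
  expect_true(all(is.na(masked$peak_sharp[in_iv])))
  expect_true(all(!masked$valid[in_iv]))
  far <- !is.na(masked$peak_idx) &
    (masked$peak_idx < 1500 | masked$peak_idx > 3000)
  expect_identical(masked$peak_sharp[far], clean$peak_sharp[far])
  expect_gt(sum(masked$valid), 0)
})
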