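rec_from <- function(mat, labels, fs = 512, ...) {
  new_recording(mat, fs = fs, labels = labels, ...)
}

test_that("demean plus common average reference behaves on canonical cases", {
  # constant channels vanish
  r <- rec_from(rbind(rep(5, 4), rep(1, 4)), c("A", "B"))
  out <- reference_average(r)
  expect_equal(max(abs(out$data)), 0)
  # antisymmetric channels are untouched (common term is zero)
  x <- sin(seq(0, 6, length.out = 100))
  r2 <- rec_from(rbind(x, -x), c("A", "B"))
  out2 <- reference_average(r2)
  expect_equal(out2$data[1, ], x - mean(x), tolerance = 1e-14)
  # referenced good channels average to zero at every sample
  set.seed(1)
  r3 <- rec_from(matrix(rnorm(300), 3), c("A", "B", "C"))
  out3 <- reference_average(r3)
  expect_lt(max(abs(colMeans(out3$data))), 1e-12)
})

test_that("average reference is idempotent and respects bad channels", {
  set.seed(2)
  r <- rec_from(matrix(rnorm(400), 4), c("A", "B", "C", "D"),
                bad_channels = "D")
  once <- reference_average(r)
  twice <- reference_average(once)
  expect_equal(once$data["A", ], twice$data["A", ], tolerance = 1e-12)
  expect_identical(once$data["D", ], r$data["D", ])  # passed through
  r2 <- rec_from(matrix(rnorm(200), 2), c("A", "B"), bad_channels = "B")
  expect_error(reference_average(r2), class = "cycleshape_error_reference")
})

test_that("bipolar referencing derives, negates and validates pairs", {
  r <- rec_from(rbind(c(1, 2), c(1, 1)), c("C3", "CP1"))
  out <- reference_bipolar(r, list(c("C3", "CP1")))
  expect_equal(unname(out$data[1, ]), c(0, 1))
  expect_equal(out$labels, "C3-CP1")
  same <- reference_bipolar(r, list(c("C3", "C3")))
  expect_equal(max(abs(same$data)), 0)
  swapped <- reference_bipolar(r, list(c("CP1", "C3")))
  expect_equal(swapped$data[1, ], -out$data[1, ])
  expect_error(reference_bipolar(r, list(c("C3", "CP2"))),
               class = "cycleshape_error_lookup")
})

test_that("zero-phase high-pass rejects DC and drift but not the passband", {
  fs <- 512
  n <- 30 * fs
  t <- (seq_len(n) - 1) / fs
  mid <- seq.int(floor(n / 3), ceiling(2 * n / 3))
  # DC rejection
  out <- filter_highpass(rec_from(matrix(1, 1, n), "A", fs))
  expect_lt(max(abs(out$data[1, mid])), 1e-6)
  # passband: 20 Hz sine essentially untouched, zero phase shift
  s20 <- sin(2 * pi * 20 * t)
  y <- filter_highpass(rec_from(matrix(s20, 1), "A", fs))$data[1, ]
  fit <- lm(y[mid] ~ sin(2 * pi * 20 * t[mid]) + cos(2 * pi * 20 * t[mid]) - 1)
  amp <- sqrt(sum(coef(fit)^2))
  phase_shift <- atan2(coef(fit)[2], coef(fit)[1])
  expect_lt(abs(amp - 1), 0.01)
  expect_lt(abs(phase_shift), 1e-3)
  # stopband: 0.05 Hz drift attenuated by more than 20 dB
  n2 <- 120 * fs
  t2 <- (seq_len(n2) - 1) / fs
  slow <- sin(2 * pi * 0.05 * t2)
  y2 <- filter_highpass(rec_from(matrix(slow, 1), "A", fs))$data[1, ]
  mid2 <- seq.int(floor(n2 / 3), ceiling(2 * n2 / 3))
  expect_lt(max(abs(y2[mid2])), 10^(-20 / 20))
})

test_that("two-way filtering commutes with time reversal", {
  x <- asym_noisy_signal(duration = 20)
  fs <- 512
  y <- filter_highpass(rec_from(matrix(x, 1), "A", fs))$data[1, ]
  yr <- filter_highpass(rec_from(matrix(rev(x), 1), "A", fs))$data[1, ]
  expect_lt(max(abs(yr - rev(y))), 1e-9)
})

test_that("interval normalization merges, drops and stays idempotent", {
  expect_equal(unname(normalize_intervals(list(c(10, 20), c(15, 30)))[1, ]),
               c(10L, 30L))
  expect_equal(nrow(normalize_intervals(NULL)), 0)
  expect_equal(nrow(normalize_intervals(list(c(5, 5)))), 0)
  iv <- list(c(40, 50), c(10, 20), c(15, 30))
  a <- normalize_intervals(iv)
  expect_identical(normalize_intervals(a), a)
  expect_identical(normalize_intervals(rev(iv)), a)
  # touching intervals merge; clipping respects recording length
  expect_equal(nrow(normalize_intervals(list(c(1, 10), c(10, 20)))), 1)
  clipped <- normalize_intervals(list(c(90, 200)), n_samples = 100)
  expect_equal(unname(clipped[1, ]), c(90L, 101L))
  expect_error(normalize_intervals(list(c(20, 10))),
               class = "cycleshape_error_interval")
})

test_that("channel composites average available channels only", {
  expect_equal(composite_channels(c(C3 = 0.4, C4 = 0.6)), 0.5)
  expect_equal(composite_channels(c(C3 = 0.4, C4 = NA)), 0.4)
  expect_true(is.na(composite_channels(c(C3 = NA, C4 = NA))))
  expect_true(is.na(composite_channels(c(F7 = 1))))
})

test_that("recordings survive a text round trip", {
  p <- synth_params(duration = 2, seed = 6,
                    artifact_intervals = list(c(100, 200)))
  rec <- simulate_recording(p)
  rec$bad_channels <- character(0)
  prefix <- tempfile()
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$artifact_intervals, rec$artifact_intervals)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
})
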