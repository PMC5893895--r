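test_that("pure tones follow the closed-form sample law", {
  s <- pure_tone(400, duration = 6, sample_rate = 8000)
  expect_length(s$samples, 48000)
  # 400 Hz at 8000 samples/s: 20-sample period, 2400 full cycles in 6 s
  expect_equal(s$samples[1 + 20], s$samples[1], tolerance = 1e-12)
  expect_equal(400 * 6, 2400)
  # quarter period: sample n = 5 is sin(2*pi*0.25) = 1
  expect_equal(s$samples[6], 1)
  expect_equal(pure_tone(0, 1, 8000)$samples, rep(0, 8000))
  # amplitude and phase are honored
  s2 <- pure_tone(100, 0.1, 8000, amplitude = 0.3, phase = pi / 2)
  expect_equal(s2$samples[1], 0.3)
  expect_lte(max(abs(s2$samples)), 0.3 + 1e-12)
})

test_that("tone spec validation rejects bad inputs", {
  expect_error(pure_tone(4000, 1, 8000), "Nyquist")
  expect_error(pure_tone(5000, 1, 8000), "Nyquist")
  expect_error(pure_tone(400, 0, 8000), "duration")
  expect_error(pure_tone(-1, 1, 8000), "non-negative")
  expect_error(tone_signal(1:5, 8000, ratio_trajectory = 1:4), "same length")
})

test_that("mono mixing is the per-sample mean", {
  x <- pure_tone(400, 0.5)
  expect_equal(mix_mono(x, x)$samples, x$samples)
  neg <- tone_signal(-x$samples, 8000)
  expect_equal(mix_mono(x, neg)$samples, rep(0, length(x$samples)))
  # product-to-sum: mean of 400 and 403 Hz unit tones has envelope
  # |cos(pi * 3 * t)| around carrier 401.5 Hz
  y <- mix_mono(pure_tone(400, 1), pure_tone(403, 1))
  t <- (seq_along(y$samples) - 1) / 8000
  expect_equal(y$samples, sin(2 * pi * 401.5 * t) * cos(pi * 3 * t),
               tolerance = 1e-12)
  expect_error(mix_mono(x, pure_tone(400, 0.25)), "length mismatch")
  expect_error(mix_mono(x, tone_signal(numeric(4000), 4000)),
               "rate mismatch")
})

test_that("mistuned intervals place the second tone at (p/q) f1 + epsilon", {
  a <- mistuned_interval(400, 1, 1, epsilon = 3, duration = 0.5)
  b <- mix_mono(pure_tone(400, 0.5), pure_tone(403, 0.5))
  expect_equal(a$samples, b$samples)
  o <- mistuned_interval(400, 2, 1, epsilon = 3, duration = 0.5)
  b2 <- mix_mono(pure_tone(400, 0.5), pure_tone(803, 0.5))
  expect_equal(o$samples, b2$samples)
  # perfectly tuned fifth: static pattern, period exactly 1/200 s
  f <- mistuned_interval(400, 3, 2, epsilon = 0, duration = 0.5)
  expect_equal(f$samples[41:80], f$samples[1:40], tolerance = 1e-12)
  expect_equal(attr(o, "mistuning"), list(p = 2, q = 1, epsilon = 3))
  expect_error(mistuned_interval(400, 1.5, 2, duration = 1),
               "positive integers")
})

test_that("glissando mix carries a linear ratio trajectory", {
  g <- glissando_mix()
  expect_length(g$samples, 48000)
  expect_equal(range(g$ratio_trajectory), c(0.9, 2.1))
  expect_equal(g$ratio_trajectory[24000], 1.5, tolerance = 1e-4)
  expect_true(all(diff(g$ratio_trajectory) > 0))
  # degenerate chirp reduces to a two-fixed-tone mixture
  d <- glissando_mix(500, 500, 400, duration = 0.5)
  ref <- mix_mono(pure_tone(500, 0.5), pure_tone(400, 0.5))
  expect_equal(d$samples, ref$samples, tolerance = 1e-12)
  expect_equal(d$ratio_trajectory, rep(1.25, 4000))
  expect_error(glissando_mix(fixed_frequency = 0), "positive")
})

test_that("chirp instantaneous frequency matches the linear law", {
  ch <- linear_chirp(360, 840, 6, 8000)
  ph <- Arg(recurtone:::analytic_signal(ch$samples))
  f_inst <- diff(ph %% (2 * pi))
  f_inst <- (f_inst %% (2 * pi)) * 8000 / (2 * pi)
  n <- length(f_inst)
  target <- 360 + (840 - 360) * (seq_len(n) - 0.5) / (48000 - 1)
  # the analytic-signal estimator itself ripples near the ends (slowly
  # decaying Fresnel transients), so the law is checked on the central 60%
  core <- seq.int(floor(n * 0.2), ceiling(n * 0.8))
  expect_lt(max(abs(f_inst[core] - target[core])), 0.1)
})

test_that("signal amplitude bounds hold for tones and mixtures", {
  for (f in c(100, 333, 1234)) {
    s <- pure_tone(f, 0.3, amplitude = 0.7)
    expect_lte(max(abs(s$samples)), 0.7 + 1e-12)
  }
  m <- mistuned_interval(400, 3, 2, 3, duration = 0.3, amplitude = 1)
  expect_lte(max(abs(m$samples)), 1 + 1e-12)
})

test_that("text round-trips are exact and malformed files fail loudly", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  sig <- tone_signal(worked_series(), 8000)
  write_signal(sig, tmp)
  back <- read_signal(tmp)
  expect_identical(back$samples, as.numeric(worked_series()))
  expect_equal(back$sample_rate, 8000)
  # fractional values round-trip exactly too
  s2 <- pure_tone(123.4, 0.05, 8000)
  write_signal(s2, tmp)
  expect_identical(read_signal(tmp)$samples, s2$samples)
  # malformed line reported with its line number
  writeLines(c("# rate=8000", "0.5", "oops", "0.25"), tmp)
  expect_error(read_signal(tmp), "line 3")
  writeLines(character(0), tmp)
  expect_error(read_signal(tmp), "empty")
})

test_that("WAV round-trip is exact up to 16-bit quantization", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  s <- pure_tone(440, 0.25, 8000)
  write_signal(s, tmp)
  back <- read_signal(tmp)
  expect_equal(back$sample_rate, 8000)
  expect_length(back$samples, length(s$samples))
  expect_lt(max(abs(back$samples - s$samples)), 2^-15 + 1e-9)
  # format dispatch by extension is overridable
  expect_error(suppressWarnings(read_signal(tmp, format = "text")))
})
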