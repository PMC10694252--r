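test_that("filterbank edges are geometrically spaced", {
  fb <- design_filterbank(vocoder_config())
  # independent closed form: f_k = 80 * (8000/80)^(k/6)
  expect_equal(fb$edges_hz, 80 * 100^((0:6) / 6), tolerance = 1e-12)
  expect_equal(design_filterbank(vocoder_config(n_channels = 1))$edges_hz,
               c(80, 8000))
  expect_equal(design_filterbank(
    vocoder_config(n_channels = 2, f_lo_hz = 100, f_hi_hz = 1600))$edges_hz,
    c(100, 400, 1600))
  # consecutive-edge ratios all equal
  r <- diff(log(fb$edges_hz))
  expect_lt(max(abs(r - r[1])) / r[1], 1e-9)
  expect_error(vocoder_config(f_lo_hz = 500, f_hi_hz = 100), "f_lo")
})

test_that("upper edge is capped near Nyquist with a warning", {
  cfg <- vocoder_config()
  expect_warning(fb <- design_filterbank(cfg, rate_hz = 16000), "Nyquist")
  expect_equal(max(fb$edges_hz), 0.95 * 8000)
})

test_that("bandpass is linear, unity-gain in band, and validates its band", {
  z <- audio_signal(numeric(1000), 44100)
  expect_equal(bandpass(z, 300, 600)$samples, numeric(1000))
  # sinusoid at geometric band centre passes at ~unity gain
  lo <- 800; hi <- 1723.5
  tone <- make_tone(sqrt(lo * hi), dur_s = 1)
  out <- discard_transient(bandpass(tone, lo, hi, 3))
  inn <- discard_transient(tone)
  expect_lt(abs(signal_rms(out) - signal_rms(inn)) / signal_rms(inn), 0.05)
  expect_error(bandpass(tone, 300, 30000), "Nyquist")
  expect_error(bandpass(tone, -10, 500), "Nyquist")
})

test_that("measured rolloff matches 6 dB/octave per filter pole", {
  expect_equal(measure_rolloff(800, 1723.5, 3, 44100), 18, tolerance = 1.5 / 18)
  expect_equal(measure_rolloff(800, 1723.5, 1, 44100), 6, tolerance = 1 / 6)
  expect_equal(measure_rolloff(800, 1723.5, 4, 44100), 24, tolerance = 2 / 24)
  expect_error(measure_rolloff(8000, 15000, 3, 44100), "Nyquist")
})

test_that("envelope extraction recovers amplitude structure", {
  cfg <- vocoder_config()
  z <- audio_signal(numeric(2000), 44100)
  expect_equal(extract_envelope(z, cfg)$samples, numeric(2000))

  # constant-amplitude carrier -> constant envelope, proportional to amplitude
  e1 <- discard_transient(extract_envelope(make_tone(1000, amp = 0.2), cfg))
  e2 <- discard_transient(extract_envelope(make_tone(1000, amp = 0.4), cfg))
  # order-2 low-pass at 300 Hz leaves ~10% residual carrier ripple at 1 kHz
  expect_lt(sd(e1$samples) / mean(e1$samples), 0.15)
  expect_equal(mean(e2$samples) / mean(e1$samples), 2, tolerance = 0.02)
  expect_true(all(e1$samples >= 0))

  # AM tone: envelope tracks the analytic modulator
  am <- make_am_tone(1000, 10, depth = 0.8)
  env <- extract_envelope(am, cfg)
  keep <- seq(floor(0.05 * am$rate_hz) + 1, length(am$samples))
  t <- (keep - 1) / am$rate_hz
  modulator <- 1 + 0.8 * sin(2 * pi * 10 * t)
  expect_gt(cor(env$samples[keep], modulator), 0.95)
  # cross-check against a Hilbert-magnitude envelope
  expect_gt(cor(env$samples[keep], hilbert_env(am)[keep]), 0.9)
})

test_that("vocode conserves RMS, is seed-deterministic, and passes silence", {
  cfg <- vocoder_config(rng_seed = 7)
  sil <- audio_signal(numeric(4410), 44100)
  expect_equal(vocode(sil, cfg)$samples, numeric(4410))

  for (x in list(make_tone(500, dur_s = 0.5),
                 make_am_tone(1200, 6, dur_s = 0.5),
                 speech_like())) {
    y <- vocode(x, vocoder_config(rng_seed = 7))
    expect_lt(abs(signal_rms(y) - signal_rms(x)) / signal_rms(x), 1e-3)
  }

  x <- make_am_tone(800, 8, dur_s = 0.3)
  y1 <- vocode(x, cfg)
  y2 <- vocode(x, cfg)
  expect_identical(y1$samples, y2$samples)
  y3 <- vocode(x, vocoder_config(rng_seed = 8))
  expect_false(identical(y1$samples, y3$samples))
})

test_that("vocoded energy stays in the analysis range and near its channel", {
  fb <- design_filterbank(vocoder_config())$edges_hz
  # input confined inside channel 3 (371-800 Hz)
  x <- brickwall_noise(450, 700, dur_s = 2, seed = 5)
  y <- vocode(x, vocoder_config(rng_seed = 3))
  fracs <- vapply(1:6, function(k)
    band_energy_fraction(y, fb[k], fb[k + 1]), numeric(1))
  expect_equal(which.max(fracs), 3)           # channel 3 dominates
  expect_gt(fracs[3], 0.5)
  expect_gt(sum(fracs[2:4]), 0.9)             # neighbourhood confinement
  # global confinement invariant, for several input types
  for (x in list(speech_like(rate = 44100, dur_s = 1),
                 make_am_tone(3000, 12, dur_s = 1))) {
    y <- vocode(x, vocoder_config(rng_seed = 2))
    expect_gt(band_energy_fraction(y, 80 * 0.9, 8000 * 1.1), 0.95)
  }
})

test_that("vocoding preserves slow temporal envelopes (fidelity > 0.8)", {
  fb <- design_filterbank(vocoder_config())$edges_hz
  cfg <- vocoder_config(rng_seed = 4)
  # compare envelopes in the modulation band of interest (<= ~60 Hz): the
  # noise carrier contributes intrinsic envelope fluctuations above that
  smooth60 <- function(sig) {
    lp <- signal::butter(2, 60 / (sig$rate_hz / 2), type = "low")
    as.numeric(signal::filter(lp, sig$samples))
  }
  for (mod_hz in c(4, 20, 50)) {
    x <- make_am_tone(1200, mod_hz, depth = 0.8, dur_s = 1)
    y <- vocode(x, cfg)
    # envelope of the analysis band containing the carrier (800-1723 Hz)
    ex <- smooth60(extract_envelope(bandpass(x, fb[4], fb[5]), cfg))
    ey <- smooth60(extract_envelope(bandpass(y, fb[4], fb[5]), cfg))
    keep <- seq(floor(0.15 * x$rate_hz) + 1, length(x$samples))
    expect_gt(cor(ex[keep], ey[keep]), 0.8)
  }
})

test_that("spectral similarity to the input is non-decreasing in channels", {
  x <- speech_like()
  ls_in <- log_band_spectrum(x)
  sims <- vapply(c(1, 2, 6, 16), function(nc) {
    y <- vocode(x, vocoder_config(n_channels = nc, rng_seed = 5))
    cosine_sim(ls_in, log_band_spectrum(y))
  }, numeric(1))
  expect_true(all(diff(sims) > -0.02))  # monotone within Monte-Carlo slack
  expect_gt(sims[4], sims[1])
})
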