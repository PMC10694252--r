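# signal fixtures ------------------------------------------------------------

make_tone <- function(freq_hz, dur_s = 0.5, rate = 44100, amp = 0.5) {
  t <- seq(0, dur_s, by = 1 / rate)
  audio_signal(amp * sin(2 * pi * freq_hz * t), rate)
}

make_am_tone <- function(freq_hz, mod_hz, depth = 0.8, dur_s = 1,
                         rate = 44100, amp = 0.5) {
  t <- seq(0, dur_s, by = 1 / rate)
  audio_signal(amp * (1 + depth * sin(2 * pi * mod_hz * t)) *
                 sin(2 * pi * freq_hz * t), rate)
}

# ideal (brick-wall) band-limited Gaussian noise, via FFT masking
brickwall_noise <- function(lo_hz, hi_hz, dur_s = 2, rate = 44100, seed = 1) {
  n <- round(dur_s * rate)
  x <- withr::with_seed(seed, rnorm(n))
  X <- stats::fft(x)
  f <- pmin((0:(n - 1)) * rate / n, rate - (0:(n - 1)) * rate / n)
  X[f < lo_hz | f > hi_hz] <- 0
  audio_signal(Re(stats::fft(X, inverse = TRUE) / n), rate)
}

# speech-like fixture: sloped spectrum with formant-like peaks, 4 Hz AM
speech_like <- function(rate = 22050, dur_s = 1, seed = 11) {
  n <- round(dur_s * rate)
  x <- withr::with_seed(seed, rnorm(n))
  X <- stats::fft(x)
  f <- pmin((0:(n - 1)) * rate / n, rate - (0:(n - 1)) * rate / n)
  shape <- ifelse(f < 80 | f > 8000, 0, 1 / sqrt(pmax(f, 100)))
  shape <- shape * (1 + 2 * exp(-((f - 500) / 200)^2) +
                      1.5 * exp(-((f - 1500) / 300)^2) +
                      exp(-((f - 2500) / 400)^2))
  s <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  t <- (0:(n - 1)) / rate
  s <- s * (1 + 0.6 * sin(2 * pi * 4 * t))
  audio_signal(s / sqrt(mean(s^2)) * 0.1, rate)
}

# log band-energy spectrum over fine log-spaced bands, and cosine similarity
log_band_spectrum <- function(sig, n_bands = 18) {
  eb <- 80 * (8000 / 80)^((0:n_bands) / n_bands)
  log(vapply(seq_len(n_bands), function(k)
    band_energy_fraction(sig, eb[k], eb[k + 1]) + 1e-12, numeric(1)))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# analytic-signal magnitude (Hilbert envelope) as an independent envelope oracle
hilbert_env <- function(sig) {
  x <- sig$samples
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# scoring fixtures ------------------------------------------------------------

toy_bank <- function() {
  assign_levels(proposition_bank(
    "toy-tavern",
    propositions = list(
      list(id = "P1", predicate = "sail", args = "captain"),
      list(id = "P2", predicate = "storm", args = "sea"),
      list(id = "P3", predicate = "brave", args = c("P1", "captain")),
      list(id = "P4", predicate = "old", args = "P2"),
      list(id = "P5", predicate = "grey", args = c("P3", "beard")),
      list(id = "P6", predicate = "howl", args = "wind")),
    roots = c("P1", "P2"),
    synonyms = list(storm = c("tempest", "gale"), captain = "skipper")))
}

toy_passages <- function() default_passages()

# acceptance-style replicate loop: five marginal contrasts + the two slopes
replicate_contrasts <- function(seeds, calibration = effect_calibration()) {
  vapply(seeds, function(s) {
    sim <- simulate_study(calibration = calibration, seed = s)
    c(pred = marginal_effect(sim$trials, "predictability", n_boot = 0)$estimate,
      main_mid = marginal_effect(sim$trials, "hierarchy",
                                 levels = c("main", "mid"),
                                 n_boot = 0)$estimate,
      mid_detail = marginal_effect(sim$trials, "hierarchy",
                                   levels = c("mid", "detail"),
                                   n_boot = 0)$estimate,
      format = marginal_effect(sim$trials, "format", n_boot = 0)$estimate,
      clarity = marginal_effect(sim$trials, "clarity", n_boot = 0)$estimate,
      slope_high = hierarchy_slope(sim$trials, predictability = "high"),
      slope_low = hierarchy_slope(sim$trials, predictability = "low"))
  }, numeric(7))
}

# hand-made cell table from explicit per-cell proportions
manual_cell_table <- function(df) {
  df$n_props <- df$n_props %||% 10L
  df$n_recalled <- round(df$proportion * df$n_props)
  df$proportion <- df$n_recalled / df$n_props
  class(df) <- c("cell_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
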