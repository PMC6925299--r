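# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

fixture_formants <- function() default_formant_table()

# predictor table computed from synthesized tokens at a light sample rate
fixture_predictors <- function() {
  memo("predictors", function() {
    pair_predictors(fixture_formants(), fs = 22050, duration = 0.5)
  })
}

# the 7 processed tokens at the full 44.1 kHz rate (pitch- and
# envelope-flattened), as the stimulus chain produces them
fixture_tokens_flat <- function() {
  memo("tokens_flat", function() {
    tab <- fixture_formants()
    lapply(seq_len(nrow(tab)), function(i) {
      tk <- synthesize_vowel(tab[i, ], f0 = 185, duration = 1.5, fs = 44100)
      tk <- flatten_pitch(tk, 185)
      flatten_envelope(tk, target_rms = 0.1)
    })
  })
}

# Discrete analytic-signal envelope (Hilbert magnitude) -- measurement
# oracle, independent of the package's rectify-and-smooth envelope.
hilbert_env <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Long-term-spectrum peak frequency: Welch power spectrum smoothed with a
# Gaussian kernel wider than the harmonic spacing, then peak-picked.
# FFT-based oracle for the spectral-envelope peak of synthetic vowels.
spectral_peak <- function(x, fs, smooth_hz, fmax = 2000, nfft = 8192) {
  ps <- accmap:::welch_psd(x, fs, nfft = nfft)
  sel <- ps$freq <= fmax
  f <- ps$freq[sel]
  p <- ps$power[sel]
  df <- f[2] - f[1]
  half <- round(3 * smooth_hz / df)
  kern <- exp(-((-half:half) * df)^2 / (2 * smooth_hz^2))
  kern <- kern / sum(kern)
  sm <- stats::filter(p, kern, sides = 2)
  f[which.max(sm)]
}

# Table-level ACC simulation (no EEG): subject random intercepts plus
# Gaussian noise around planted per-ordered-pair means. Used by the
# statistics tests, where the generative mechanism must be transparent.
simulate_acc_table <- function(model, n_subjects, age_group = "4-5m",
                               subj_sd = 0.5, noise_sd = 0.3,
                               age_shift = 0) {
  rows <- lapply(seq_len(n_subjects), function(s) {
    intercept <- rnorm(1, 0, subj_sd)
    mag <- model$amplitude_uv + age_shift + intercept +
      rnorm(nrow(model), 0, noise_sd)
    data.frame(subject = sprintf("%s_s%02d", age_group, s),
               age_group = age_group, from = model$from, to = model$to,
               pair = model$pair, n_trials = 100L,
               acc_mean_uv = mag, acc_max_uv = mag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
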