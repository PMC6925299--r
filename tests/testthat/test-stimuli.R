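test_that("synthesized vowels have the requested fundamental", {
  tab <- fixture_formants()
  for (v in c("i", "a", "u")) {
    tk <- synthesize_vowel(tab[tab$vowel == v, ], f0 = 185, duration = 1.5,
                           fs = 44100)
    p <- track_pitch(tk$x, tk$fs)
    expect_gt(mean(p$voiced), 0.9)
    expect_lt(abs(median(p$f0[p$voiced]) - 185), 1)
  }
})

test_that("synthesis rejects invalid parameters", {
  tab <- fixture_formants()
  expect_error(synthesize_vowel(tab[1, ], duration = 0), "invalid")
  expect_error(synthesize_vowel(tab[1, ], f0 = -10), "invalid")
  expect_error(synthesize_vowel(tab[1, ], f0 = 500), "below F1")
  expect_error(synthesize_vowel(tab[1, ], fs = 4000), "Nyquist")
})

test_that("spectral envelope peaks at F1", {
  tab <- fixture_formants()
  # A periodic source only carries energy at harmonics of f0, so the
  # long-term spectrum can resolve the first resonance within 5% only when
  # the harmonics sample the envelope densely (f0 well below F1). At
  # f0 = 50 Hz that holds for all 7 vowels ...
  for (i in seq_len(nrow(tab))) {
    tk <- synthesize_vowel(tab[i, ], f0 = 50, duration = 1, fs = 44100)
    pk <- spectral_peak(tk$x, tk$fs, smooth_hz = 60)
    expect_lt(abs(pk - tab$F1[i]) / tab$F1[i], 0.05)
  }
  # ... and at the talker's 185 Hz it holds for the open vowels whose F1 is
  # several harmonics up.
  for (i in which(tab$F1 >= 3.5 * 185)) {
    tk <- synthesize_vowel(tab[i, ], f0 = 185, duration = 1, fs = 44100)
    pk <- spectral_peak(tk$x, tk$fs, smooth_hz = 200)
    expect_lt(abs(pk - tab$F1[i]) / tab$F1[i], 0.05)
  }
})

test_that("pitch flattening is a fixed point for already-flat tokens", {
  tab <- fixture_formants()
  tk <- synthesize_vowel(tab[2, ], f0 = 185, duration = 1.5, fs = 44100)
  out <- flatten_pitch(tk, 185)
  p <- track_pitch(out$x, out$fs)
  expect_lt(abs(median(p$f0[p$voiced]) - 185), 1)
  expect_lt(abs(rms(out$x) / rms(tk$x) - 1), 0.01)
  expect_equal(out$duration, tk$duration)
})

test_that("pitch flattening straightens a glide, frame by frame", {
  fs <- 44100
  t <- seq(0, 1.5, by = 1 / fs)
  f_inst <- 170 + 30 * t / 1.5                    # 170 -> 200 Hz glide
  phase <- 2 * pi * cumsum(f_inst) / fs
  # pulse-like periodic signal so epoch marking has clear peaks
  x <- 0.6 * cos(phase) + 0.3 * cos(2 * phase) + 0.1 * cos(3 * phase)
  tk <- vowel_token(x, fs, label = "glide")
  p_in <- track_pitch(tk$x, fs)
  expect_gt(max(p_in$f0[p_in$voiced]) - min(p_in$f0[p_in$voiced]), 20)
  out <- flatten_pitch(tk, 185)
  p <- track_pitch(out$x, out$fs)
  # trim half a frame at each edge where the tracker window leaves the signal
  inner <- p$time > 0.05 & p$time < 1.45
  expect_true(all(p$voiced[inner]))
  expect_lt(max(abs(p$f0[inner & p$voiced] - 185)), 2)
})

test_that("unvoiced input is rejected", {
  set.seed(42)
  tk <- vowel_token(rnorm(44100), 44100, label = "noise")
  expect_error(flatten_pitch(tk, 185), "unvoiced")
})

test_that("envelope flattening leaves flat tokens alone and kills AM", {
  fs <- 44100
  t <- seq(0, 1, by = 1 / fs)
  sine <- vowel_token(0.2 * sin(2 * pi * 185 * t), fs)
  out <- flatten_envelope(sine, target_rms = 0.1)
  mid <- seq(round(0.2 * fs), round(0.8 * fs))
  scale <- rms(out$x[mid]) / rms(sine$x[mid])
  expect_lt(max(abs(out$x[mid] - scale * sine$x[mid])) / rms(out$x), 0.02)

  am <- vowel_token((1 + 0.5 * sin(2 * pi * 4 * t)) * sin(2 * pi * 185 * t),
                    fs)
  depth <- function(tok) {
    e <- hilbert_env(tok$x)[mid]
    e <- stats::filter(e, rep(1 / 441, 441), sides = 2)  # 10 ms smoother
    e <- e[!is.na(e)]
    (max(e) - min(e)) / (max(e) + min(e))
  }
  expect_gt(depth(am), 0.4)
  flat <- flatten_envelope(am, target_rms = 0.1)
  expect_lt(depth(flat), 0.05)
})

test_that("RMS is equalized across tokens to within 0.1%", {
  toks <- fixture_tokens_flat()
  r <- vapply(toks, function(tk) rms(tk$x), 0)
  expect_lt(diff(range(r)) / mean(r), 0.001)
  expect_error(flatten_envelope(vowel_token(numeric(100) + 0, 100)),
               "all-zero|division")
})

test_that("sequencer covers all 42 ordered transitions and conserves counts", {
  tab <- fixture_formants()
  dr <- sample_transition_events(tab$vowel, 20000, seed = 11)
  types <- table(paste(dr$events$from, dr$events$to))
  expect_equal(length(types), 42L)
  expect_equal(sum(types), 20000L - 1L)
  expect_equal(length(unique(paste_pair(dr$events$from, dr$events$to))), 21L)
  # near-uniformity: each type within +/-20% of 1/42
  rel <- as.numeric(types) / sum(types)
  expect_true(all(abs(rel - 1 / 42) < 0.2 / 42))
  # consecutive labels always differ
  expect_true(all(dr$events$from != dr$events$to))
})

test_that("sequences are reproducible and bookkeeping is sample-exact", {
  tab <- fixture_formants()
  toks <- lapply(1:3, function(i)
    synthesize_vowel(tab[i, ], duration = 0.6, fs = 8000))
  s1 <- build_sequence(toks, 15, seed = 9)
  s2 <- build_sequence(toks, 15, seed = 9)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$events, s2$events)
  expect_equal(nrow(s1$events), 14L)
  oracle <- sum(s1$durations) - 14 * 0.050
  expect_lt(abs(length(s1$x) / s1$fs - oracle), 1 / s1$fs + 1e-12)
  # single token: no splice
  s0 <- build_sequence(toks[1], 1, seed = 1)
  expect_equal(nrow(s0$events), 0L)
  # degenerate inventory
  expect_error(build_sequence(toks[1], 5, seed = 1), "infeasible")
})

test_that("event tables and WAV round-trip through disk", {
  tab <- fixture_formants()
  toks <- lapply(1:2, function(i)
    synthesize_vowel(tab[i, ], duration = 0.5, fs = 8000))
  sq <- build_sequence(toks, 5, seg_range = c(0.2, 0.3), seed = 2)
  ef <- tempfile(fileext = ".tsv")
  write_events(sq$events, ef)
  back <- read_events(ef)
  expect_equal(back$onset_s, sq$events$onset_s, tolerance = 1e-9)
  expect_equal(back$from, sq$events$from)
  wf <- tempfile(fileext = ".wav")
  write_wav(sq$x, wf, fs = sq$fs)
  w <- read_wav(wf)
  expect_equal(w$fs, 8000)
  expect_lt(max(abs(w$x - pmin(1, pmax(-1, sq$x)))), 1 / 32767)
})
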