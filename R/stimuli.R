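#' Construct a vowel token
#'
#' @param x numeric waveform (arbitrary linear amplitude units).
#' @param fs sample rate (Hz).
#' @param label vowel label.
#' @return object of class `vowel_token`: list with `label`, `x`, `fs`,
#'   `duration` (s).
#' @export
vowel_token <- function(x, fs, label = NA_character_) {
  stopifnot(is.numeric(x), length(x) > 0, fs > 0)
  structure(list(label = label, x = as.numeric(x), fs = fs,
                 duration = length(x) / fs),
            class = "vowel_token")
}

#' @export
print.vowel_token <- function(x, ...) {
  cat(sprintf("<vowel_token /%s/: %.3f s @ %d Hz, RMS %.4f>\n",
              x$label, x$duration, as.integer(x$fs), rms(x$x)))
  invisible(x)
}

# Klatt-style digital resonator: second-order recursive filter with unity
# gain at the resonance, centre frequency f and bandwidth bw (Hz).
resonator <- function(x, f, bw, fs) {
  C <- -exp(-2 * pi * bw / fs)
  B <- 2 * exp(-pi * bw / fs) * cos(2 * pi * f / fs)
  A <- 1 - B - C
  as.numeric(stats::filter(A * x, filter = c(B, C), method = "recursive"))
}

#' Synthesize a sustained vowel token
#'
#' Source-filter synthesis standing in for recorded sustained utterances:
#' an impulse train at `f0` with a mild one-pole spectral tilt (emulating
#' the falling glottal + radiation spectrum) is passed through a cascade of
#' second-order resonators at the entry's formant frequencies (bandwidths
#' 60/90/120 Hz). The spectrum is stationary over the token.
#'
#' @param entry one row of a formant table (columns `vowel`, `F1`, `F2`,
#'   optionally `F3`).
#' @param f0 fundamental frequency (Hz); must lie below the entry's F1.
#' @param duration token duration (s).
#' @param fs sample rate (Hz); must be at least twice the highest formant.
#' @param tilt_pole pole of the one-pole low-pass shaping the source
#'   spectrum (0 disables the tilt).
#' @param target_rms RMS amplitude of the returned waveform.
#' @return a [vowel_token()].
#' @export
synthesize_vowel <- function(entry, f0 = 185, duration = 1.5, fs = 44100,
                             tilt_pole = 0.95, target_rms = 0.1) {
  if (!is.finite(duration) || duration <= 0)
    stop("invalid parameter: duration must be positive")
  if (!is.finite(f0) || f0 <= 0)
    stop("invalid parameter: f0 must be positive")
  formants <- c(entry$F1, entry$F2, if (!is.null(entry$F3)) entry$F3)
  formants <- formants[is.finite(formants)]
  if (f0 >= formants[1]) stop("invalid parameter: f0 must be below F1")
  if (any(formants >= fs / 2))
    stop("configuration error: formant above Nyquist frequency")
  bandwidths <- c(60, 90, 120)[seq_along(formants)]
  n <- round(duration * fs)
  src <- numeric(n)
  src[unique(pmin(n, round(seq(1, n, by = fs / f0))))] <- 1
  if (tilt_pole > 0)
    src <- as.numeric(stats::filter(src, filter = tilt_pole,
                                    method = "recursive"))
  y <- src
  for (k in seq_along(formants))
    y <- resonator(y, formants[k], bandwidths[k], fs)
  y <- y - mean(y)
  y <- y * target_rms / rms(y)
  vowel_token(y, fs, label = if (!is.null(entry$vowel)) entry$vowel else NA)
}

#' Autocorrelation pitch tracker
#'
#' Frame-wise fundamental-frequency estimation by normalized autocorrelation
#' with parabolic peak interpolation. A frame is voiced when the normalized
#' autocorrelation peak in the candidate lag range exceeds
#' `voicing_threshold`.
#'
#' @param x waveform (numeric vector).
#' @param fs sample rate (Hz).
#' @param fmin,fmax F0 search range (Hz).
#' @param frame,hop analysis frame length and hop (s).
#' @param voicing_threshold normalized-autocorrelation voicing cutoff.
#' @return data.frame with `time` (frame centre, s), `f0` (Hz, NA when
#'   unvoiced), `strength` (peak normalized autocorrelation), `voiced`.
#' @export
track_pitch <- function(x, fs, fmin = 75, fmax = 400,
                        frame = 0.04, hop = 0.01, voicing_threshold = 0.5) {
  fl <- round(frame * fs)
  hp <- max(1L, round(hop * fs))
  if (length(x) < fl) stop("signal shorter than one analysis frame")
  starts <- seq(1L, length(x) - fl + 1L, by = hp)
  lag_min <- max(2L, floor(fs / fmax))
  lag_max <- min(fl - 2L, ceiling(fs / fmin))
  nfft <- 2^ceiling(log2(2L * fl))
  out <- data.frame(time = (starts - 1 + fl / 2) / fs, f0 = NA_real_,
                    strength = 0)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + fl - 1L)]
    seg <- seg - mean(seg)
    if (all(seg == 0)) next
    sp <- fft(c(seg, numeric(nfft - fl)))
    r <- Re(fft(Mod(sp)^2, inverse = TRUE))[1:(lag_max + 2L)]
    if (r[1] <= 0) next
    r <- r / r[1]
    k <- lag_min + which.max(r[(lag_min + 1L):(lag_max + 1L)]) - 1L  # lag k
    out$strength[i] <- r[k + 1L]
    if (r[k + 1L] >= voicing_threshold) {
      denom <- r[k] - 2 * r[k + 1L] + r[k + 2L]
      delta <- if (denom != 0) 0.5 * (r[k] - r[k + 2L]) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      out$f0[i] <- fs / (k + delta)
    }
  }
  out$voiced <- !is.na(out$f0)
  out
}

# Locate glottal-cycle peaks (pitch marks) by guided peak picking: start at
# the waveform maximum within the first two periods, then step forward one
# local period at a time, snapping to the local maximum within +/- 25% of
# the predicted position.
find_pitch_marks <- function(x, fs, pitch) {
  voiced <- pitch[pitch$voiced, , drop = FALSE]
  f0_at <- approxfun(voiced$time, voiced$f0, rule = 2)
  p0 <- fs / f0_at(0)
  first <- 1:min(length(x), max(3L, round(2 * p0)))
  marks <- which.max(x[first])
  repeat {
    last <- marks[length(marks)]
    p <- fs / f0_at((last - 1) / fs)
    centre <- last + p
    if (centre + 0.25 * p > length(x)) break
    win <- max(1L, round(centre - 0.25 * p)):min(length(x),
                                                 round(centre + 0.25 * p))
    marks <- c(marks, win[which.max(x[win])])
  }
  marks
}

#' Flatten the pitch contour of a voiced token
#'
#' Pitch-synchronous overlap-add (PSOLA): glottal-cycle epochs are marked by
#' autocorrelation-guided peak picking, two-period Hann-windowed grains are
#' extracted at the analysis marks, and re-placed on a uniform grid at the
#' target period. Duration is preserved.
#'
#' @param token a [vowel_token()]; must be voiced (periodicity detectable in
#'   at least half of the analysis frames).
#' @param target_f0 target fundamental (Hz), within [0.5, 2] times the
#'   token's median F0.
#' @param fmin,fmax pitch-tracking search range passed to [track_pitch()].
#' @return a [vowel_token()] with constant F0 at `target_f0`.
#' @export
flatten_pitch <- function(token, target_f0 = 185, fmin = 75, fmax = 400) {
  x <- token$x
  fs <- token$fs
  pitch <- track_pitch(x, fs, fmin = fmin, fmax = fmax)
  if (mean(pitch$voiced) < 0.5)
    stop("unvoiced input: no reliable periodicity detected")
  med_f0 <- median(pitch$f0[pitch$voiced])
  if (target_f0 < 0.5 * med_f0 || target_f0 > 2 * med_f0)
    stop("invalid parameter: target_f0 outside [0.5, 2] x median F0 (",
         round(med_f0, 1), " Hz)")
  marks <- find_pitch_marks(x, fs, pitch)
  f0_at <- approxfun(pitch$time[pitch$voiced], pitch$f0[pitch$voiced],
                     rule = 2)
  period_t <- fs / target_f0
  targets <- seq(marks[1], length(x), by = period_t)
  y <- numeric(length(x))
  wsum <- numeric(length(x))
  for (ct in round(targets)) {
    am <- marks[which.min(abs(marks - ct))]
    L <- round(fs / f0_at((am - 1) / fs))
    lo_a <- am - L
    hi_a <- am + L
    if (lo_a < 1 || hi_a > length(x)) next
    g <- x[lo_a:hi_a]
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(2 * L)) / (2 * L))
    lo_t <- ct - L
    hi_t <- ct + L
    sel <- lo_t:hi_t
    keep <- sel >= 1 & sel <= length(x)
    y[sel[keep]] <- y[sel[keep]] + (g * w)[keep]
    wsum[sel[keep]] <- wsum[sel[keep]] + w[keep]
  }
  y <- y / pmax(wsum, 0.25)
  vowel_token(y, fs, label = token$label)
}

# Amplitude envelope by full rectification and zero-phase Butterworth
# low-pass at `cutoff` Hz.
rectified_envelope <- function(x, fs, cutoff = 50) {
  bf <- butter(4, cutoff / (fs / 2), type = "low")
  as.numeric(filtfilt(bf, abs(x)))
}

#' Flatten the amplitude envelope of a token
#'
#' Computes the token's envelope (full rectification followed by a zero-phase
#' low-pass at `cutoff` Hz), divides the waveform by it, and rescales to
#' `target_rms` so RMS amplitude is equal across tokens. Envelope samples
#' below `floor_frac` of the median envelope are clamped before the division
#' so silence is not amplified.
#'
#' @param token a [vowel_token()] with non-zero RMS.
#' @param cutoff envelope low-pass cutoff (Hz), below `fs / 2`.
#' @param target_rms RMS amplitude of the output (linear units).
#' @param floor_frac clamping floor as a fraction of the median envelope.
#' @return a [vowel_token()] with a flat envelope and RMS `target_rms`.
#' @export
flatten_envelope <- function(token, cutoff = 50, target_rms = 0.1,
                             floor_frac = 0.01) {
  x <- token$x
  fs <- token$fs
  if (rms(x) == 0) stop("division guard: all-zero input token")
  if (cutoff >= fs / 2) stop("configuration error: cutoff above Nyquist")
  env <- rectified_envelope(x, fs, cutoff)
  env <- pmax(env, floor_frac * median(env))
  y <- x / env
  y <- y * target_rms / rms(y)
  vowel_token(y, fs, label = token$label)
}

#' Draw a random transition sequence of vowel labels
#'
#' Samples `n_tokens` labels (each drawn uniformly from the labels differing
#' from its predecessor) together with segment durations, and derives the
#' splice-event times. With 7 labels this paradigm yields 42 ordered
#' transition types, i.e. 21 vowel pairs in two orders.
#'
#' @param labels vowel inventory (character).
#' @param n_tokens number of segments in the sequence.
#' @param seg_range segment-duration range (s), drawn uniformly.
#' @param overlap cross-fade duration (s).
#' @param seed optional RNG seed (integer) for reproducibility.
#' @param fs optional sample rate; when given, durations are quantized to
#'   the sample grid so event times are sample-exact.
#' @return list with `labels` (length `n_tokens`), `durations` (s),
#'   `events` (data.frame `onset_s`, `from`, `to`; event time is the start
#'   of the cross-fade window), and `total_duration` (s).
#' @export
sample_transition_events <- function(labels, n_tokens,
                                     seg_range = c(0.300, 0.400),
                                     overlap = 0.050, seed = NULL, fs = NULL) {
  stopifnot(n_tokens >= 1)
  labels <- unique(as.character(labels))
  if (length(labels) < 2 && n_tokens > 1)
    stop("infeasible constraint: need at least 2 distinct labels")
  if (!is.null(seed)) set.seed(seed)
  lab <- character(n_tokens)
  lab[1] <- sample(labels, 1)
  if (n_tokens > 1)
    for (i in 2:n_tokens)
      lab[i] <- sample(labels[labels != lab[i - 1]], 1)
  dur <- runif(n_tokens, seg_range[1], seg_range[2])
  if (!is.null(fs)) dur <- round(dur * fs) / fs
  if (n_tokens > 1) {
    onsets <- cumsum(dur)[-n_tokens] - seq_len(n_tokens - 1) * overlap
    events <- data.frame(onset_s = onsets, from = lab[-n_tokens],
                         to = lab[-1], stringsAsFactors = FALSE)
  } else {
    events <- data.frame(onset_s = numeric(0), from = character(0),
                         to = character(0), stringsAsFactors = FALSE)
  }
  list(labels = lab, durations = dur, events = events,
       total_duration = sum(dur) - (n_tokens - 1) * overlap)
}

#' Build a concatenated-vowel stimulus sequence
#'
#' Splices random 300-400 ms segments of the supplied tokens with a 50 ms
#' raised-cosine cross-fade, with consecutive segments constrained to differ
#' in vowel label. Each splice is annotated as a transition event whose time
#' is the start of the cross-fade window.
#'
#' @param tokens list of [vowel_token()]s (one per vowel, all at the same
#'   sample rate, each longer than `max(seg_range)`).
#' @param n_tokens number of segments to splice.
#' @param seg_range segment-duration range (s).
#' @param overlap cross-fade duration (s).
#' @param seed RNG seed (integer); identical seed and configuration give a
#'   bit-identical sequence.
#' @return object of class `stimulus_sequence`: list with `x` (waveform),
#'   `fs`, `events` (data.frame `onset_s`, `from`, `to`), `labels`,
#'   `durations`, `seed`.
#' @export
build_sequence <- function(tokens, n_tokens, seg_range = c(0.300, 0.400),
                           overlap = 0.050, seed = 1) {
  labs <- vapply(tokens, function(tk) as.character(tk$label), "")
  fs <- tokens[[1]]$fs
  stopifnot(all(vapply(tokens, function(tk) tk$fs, 0) == fs))
  if (any(vapply(tokens, function(tk) tk$duration, 0) < max(seg_range)))
    stop("every token must be longer than the maximum segment length")
  names(tokens) <- labs
  draw <- sample_transition_events(labs, n_tokens, seg_range, overlap,
                                   seed = seed, fs = fs)
  o_s <- round(overlap * fs)
  n_seg <- round(draw$durations * fs)
  pos <- cumsum(c(0, head(n_seg, -1) - o_s))  # start sample (0-based)
  total <- pos[n_tokens] + n_seg[n_tokens]
  y <- numeric(total)
  fade_in <- 0.5 * (1 - cos(pi * (seq_len(o_s) - 0.5) / o_s))
  for (i in seq_len(n_tokens)) {
    tk <- tokens[[draw$labels[i]]]
    max_start <- length(tk$x) - n_seg[i]
    s0 <- if (max_start > 0) sample.int(max_start + 1L, 1L) else 1L
    seg <- tk$x[s0:(s0 + n_seg[i] - 1L)]
    w <- rep(1, n_seg[i])
    if (i > 1) w[seq_len(o_s)] <- fade_in
    if (i < n_tokens) w[(n_seg[i] - o_s + 1):n_seg[i]] <- rev(fade_in)
    idx <- (pos[i] + 1):(pos[i] + n_seg[i])
    y[idx] <- y[idx] + seg * w
  }
  events <- draw$events
  if (n_tokens > 1) events$onset_s <- pos[-1] / fs
  structure(list(x = y, fs = fs, events = events, labels = draw$labels,
                 durations = n_seg / fs, seed = seed),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence: %d tokens, %d events, %.1f s @ %d Hz>\n",
              length(x$labels), nrow(x$events), length(x$x) / x$fs,
              as.integer(x$fs)))
  invisible(x)
}

#' Write transition events as tab-separated text
#'
#' @param events data.frame with columns `onset_s`, `from`, `to`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.table(events[, c("onset_s", "from", "to")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read transition events from tab-separated text
#'
#' @param path path to a file written by [write_events()].
#' @return data.frame with `onset_s`, `from`, `to`.
#' @export
read_events <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
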