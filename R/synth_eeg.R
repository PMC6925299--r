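#' Tri-phasic ACC response template
#'
#' P1-N1-P2-like kernel supported on [0, 0.35] s, built as a sum of three
#' Gaussians (positive-negative-positive) and normalized to unit peak
#' amplitude, with the dominant positive peak near `peak_latency` (default
#' 200 ms, the canonical ACC peak). The topography is a bilateral
#' frontal-central Gaussian weight map with unit maximum.
#'
#' @param mont a [montage()].
#' @param fs sample rate (Hz).
#' @param peak_latency requested latency (s) of the dominant positive peak.
#' @param support kernel support (s).
#' @return object of class `acc_template`: list with `kernel` (unit peak),
#'   `times`, `fs`, `peak_latency` (realized argmax, s), `topography`
#'   (named weights per channel, unit max).
#' @export
acc_template <- function(mont, fs = 512, peak_latency = 0.200,
                         support = 0.350) {
  t <- seq(0, support, by = 1 / fs)
  k <- 0.45 * exp(-(t - 0.425 * peak_latency)^2 / (2 * 0.022^2)) -
       0.70 * exp(-(t - 0.700 * peak_latency)^2 / (2 * 0.025^2)) +
       1.00 * exp(-(t - peak_latency)^2 / (2 * 0.045^2))
  # taper to zero at the support edges
  edge <- 0.04
  taper <- pmin(1, t / edge) * pmin(1, (support - t) / edge)
  k <- k * taper
  k <- k / max(k)
  topo <- scalp_gaussian(mont, rbind(c(-0.25, 0.30), c(0.25, 0.30)),
                         sigma = 0.45)
  structure(list(kernel = k, times = t, fs = fs,
                 peak_latency = t[which.max(k)], topography = topo),
            class = "acc_template")
}

#' Noise model for synthetic EEG
#'
#' @param pink_rms pink (1/f) background level per channel (uV RMS).
#' @param white_rms sensor white-noise level (uV RMS).
#' @param blink_rate blink-artifact rate (events/min).
#' @param blink_amp blink amplitude (uV) at the frontal maximum.
#' @param blink_dur blink duration (s).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(pink_rms = 8, white_rms = 1, blink_rate = 2,
                        blink_amp = 200, blink_dur = 0.3) {
  stopifnot(pink_rms >= 0, white_rms >= 0, blink_rate >= 0, blink_amp >= 0)
  structure(list(pink_rms = pink_rms, white_rms = white_rms,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 blink_dur = blink_dur), class = "noise_model")
}

#' Map acoustic predictors to planted ACC amplitudes
#'
#' Defines, per ordered vowel transition, the ACC amplitude (uV) a virtual
#' subject generates. Two age presets:
#' \describe{
#'   \item{young}{amplitude = `a * dF1 + b * dF2 + c` with `b < a`: responses
#'     track raw acoustic (chiefly F1) differences.}
#'   \item{old}{a saturating function of dF1,
#'     `c + A (1 - exp(-dF1 / knee))`, flattening above the knee, plus an
#'     additive `boost` for the `n_boost` pairs with the smallest
#'     cochlear-scaled difference (selective gain for confusable pairs,
#'     i.e. perceptual warping).}
#' }
#' An order asymmetry adds +`asym_uv`/2 to transitions into `asym_vowel`
#' and -`asym_uv`/2 to transitions out of it, so the planted signed
#' (into - out of) difference equals `asym_uv`.
#'
#' @param preset `"young"` or `"old"`.
#' @param predictors output of [pair_predictors()] (21 unordered pairs).
#' @param params optional overrides: `a`, `b`, `c` (young); `A`, `knee`,
#'   `boost`, `n_boost`, `c` (old); `asym_vowel`, `asym_uv` (both).
#' @return data.frame of class `sensitivity_model` with 42 rows: `from`,
#'   `to`, `pair`, `amplitude_uv`; attributes `preset` and `params`.
#' @export
make_sensitivity <- function(preset = c("young", "old"), predictors,
                             params = list()) {
  preset <- match.arg(preset)
  stopifnot(is.data.frame(predictors),
            all(c("v1", "v2", "dF1", "dF2") %in% names(predictors)))
  p <- switch(preset,
    young = list(a = 0.010, b = 0.002, c = 1.0),
    old   = list(A = 5.0, knee = 120, boost = 2.0, n_boost = 3, c = 1.0))
  p <- utils::modifyList(c(p, list(asym_vowel = "\u0254", asym_uv = 1.5)),
                         params)
  base <- switch(preset,
    young = p$a * predictors$dF1 + p$b * predictors$dF2 + p$c,
    old = {
      amp <- p$c + p$A * (1 - exp(-predictors$dF1 / p$knee))
      if (p$n_boost > 0 && "csd_db" %in% names(predictors)) {
        small <- order(predictors$csd_db)[seq_len(p$n_boost)]
        amp[small] <- amp[small] + p$boost
      }
      amp
    })
  fwd <- data.frame(from = predictors$v1, to = predictors$v2,
                    amplitude_uv = base, stringsAsFactors = FALSE)
  rev <- data.frame(from = predictors$v2, to = predictors$v1,
                    amplitude_uv = base, stringsAsFactors = FALSE)
  model <- rbind(fwd, rev)
  model$amplitude_uv <- model$amplitude_uv +
    p$asym_uv / 2 * ((model$to == p$asym_vowel) - (model$from == p$asym_vowel))
  model$amplitude_uv <- pmax(model$amplitude_uv, 0)
  model$pair <- paste_pair(model$from, model$to)
  model <- model[, c("from", "to", "pair", "amplitude_uv")]
  attr(model, "preset") <- preset
  attr(model, "params") <- p
  class(model) <- c("sensitivity_model", "data.frame")
  model
}

#' Canonical unordered pair label
#'
#' Joins two vowel labels in a fixed (sorted) order so both presentation
#' orders of a pair map to the same label.
#'
#' @param a,b vowel labels (vectorized).
#' @return character vector of pair labels.
#' @export
paste_pair <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = "-")
}

# Pink (1/f power) noise via spectral shaping of white Gaussian noise,
# normalized to the requested RMS.
pink_noise <- function(n, rms_uv) {
  if (rms_uv == 0) return(numeric(n))
  nf <- 2^ceiling(log2(n))
  sp <- fft(rnorm(nf))
  f <- c(1, seq_len(nf - 1))  # avoid DC blow-up
  f <- pmin(f, nf - f + 1)    # mirror for negative frequencies
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x * rms_uv / rms(x)
}

# Smooth blink bump: raised-cosine of duration dur (s).
blink_bump <- function(fs, dur) {
  n <- max(3L, round(dur * fs))
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Simulate a raw multichannel EEG recording with planted ACC responses
#'
#' The recording is the sum over transition events of
#' `amplitude(from, to) * topography (x) kernel` placed at the event time,
#' plus pink background noise, occasional high-amplitude frontal blink
#' artifacts, and sensor white noise. Deterministic given `seed`.
#'
#' @param events data.frame with `onset_s`, `from`, `to` (e.g. from
#'   [build_sequence()] or [sample_transition_events()]).
#' @param model a [make_sensitivity()] model.
#' @param mont a [montage()].
#' @param template an [acc_template()] (its `fs` must match `fs`).
#' @param noise a [noise_model()].
#' @param fs sample rate (Hz), at least 256.
#' @param seed RNG seed.
#' @param gain subject-level multiplicative gain applied to all planted
#'   amplitudes.
#' @param duration recording length (s); defaults to the last event plus
#'   0.6 s.
#' @return object of class `eeg_recording`: list with `data` (channels x
#'   samples matrix, uV), `fs`, `channels`, `montage`, `events`, `gain`.
#' @export
simulate_recording <- function(events, model, mont, template = NULL,
                               noise = noise_model(), fs = 512, seed = 1,
                               gain = 1, duration = NULL) {
  stopifnot(nrow(events) > 0, fs >= 256)
  if (is.null(template)) template <- acc_template(mont, fs = fs)
  if (abs(template$fs - fs) > 1e-9)
    stop("template sample rate must match fs")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) duration <- max(events$onset_s) + 0.6
  n <- round(duration * fs)
  if (any(round(events$onset_s * fs) + length(template$kernel) > n))
    stop("bounds error: event beyond recording span")
  key <- paste(model$from, model$to)
  amp <- setNames(model$amplitude_uv, key)[paste(events$from, events$to)]
  if (anyNA(amp)) stop("event transition not covered by sensitivity model")
  amp <- amp * gain
  # component time course: sum of scaled kernels at event times
  comp <- numeric(n)
  klen <- length(template$kernel)
  for (e in seq_len(nrow(events))) {
    i0 <- round(events$onset_s[e] * fs) + 1L
    idx <- i0:(i0 + klen - 1L)
    comp[idx] <- comp[idx] + amp[e] * template$kernel
  }
  ch <- mont$channels$name
  topo <- template$topography[ch]
  data <- outer(unname(topo), comp)
  rownames(data) <- ch
  # pink + white noise
  for (c_i in seq_along(ch)) {
    data[c_i, ] <- data[c_i, ] + pink_noise(n, noise$pink_rms)
    if (noise$white_rms > 0)
      data[c_i, ] <- data[c_i, ] + rnorm(n, sd = noise$white_rms)
  }
  # blinks: frontal raised-cosine deflections
  if (noise$blink_rate > 0 && noise$blink_amp > 0) {
    n_blinks <- rpois(1, noise$blink_rate * duration / 60)
    if (n_blinks > 0) {
      bump <- blink_bump(fs, noise$blink_dur)
      btopo <- scalp_gaussian(mont, rbind(c(0, 0.95)), sigma = 0.30)[ch]
      for (b in seq_len(n_blinks)) {
        i0 <- sample.int(n - length(bump), 1)
        idx <- i0:(i0 + length(bump) - 1L)
        data[, idx] <- data[, idx] +
          noise$blink_amp * outer(unname(btopo), bump)
      }
    }
  }
  structure(list(data = data, fs = fs, channels = ch, montage = mont,
                 events = events, gain = gain),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %.1f s @ %d Hz, %d events>\n",
              nrow(x$data), ncol(x$data) / x$fs, as.integer(x$fs),
              nrow(x$events)))
  invisible(x)
}

#' Write an EEG recording as TSV + JSON sidecar
#'
#' Data as a samples-by-channels tab-separated table, events as TSV, and a
#' small JSON sidecar with the sample rate and montage preset.
#'
#' @param rec an [simulate_recording()] output.
#' @param prefix output path prefix; writes `<prefix>_data.tsv`,
#'   `<prefix>_events.tsv`, `<prefix>_meta.json`.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  dat <- as.data.frame(t(rec$data))
  names(dat) <- rec$channels
  write.table(dat, paste0(prefix, "_data.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_events(rec$events, paste0(prefix, "_events.tsv"))
  meta <- sprintf('{"fs": %d, "montage": "%s", "n_channels": %d, "gain": %g}',
                  as.integer(rec$fs), rec$montage$preset, nrow(rec$data),
                  rec$gain)
  writeLines(meta, paste0(prefix, "_meta.json"))
  invisible(prefix)
}
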