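#' ERB-number (Cam) scale conversions
#'
#' Glasberg & Moore (1990) equivalent-rectangular-bandwidth scale for
#' moderate levels: `erb_number(f) = 21.4 log10(4.37 f / 1000 + 1)` and the
#' ERB bandwidth `erb_bandwidth(f) = 24.7 (4.37 f / 1000 + 1)` Hz.
#'
#' @param f frequency (Hz).
#' @param e ERB number (Cams).
#' @return converted values.
#' @export
hz_to_erb <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname hz_to_erb
#' @export
erb_to_hz <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' @rdname hz_to_erb
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# Long-term power spectral density by Welch's method (Hann windows, 50%
# overlap). Returns freq (Hz) and power per frequency bin (linear, such that
# sum(power) ~ mean-square amplitude).
welch_psd <- function(x, fs, nfft = 4096) {
  nfft <- min(nfft, 2^floor(log2(length(x))))
  hop <- nfft %/% 2
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft)
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[1:(nfft %/% 2 + 1)]
  }
  acc <- acc / length(starts)
  # one-sided, normalized so that the sum over bins equals the mean square
  acc <- 2 * acc / (nfft * sum(w^2))
  acc[1] <- acc[1] / 2
  acc[length(acc)] <- acc[length(acc)] / 2
  list(freq = (0:(nfft %/% 2)) * fs / nfft, power = acc)
}

#' Auditory excitation spectrum of a token
#'
#' Long-term Welch power spectrum integrated through a bank of roex-shaped
#' auditory filters with centre frequencies spaced at `step` ERB-numbers
#' between `flo` and `fhi`. Filter shape is the symmetric rounded
#' exponential `W(g) = (1 + p g) exp(-p g)` with `p = 4 fc / ERB(fc)`
#' (Patterson/Moore). Band levels are absolute dB (re: unit amplitude),
#' floored at `dynamic_range` dB below the maximum band so near-silent bands
#' do not dominate spectral differences.
#'
#' @param token a [vowel_token()] of at least 100 ms.
#' @param flo,fhi frequency range of the filterbank (Hz).
#' @param step centre-frequency spacing in ERB-numbers.
#' @param dynamic_range level floor below the maximum band (dB).
#' @param nfft Welch segment length.
#' @return object of class `excitation_spectrum`: list with `cf` (centre
#'   frequencies, Hz), `erb` (ERB numbers), `level_db`.
#' @export
excitation_spectrum <- function(token, flo = 50, fhi = 11000, step = 0.5,
                                dynamic_range = 60, nfft = 4096) {
  if (token$duration < 0.1) stop("token must be at least 100 ms long")
  if (rms(token$x) == 0) stop("undefined level: silent token")
  fhi <- min(fhi, 0.999 * token$fs / 2)
  ps <- welch_psd(token$x, token$fs, nfft = nfft)
  erbs <- seq(hz_to_erb(flo), hz_to_erb(fhi), by = step)
  cf <- erb_to_hz(erbs)
  f <- ps$freq
  level <- vapply(cf, function(fc) {
    p <- 4 * fc / erb_bandwidth(fc)
    g <- abs(f - fc) / fc
    w <- (1 + p * g) * exp(-p * g)
    sum(w * ps$power)
  }, 0)
  level_db <- 10 * log10(pmax(level, .Machine$double.xmin))
  level_db <- pmax(level_db, max(level_db) - dynamic_range)
  structure(list(cf = cf, erb = erbs, level_db = level_db),
            class = "excitation_spectrum")
}

#' @export
print.excitation_spectrum <- function(x, ...) {
  cat(sprintf("<excitation_spectrum: %d bands, %.0f-%.0f Hz, peak %.1f dB>\n",
              length(x$cf), min(x$cf), max(x$cf), max(x$level_db)))
  invisible(x)
}

#' Cochlear-scaled spectral difference between two excitation spectra
#'
#' Mean absolute per-band level difference (dB) between two excitation
#' spectra with identical band layouts: symmetric, zero iff the spectra are
#' identical. Quantifies overall acoustic dissimilarity on a scale that
#' approximates human hearing.
#'
#' @param a,b [excitation_spectrum()] objects with identical band layouts.
#' @return spectral difference in dB.
#' @export
cochlear_difference <- function(a, b) {
  if (length(a$cf) != length(b$cf) || any(abs(a$cf - b$cf) > 1e-9))
    stop("layout error: excitation spectra have different band layouts")
  mean(abs(a$level_db - b$level_db))
}

#' Formant frequency differences for all unordered vowel pairs
#'
#' @param table complete formant table (see [default_formant_table()]).
#' @param erb_scale if `TRUE`, differences are taken on the ERB-number scale
#'   instead of Hz (off by default; figures and models use Hz).
#' @return data.frame with one row per unordered pair (21 for 7 vowels):
#'   `v1`, `v2`, `pair`, `dF1`, `dF2` (absolute differences).
#' @export
formant_diffs <- function(table, erb_scale = FALSE) {
  validate_formant_table(table, n_vowels = NULL)
  if (anyNA(table$F1) || anyNA(table$F2))
    stop("incomplete table: missing formant values")
  xf <- if (erb_scale) function(f) hz_to_erb(f) else identity
  idx <- combn(nrow(table), 2)
  data.frame(
    v1 = table$vowel[idx[1, ]],
    v2 = table$vowel[idx[2, ]],
    pair = paste_pair(table$vowel[idx[1, ]], table$vowel[idx[2, ]]),
    dF1 = abs(xf(table$F1[idx[1, ]]) - xf(table$F1[idx[2, ]])),
    dF2 = abs(xf(table$F2[idx[1, ]]) - xf(table$F2[idx[2, ]])),
    stringsAsFactors = FALSE
  )
}

#' Acoustic predictors for all unordered vowel pairs
#'
#' Synthesizes (or accepts) one token per vowel, computes each token's
#' auditory excitation spectrum, and tabulates the cochlear-scaled spectral
#' difference together with the absolute F1/F2 differences for every
#' unordered pair.
#'
#' @param table formant table (7 vowels).
#' @param tokens optional named list of [vowel_token()]s keyed by vowel
#'   label; when `NULL`, tokens are synthesized from `table` at `f0`/`fs`.
#' @param f0,fs,duration synthesis parameters used when `tokens` is `NULL`.
#' @param ... passed to [excitation_spectrum()].
#' @return data.frame (`pair_predictors`) with `v1`, `v2`, `pair`, `csd_db`,
#'   `dF1`, `dF2`; 21 rows for a 7-vowel table.
#' @export
pair_predictors <- function(table, tokens = NULL, f0 = NULL, fs = 44100,
                            duration = 0.5, ...) {
  validate_formant_table(table)
  if (is.null(f0)) f0 <- attr(table, "f0")
  if (is.null(f0)) f0 <- 185
  if (is.null(tokens)) {
    tokens <- lapply(seq_len(nrow(table)), function(i)
      synthesize_vowel(table[i, ], f0 = f0, duration = duration, fs = fs))
    names(tokens) <- table$vowel
  }
  spectra <- lapply(tokens, excitation_spectrum, ...)
  fd <- formant_diffs(table)
  fd$csd_db <- mapply(function(a, b) cochlear_difference(spectra[[a]],
                                                         spectra[[b]]),
                      fd$v1, fd$v2)
  fd[, c("v1", "v2", "pair", "csd_db", "dF1", "dF2")]
}

#' Write pair predictors as TSV
#' @param predictors output of [pair_predictors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictors <- function(predictors, path) {
  write.table(predictors, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
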