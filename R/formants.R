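#' Default formant table for the 7-vowel inventory
#'
#' Per-vowel first and second formant frequencies for the seven Southern
#' British English monophthongs /i/, /ɪ/, /ɛ/, /a/, /ɒ/,
#' /ɔ/, /u/ (as in beat, bit, bet, bat, Bart, bought, boot), from
#' published female speaker measurements (Deterding 1997, JIPA 27).
#' Third-formant values are nominal plausible female values (F3 is only
#' used to shape the upper spectrum of synthetic tokens, not as a
#' predictor). The talker fundamental defaults to 185 Hz.
#'
#' @param f0 talker fundamental frequency in Hz.
#' @return A `data.frame` with columns `vowel`, `F1`, `F2`, `F3` (Hz) and
#'   attribute `f0`; one row per vowel, 7 rows.
#' @export
default_formant_table <- function(f0 = 185) {
  # IPA labels as \u escapes so the source parses identically in any locale
  tab <- data.frame(
    vowel = c("i", "\u026a", "\u025b", "a", "\u0252", "\u0254", "u"),
    F1 = c(303, 384, 719, 1018, 910, 389, 328),
    F2 = c(2654, 2174, 2063, 1799, 1316, 888, 1437),
    F3 = c(3203, 2973, 2997, 2869, 2787, 2796, 2674),
    stringsAsFactors = FALSE
  )
  attr(tab, "f0") <- f0
  validate_formant_table(tab)
  tab
}

#' Validate a formant table
#'
#' Checks the invariants required of a formant table: positive frequencies,
#' F1 < F2 (< F3 when present), and distinct vowel labels. For the standard
#' inventory exactly 7 vowels are expected; other inventory sizes are allowed
#' when `n_vowels = NULL`.
#'
#' @param tab data.frame with columns `vowel`, `F1`, `F2` and optionally `F3`.
#' @param n_vowels required inventory size, or `NULL` to skip the size check.
#' @return `tab`, invisibly.
#' @export
validate_formant_table <- function(tab, n_vowels = 7) {
  stopifnot(is.data.frame(tab), all(c("vowel", "F1", "F2") %in% names(tab)))
  if (!is.null(n_vowels) && nrow(tab) != n_vowels)
    stop("formant table must have exactly ", n_vowels, " vowels")
  if (anyDuplicated(tab$vowel)) stop("duplicate vowel labels")
  freqs <- c(tab$F1, tab$F2, if ("F3" %in% names(tab)) tab$F3)
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("all formant frequencies must be positive and finite")
  if (any(tab$F1 >= tab$F2)) stop("F1 must be below F2 for every vowel")
  if ("F3" %in% names(tab) && any(tab$F2 >= tab$F3))
    stop("F2 must be below F3 for every vowel")
  invisible(tab)
}

#' Read a formant table from delimited text
#'
#' @param path path to a tab-separated file with header columns
#'   `vowel`, `F1`, `F2` and optionally `F3`.
#' @param f0 talker fundamental (Hz) attached as an attribute.
#' @param n_vowels required inventory size (see [validate_formant_table()]).
#' @return validated formant table.
#' @export
read_formant_table <- function(path, f0 = 185, n_vowels = 7) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  attr(tab, "f0") <- f0
  validate_formant_table(tab, n_vowels = n_vowels)
  tab
}
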