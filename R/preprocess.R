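#' Re-reference a recording to the mastoid average
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#'
#' @param rec an `eeg_recording`.
#' @return the recording, re-referenced.
#' @export
rereference <- function(rec) {
  m <- rec$montage$mastoids
  if (!all(m %in% rec$channels))
    stop("montage error: mastoid channels missing from recording")
  ref <- colMeans(rec$data[m, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref, "-")
  rec
}

#' Band-limit a recording with zero-phase Butterworth filters
#'
#' 4th-order Butterworth high-pass at `low` Hz and low-pass at `high` Hz,
#' each applied forward-backward (zero phase, so evoked-response latencies
#' are preserved).
#'
#' @param rec an `eeg_recording`.
#' @param low high-pass edge (Hz).
#' @param high low-pass edge (Hz); must be below `fs / 2`.
#' @param order filter order of each section.
#' @return the filtered recording.
#' @export
bandpass <- function(rec, low = 0.1, high = 30, order = 4) {
  if (high >= rec$fs / 2)
    stop("configuration error: low-pass edge at or above Nyquist")
  hp <- butter(order, low / (rec$fs / 2), type = "high")
  lp <- butter(order, high / (rec$fs / 2), type = "low")
  for (i in seq_len(nrow(rec$data))) {
    rec$data[i, ] <- filtfilt(lp, filtfilt(hp, rec$data[i, ]))
  }
  rec
}

#' Drop posterior channels and interpolate bad channels
#'
#' Removes the montage's posterior exclusion list (and, optionally, the
#' mastoids, which have served their purpose after re-referencing), then
#' replaces each remaining bad channel by an inverse-distance-weighted
#' average of its `k` nearest good neighbours.
#'
#' @param rec an `eeg_recording`.
#' @param bad_channels channels to interpolate (must be in the montage).
#' @param drop_mastoids drop the mastoid channels as well.
#' @param k number of nearest neighbours for interpolation.
#' @return the reduced recording.
#' @export
drop_and_interpolate <- function(rec, bad_channels = character(),
                                 drop_mastoids = TRUE, k = 4) {
  mont <- rec$montage
  if (!all(bad_channels %in% rec$channels))
    stop("bad channels not in montage")
  drop <- intersect(c(mont$posterior, if (drop_mastoids) mont$mastoids),
                    rec$channels)
  keep <- setdiff(rec$channels, drop)
  if (length(setdiff(keep, bad_channels)) == 0)
    stop("unrecoverable: all remaining channels are bad")
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channels <- keep
  pos <- mont$channels[match(keep, mont$channels$name), ]
  for (bc in intersect(bad_channels, keep)) {
    good <- setdiff(keep, bad_channels)
    i <- match(bc, keep)
    d <- sqrt((pos$x[match(good, keep)] - pos$x[i])^2 +
              (pos$y[match(good, keep)] - pos$y[i])^2)
    nn <- order(d)[seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[nn], 1e-6)
    w <- w / sum(w)
    rec$data[i, ] <- as.numeric(w %*% rec$data[match(good[nn], keep), ,
                                               drop = FALSE])
  }
  rec
}

#' Epoch a recording around transition events, with threshold rejection
#'
#' Cuts one epoch per event over `window` (relative to the event time),
#' subtracts the per-channel pre-stimulus baseline mean, and flags epochs
#' containing any sample beyond `threshold` uV as rejected. Events whose
#' window does not fit inside the recording are dropped with a warning.
#'
#' @param rec an `eeg_recording`.
#' @param window epoch window in seconds relative to the event
#'   (default -0.100 to +0.350).
#' @param threshold absolute rejection threshold (uV); `NULL` disables
#'   rejection.
#' @param subject,age_group metadata carried on the epoch set.
#' @return object of class `epoch_set`: list with `data` (channels x time x
#'   trials array, uV, baseline-subtracted), `times` (s), `fs`, `channels`,
#'   `labels` (data.frame `from`, `to`, `pair` per trial), `retained`
#'   (logical rejection mask), `subject`, `age_group`, `n_events`.
#' @export
epoch_and_reject <- function(rec, window = c(-0.100, 0.350), threshold = 150,
                             subject = NA, age_group = NA) {
  fs <- rec$fs
  i_rel <- round(window[1] * fs):round(window[2] * fs)
  times <- i_rel / fs
  centers <- round(rec$events$onset_s * fs) + 1L
  ok <- centers + min(i_rel) >= 1 & centers + max(i_rel) <= ncol(rec$data)
  if (!all(ok)) warning(sum(!ok), " events outside recording span dropped")
  centers <- centers[ok]
  ev <- rec$events[ok, , drop = FALSE]
  n_ch <- nrow(rec$data)
  n_t <- length(i_rel)
  n_tr <- length(centers)
  dat <- array(NA_real_, dim = c(n_ch, n_t, n_tr),
               dimnames = list(rec$channels, NULL, NULL))
  base_idx <- which(times < 0)
  for (tr in seq_len(n_tr)) {
    ep <- rec$data[, centers[tr] + i_rel, drop = FALSE]
    ep <- ep - rowMeans(ep[, base_idx, drop = FALSE])
    dat[, , tr] <- ep
  }
  retained <- rep(TRUE, n_tr)
  if (!is.null(threshold)) {
    retained <- apply(dat, 3, function(ep) all(abs(ep) <= threshold))
    if (!any(retained))
      stop("empty set: no epochs retained after rejection")
  }
  labels <- data.frame(from = ev$from, to = ev$to,
                       pair = paste_pair(ev$from, ev$to),
                       stringsAsFactors = FALSE)
  structure(list(data = dat, times = times, fs = fs,
                 channels = rec$channels, labels = labels,
                 retained = retained, subject = subject,
                 age_group = age_group, n_events = nrow(rec$events)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set: %d channels x %d samples x %d trials (%d retained), %.3f..%.3f s>\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], sum(x$retained),
    min(x$times), max(x$times)))
  invisible(x)
}

#' Subject inclusion by total trial count
#'
#' Subjects contributing fewer than `min_trials` transition events (counted
#' before artifact rejection) are excluded from cohort-level tables.
#'
#' @param n_events events recorded per subject (named or plain vector).
#' @param min_trials inclusion cutoff (default 1800).
#' @return logical inclusion vector.
#' @export
include_subjects <- function(n_events, min_trials = 1800) {
  n_events >= min_trials
}
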