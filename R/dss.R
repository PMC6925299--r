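#' Fit a single-component Denoising Source Separation model
#'
#' Finds the linear combination of channels that maximizes the
#' trial-to-trial repeatability of the evoked response. Let C0 be the
#' covariance of the concatenated single-trial data and C1 the covariance of
#' the trial-averaged data. The data are whitened by C0 (PCA with rank
#' truncation retaining `rank_tol` of the variance), C1 is projected into
#' the whitened space and eigendecomposed; the leading eigenvector is the
#' component, and its eigenvalue -- the ratio of evoked to total variance in
#' whitened space, in [0, 1] -- is the repeatability score.
#'
#' The rank-1 sensor-space reconstruction uses the covariance pattern
#' `a = C0 w / (w' C0 w)`, so a noiseless planted source is reconstructed at
#' its true amplitude. The reporting electrode is the channel where the
#' reconstructed trial-average has maximum absolute amplitude, which scales
#' the component back to EEG microvolt units. The sign convention makes the
#' pattern positive at the reporting electrode, so the component time course
#' carries the sensor polarity.
#'
#' @param epochs an [epoch_and_reject()] epoch set; only retained trials are
#'   used. Needs at least 2 trials and 2 channels.
#' @param rank_tol fraction of C0 variance retained before whitening.
#' @return object of class `dss_model`: `weights` (unmixing, per channel),
#'   `pattern` (mixing topography, per channel), `eigenvalues`
#'   (repeatability spectrum, non-increasing, clamped to [0, 1]),
#'   `lambda1`, `electrode`, `scale` (pattern value at the electrode),
#'   `component` (time x trial matrix of component time courses),
#'   `avg_component`, `times`, `fs`, `channels`, `trial_index`.
#' @export
fit_dss <- function(epochs, rank_tol = 0.999) {
  keep <- which(epochs$retained)
  X <- epochs$data[, , keep, drop = FALSE]
  d <- dim(X)
  if (d[3] < 2) stop("need at least 2 retained trials")
  if (d[1] < 2) stop("need at least 2 channels")
  flat <- matrix(X, nrow = d[1])            # channels x (time * trials)
  mu <- rowMeans(flat)
  flat <- flat - mu
  C0 <- tcrossprod(flat) / (ncol(flat) - 1)
  avg <- apply(X, c(1, 2), mean) - mu       # trial-averaged, channels x time
  C1 <- tcrossprod(avg) / (ncol(avg) - 1)
  e0 <- eigen(C0, symmetric = TRUE)
  pos <- e0$values > max(e0$values) * 1e-12
  if (!any(pos)) stop("degenerate input: zero-variance data")
  cum <- cumsum(e0$values[pos]) / sum(e0$values[pos])
  r <- which(cum >= rank_tol)[1]  # smallest rank covering rank_tol variance
  if (d[3] < r) stop("degenerate input: fewer trials than retained rank")
  E <- e0$vectors[, seq_len(r), drop = FALSE]
  W <- diag(1 / sqrt(e0$values[seq_len(r)]), r) %*% t(E)  # whitener
  Cw <- W %*% C1 %*% t(W)
  e1 <- eigen((Cw + t(Cw)) / 2, symmetric = TRUE)
  evals <- pmin(pmax(e1$values, 0), 1)
  u1 <- e1$vectors[, 1]
  w <- as.numeric(t(W) %*% u1)              # unmixing channel weights
  a <- as.numeric(C0 %*% w) / as.numeric(t(w) %*% C0 %*% w)  # pattern
  # reconstructed trial average and reporting electrode; time courses are
  # taken on the raw (baseline-subtracted) epochs so amplitudes survive --
  # only the covariances use demeaned data
  avg_raw <- apply(X, c(1, 2), mean)
  y_avg <- as.numeric(w %*% avg_raw)
  recon <- outer(a, y_avg)
  electrode <- epochs$channels[which.max(apply(abs(recon), 1, max))]
  i_el <- match(electrode, epochs$channels)
  if (a[i_el] < 0) {                         # sign convention
    w <- -w
    a <- -a
    y_avg <- -y_avg
  }
  comp <- matrix(w %*% matrix(X, nrow = d[1]), nrow = d[2])
  structure(list(weights = setNames(w, epochs$channels),
                 pattern = setNames(a, epochs$channels),
                 eigenvalues = evals, lambda1 = evals[1],
                 electrode = electrode, scale = a[i_el],
                 component = comp, avg_component = y_avg,
                 times = epochs$times, fs = epochs$fs,
                 channels = epochs$channels, trial_index = keep),
            class = "dss_model")
}

#' @export
print.dss_model <- function(x, ...) {
  cat(sprintf(
    "<dss_model: lambda1 = %.3f, electrode %s (pattern %.2f), %d trials>\n",
    x$lambda1, x$electrode, x$scale, ncol(x$component)))
  invisible(x)
}

#' Single-trial back-projected component traces (uV)
#'
#' The component time course of each trial scaled by the pattern value at
#' the reporting electrode, i.e. the rank-1 reconstruction evaluated at that
#' electrode.
#'
#' @param model a [fit_dss()] model.
#' @return time x trial matrix in uV (columns follow `model$trial_index`).
#' @export
dss_trial_traces <- function(model) {
  model$scale * model$component
}

#' Back-project the DSS component into sensor space, per condition
#'
#' Rank-1 reconstruction at the reporting electrode, averaged within each
#' ordered-pair condition.
#'
#' @param model a [fit_dss()] model.
#' @param epochs the epoch set the model was fitted on (provides labels).
#' @param trial_keep optional logical over the model's trials (e.g. a
#'   second-stage rejection mask); defaults to all.
#' @return object of class `evoked_set`: list with `times`, `waveforms`
#'   (condition x time matrix, uV), `conditions` (data.frame `from`, `to`,
#'   `pair`, `n_trials`), `electrode`.
#' @export
backproject <- function(model, epochs, trial_keep = NULL) {
  traces <- dss_trial_traces(model)
  labs <- epochs$labels[model$trial_index, , drop = FALSE]
  if (is.null(trial_keep)) trial_keep <- rep(TRUE, ncol(traces))
  key <- paste(labs$from, labs$to, sep = "\r")
  conds <- unique(key)
  wave <- matrix(NA_real_, nrow = length(conds), ncol = nrow(traces))
  n_tr <- integer(length(conds))
  for (i in seq_along(conds)) {
    sel <- key == conds[i] & trial_keep
    n_tr[i] <- sum(sel)
    if (n_tr[i] > 0)
      wave[i, ] <- rowMeans(traces[, sel, drop = FALSE])
  }
  parts <- strsplit(conds, "\r", fixed = TRUE)
  conditions <- data.frame(from = vapply(parts, `[`, "", 1),
                           to = vapply(parts, `[`, "", 2),
                           stringsAsFactors = FALSE)
  conditions$pair <- paste_pair(conditions$from, conditions$to)
  conditions$n_trials <- n_tr
  structure(list(times = model$times, waveforms = wave,
                 conditions = conditions, electrode = model$electrode),
            class = "evoked_set")
}

#' @export
print.evoked_set <- function(x, ...) {
  cat(sprintf("<evoked_set: %d conditions at electrode %s, %.3f..%.3f s>\n",
              nrow(x$conditions), x$electrode, min(x$times), max(x$times)))
  invisible(x)
}
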