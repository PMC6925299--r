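#' Process one raw recording into per-pair ACC rows
#'
#' The full single-subject pipeline: mastoid-average re-reference, 0.1-30 Hz
#' zero-phase Butterworth band-limiting, posterior-channel exclusion and bad
#' channel interpolation, transition-locked epoching (-100..+350 ms,
#' baseline-subtracted) with a gross sensor-space rejection pass, DSS
#' extraction of a single repeatability-maximizing component, back-projection
#' to the maximum-amplitude electrode, a second +/-`threshold` uV rejection
#' pass, and per-ordered-pair magnitude extraction (windowed mean and max
#' over 0-350 ms).
#'
#' Rejection is two-stage: epochs with any sensor sample beyond
#' `gross_threshold` are discarded before the DSS covariances are estimated,
#' and the +/-`threshold` rule is then applied to the back-projected
#' component traces (`reject_on = "component"`, the default) or to sensor
#' space (`reject_on = "sensor"`).
#'
#' @param rec an `eeg_recording`.
#' @param subject,age_group metadata for the output rows.
#' @param bad_channels channels to interpolate.
#' @param window epoch window (s).
#' @param threshold final artifact-rejection threshold (uV).
#' @param gross_threshold sensor-space pre-rejection threshold (uV) applied
#'   before DSS.
#' @param reject_on where the +/-`threshold` rule is evaluated.
#' @return list with `acc` (per-ordered-pair rows, see
#'   [evoked_to_acc_rows()]), `dss` (the fitted [fit_dss()] model), `evoked`
#'   (the [backproject()] set), `n_events`, `n_retained`.
#' @export
process_subject <- function(rec, subject = NA, age_group = NA,
                            bad_channels = character(),
                            window = c(-0.100, 0.350), threshold = 150,
                            gross_threshold = 500,
                            reject_on = c("component", "sensor")) {
  reject_on <- match.arg(reject_on)
  rec <- rereference(rec)
  rec <- bandpass(rec)
  rec <- drop_and_interpolate(rec, bad_channels = bad_channels)
  sensor_threshold <- if (reject_on == "sensor") threshold else gross_threshold
  epochs <- epoch_and_reject(rec, window = window,
                             threshold = sensor_threshold,
                             subject = subject, age_group = age_group)
  model <- fit_dss(epochs)
  trial_keep <- NULL
  if (reject_on == "component") {
    traces <- dss_trial_traces(model)
    trial_keep <- apply(abs(traces) <= threshold, 2, all)
    if (!any(trial_keep))
      stop("empty set: no epochs retained after component-space rejection")
  }
  evoked <- backproject(model, epochs, trial_keep = trial_keep)
  acc <- evoked_to_acc_rows(evoked, subject = subject,
                            age_group = age_group)
  n_retained <- if (is.null(trial_keep)) sum(epochs$retained)
                else sum(trial_keep)
  list(acc = acc, dss = model, evoked = evoked,
       n_events = epochs$n_events, n_retained = n_retained)
}

#' Simulate and process a cohort of virtual subjects
#'
#' Generates one recording per virtual subject (fresh random vowel sequence,
#' subject-level lognormal gain, pink noise and blinks) under the given
#' sensitivity model, runs [process_subject()] on each, and returns the
#' pooled ACC table. Subjects below the `min_trials` inclusion cutoff are
#' excluded (with all-clean synthetic sequences this only matters when
#' `trials_per_pair` is set very low).
#'
#' @param model a [make_sensitivity()] model.
#' @param n_subjects number of virtual subjects.
#' @param trials_per_pair target mean trials per ordered transition; the
#'   sequence length is `42 * trials_per_pair + 1` tokens.
#' @param age_group label stored in the table.
#' @param mont a [montage()]; the 16-channel preset keeps desk-scale runs
#'   light.
#' @param fs simulation sample rate (Hz).
#' @param noise a [noise_model()].
#' @param gain_sd standard deviation of the subject-level log-normal gain.
#' @param seed base RNG seed; subject s uses `seed + s`.
#' @param min_trials subject inclusion cutoff on recorded events.
#' @param labels vowel inventory for the sequences.
#' @param ... passed to [process_subject()].
#' @return list with `acc` (pooled ACC table), `gains` (named planted
#'   subject gains), `n_events` per subject, `included` logical.
#' @export
simulate_cohort <- function(model, n_subjects = 15, trials_per_pair = 100,
                            age_group = "4-5m", mont = montage("biosemi16"),
                            fs = 256, noise = noise_model(), gain_sd = 0.2,
                            seed = 1, min_trials = 1800,
                            labels = unique(model$from), ...) {
  template <- acc_template(mont, fs = fs)
  n_tokens <- 42 * trials_per_pair + 1
  rows <- list()
  gains <- numeric(n_subjects)
  n_events <- integer(n_subjects)
  included <- logical(n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(seed + s)
    gains[s] <- rlnorm(1, 0, gain_sd)
    draw <- sample_transition_events(labels, n_tokens, fs = fs)
    n_events[s] <- nrow(draw$events)
    included[s] <- include_subjects(n_events[s], min_trials)
    if (!included[s]) next
    rec <- simulate_recording(draw$events, model, mont, template = template,
                              noise = noise, fs = fs, seed = NULL,
                              gain = gains[s])
    subj <- sprintf("%s_s%02d", age_group, s)
    res <- process_subject(rec, subject = subj, age_group = age_group, ...)
    rows[[s]] <- res$acc
  }
  names(gains) <- sprintf("%s_s%02d", age_group, seq_len(n_subjects))
  list(acc = do.call(rbind, rows), gains = gains, n_events = n_events,
       included = included)
}
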