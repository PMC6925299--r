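#' ACC magnitude of an evoked waveform
#'
#' Windowed mean (used in the models) or windowed maximum (used for the
#' per-pair boxplots) of the evoked response, default window 0-350 ms.
#'
#' @param waveform evoked waveform (uV).
#' @param times time axis (s), same length as `waveform`.
#' @param window analysis window (s).
#' @param mode `"mean"` or `"max"`.
#' @return magnitude in uV.
#' @export
acc_magnitude <- function(waveform, times, window = c(0, 0.350),
                          mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (window[1] < min(times) - 1e-9 || window[2] > max(times) + 1e-9)
    stop("bounds error: window outside waveform span")
  sel <- times >= window[1] - 1e-9 & times <= window[2] + 1e-9
  if (mode == "mean") mean(waveform[sel]) else max(waveform[sel])
}

#' Per-subject ACC table from condition-average evoked responses
#'
#' @param evoked an [backproject()] `evoked_set`.
#' @param subject,age_group metadata columns.
#' @param window magnitude window (s).
#' @return data.frame with one row per ordered pair: `subject`, `age_group`,
#'   `from`, `to`, `pair`, `n_trials`, `acc_mean_uv`, `acc_max_uv`.
#' @export
evoked_to_acc_rows <- function(evoked, subject = NA, age_group = NA,
                               window = c(0, 0.350)) {
  mags_mean <- apply(evoked$waveforms, 1, acc_magnitude, times = evoked$times,
                     window = window, mode = "mean")
  mags_max <- apply(evoked$waveforms, 1, acc_magnitude, times = evoked$times,
                    window = window, mode = "max")
  data.frame(subject = subject, age_group = age_group,
             from = evoked$conditions$from, to = evoked$conditions$to,
             pair = evoked$conditions$pair,
             n_trials = evoked$conditions$n_trials,
             acc_mean_uv = mags_mean, acc_max_uv = mags_max,
             stringsAsFactors = FALSE)
}

#' Classical one-way ANOVA from explicit sums of squares
#'
#' Between/within decomposition with the p-value from the F distribution.
#'
#' @param x response values.
#' @param g group labels (factor or coercible).
#' @return list with `F`, `df1`, `df2`, `p`, `group_means`.
#' @export
oneway_anova <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) stop("insufficient data: need at least 2 groups")
  n_k <- tabulate(g)
  if (any(n_k < 2)) stop("insufficient data: a group has fewer than 2 values")
  means <- tapply(x, g, mean)
  grand <- mean(x)
  ss_between <- sum(n_k * (means - grand)^2)
  ss_within <- sum((x - means[as.integer(g)])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(x) - nlevels(g)
  if (ss_within == 0) {
    Fstat <- if (ss_between == 0) 0 else Inf
  } else {
    Fstat <- (ss_between / df1) / (ss_within / df2)
  }
  list(F = Fstat, df1 = df1, df2 = df2, p = pf(Fstat, df1, df2,
                                               lower.tail = FALSE),
       group_means = means)
}

#' Per-pair one-way ANOVAs of ACC magnitude across age groups
#'
#' For each unordered vowel pair, compares the per-subject ACC magnitude
#' (both presentation orders averaged within subject) across age groups.
#'
#' @param table ACC table (rows as produced by [evoked_to_acc_rows()]).
#' @param response magnitude column, default the windowed maximum
#'   (`"acc_max_uv"`) as used for the boxplot-style summaries.
#' @param adjust optional multiple-testing adjustment method for an added
#'   `p_adj` column (e.g. `"BH"`); default `"none"` reports raw p-values
#'   only.
#' @return data.frame with `pair`, `F`, `df1`, `df2`, `p` (and `p_adj`).
#' @export
anova_per_pair <- function(table, response = "acc_max_uv", adjust = "none") {
  per_subj <- aggregate(table[[response]],
                        by = list(subject = table$subject,
                                  age_group = table$age_group,
                                  pair = table$pair),
                        FUN = mean)
  names(per_subj)[4] <- "mag"
  pairs <- sort(unique(per_subj$pair))
  res <- lapply(pairs, function(pp) {
    d <- per_subj[per_subj$pair == pp, ]
    a <- oneway_anova(d$mag, d$age_group)
    data.frame(pair = pp, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!identical(adjust, "none")) out$p_adj <- stats::p.adjust(out$p, adjust)
  out
}

#' Mixed-effects models of ACC magnitude on acoustic predictors
#'
#' Fits the three models of the analysis, each with by-subject random
#' intercepts, and evaluates fixed effects with type-II Wald chi-square
#' tests:
#' \enumerate{
#'   \item `magnitude ~ age_group * pair`
#'   \item `magnitude ~ age_group * csd_db` (cochlear-scaled spectral
#'     difference replacing the pair factor)
#'   \item `magnitude ~ age_group * dF1 + age_group * dF2`
#' }
#' With a single age group the interaction terms are dropped with a warning.
#' If the random-intercept fit fails (e.g. one subject per group), an
#' ordinary-least-squares fallback with subject-mean centering is used and
#' flagged.
#'
#' @param table ACC table.
#' @param predictors [pair_predictors()] table, joined on the unordered
#'   pair label.
#' @param response magnitude column, default the windowed mean
#'   (`"acc_mean_uv"`).
#' @return list of class `acc_models` with elements `pair`, `csd`,
#'   `formant`, each a list with `fit`, `anova` (type-II chi-square table),
#'   `method` (`"lmer"` or `"ols"`); plus `data` (the joined table).
#' @export
fit_acoustic_models <- function(table, predictors,
                                response = "acc_mean_uv") {
  d <- table
  d$mag <- d[[response]]
  i <- match(d$pair, predictors$pair)
  if (anyNA(i)) stop("some pairs missing from predictor table")
  d$csd_db <- predictors$csd_db[i]
  d$dF1 <- predictors$dF1[i]
  d$dF2 <- predictors$dF2[i]
  d$age_group <- factor(d$age_group, levels = unique(d$age_group))
  d$subject <- factor(d$subject)
  one_age <- nlevels(d$age_group) < 2
  if (one_age)
    warning("single age group: interaction terms dropped (reduced model)")
  forms <- if (one_age) {
    list(pair = mag ~ pair, csd = mag ~ csd_db, formant = mag ~ dF1 + dF2)
  } else {
    list(pair = mag ~ age_group * pair,
         csd = mag ~ age_group * csd_db,
         formant = mag ~ age_group * dF1 + age_group * dF2)
  }
  # a group with a single subject confounds the random intercept with the
  # group effect: the random-intercept model is degenerate by design there
  degenerate <- min(table(unique(d[c("subject", "age_group")])$age_group)) < 2
  fit_one <- function(f) {
    fme <- update_formula_re(f)
    fit <- if (degenerate) NULL else tryCatch(
      suppressWarnings(
        lme4::lmer(fme, data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore"))),
      error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) fit <- NULL
    if (is.null(fit)) {
      warning("random-intercept model degenerate; using OLS fallback with ",
              "subject-mean centering")
      dd <- d
      ctr <- tapply(dd$mag, dd$subject, mean)
      dd$mag <- dd$mag - ctr[as.character(dd$subject)] + mean(dd$mag)
      fit <- lm(f, data = dd)
      list(fit = fit, anova = car::Anova(fit, type = 2), method = "ols")
    } else {
      list(fit = fit, anova = car::Anova(fit, type = 2), method = "lmer")
    }
  }
  out <- lapply(forms, fit_one)
  out$data <- d
  class(out) <- "acc_models"
  out
}

# append the by-subject random intercept to a fixed-effect formula
update_formula_re <- function(f) {
  stats::as.formula(paste(paste(deparse(f), collapse = " "),
                          "+ (1 | subject)"))
}

#' @export
print.acc_models <- function(x, ...) {
  for (nm in c("pair", "csd", "formant")) {
    cat("==", nm, "model (", x[[nm]]$method, ") ==\n", sep = "")
    print(x[[nm]]$anova)
    cat("\n")
  }
  invisible(x)
}

#' OLS fallback with subject-mean centering
#'
#' Companion estimator for [fit_acoustic_models()]: removes each subject's
#' mean from the response (re-adding the grand mean) and fits ordinary least
#' squares. On well-behaved data its fixed-effect signs agree with the
#' mixed model's.
#'
#' @param table ACC table joined to predictors as in
#'   [fit_acoustic_models()].
#' @param formula fixed-effects formula in terms of `mag`, `age_group`,
#'   `csd_db`, `dF1`, `dF2`.
#' @param predictors predictor table.
#' @param response magnitude column.
#' @return an `lm` fit.
#' @export
fit_acoustic_ols <- function(table, formula, predictors,
                             response = "acc_mean_uv") {
  d <- table
  d$mag <- d[[response]]
  i <- match(d$pair, predictors$pair)
  d$csd_db <- predictors$csd_db[i]
  d$dF1 <- predictors$dF1[i]
  d$dF2 <- predictors$dF2[i]
  d$age_group <- factor(d$age_group)
  ctr <- tapply(d$mag, d$subject, mean)
  d$mag <- d$mag - ctr[as.character(d$subject)] + mean(d$mag)
  lm(formula, data = d)
}

#' Order-asymmetry table
#'
#' For every unordered pair and age group, the signed difference between the
#' two presentation orders of the subject-mean ACC magnitudes,
#' `mean(a -> b) - mean(b -> a)` where `a < b` in the canonical pair label,
#' together with its absolute value. Pairs missing one order are flagged
#' with `NA`.
#'
#' @param table ACC table.
#' @param response magnitude column.
#' @return data.frame with `age_group`, `pair`, `v1`, `v2`, `signed_uv`
#'   (`mean(v1 -> v2) - mean(v2 -> v1)`), `abs_uv`.
#' @export
asymmetry_table <- function(table, response = "acc_mean_uv") {
  tab <- table
  tab$mag <- tab[[response]]
  v1 <- pmin(tab$from, tab$to)
  v2 <- pmax(tab$from, tab$to)
  tab$forward <- tab$from == v1
  agg <- aggregate(mag ~ age_group + pair + forward, data = tab, FUN = mean)
  out <- list()
  for (ag in unique(agg$age_group)) {
    for (pp in unique(agg$pair[agg$age_group == ag])) {
      fwd <- agg$mag[agg$age_group == ag & agg$pair == pp & agg$forward]
      bwd <- agg$mag[agg$age_group == ag & agg$pair == pp & !agg$forward]
      signed <- if (length(fwd) && length(bwd)) fwd - bwd else NA_real_
      if (is.na(signed))
        warning("pair ", pp, " missing one presentation order")
      vs <- strsplit(pp, "-", fixed = TRUE)[[1]]
      out[[length(out) + 1]] <- data.frame(
        age_group = ag, pair = pp, v1 = vs[1], v2 = vs[2],
        signed_uv = signed, abs_uv = abs(signed), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
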