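# Full-size synthetic cohorts (15 virtual subjects, ~100 trials per ordered
# transition) shared by the end-to-end acceptance checks. Built once per run.
fixture_cohort <- function(preset) {
  memo(paste0("cohort_", preset), function() {
    pp <- fixture_predictors()
    sm <- make_sensitivity(preset, pp)
    seed <- if (preset == "young") 2000 else 3000
    coh <- simulate_cohort(sm, n_subjects = 15, trials_per_pair = 100,
                           age_group = if (preset == "young") "4-5m"
                                       else "10-11m",
                           seed = seed)
    coh$model <- sm
    coh
  })
}
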