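test_that("windowed magnitudes match closed forms", {
  times <- seq(-0.1, 0.35, by = 1 / 1000)
  const <- rep(5, length(times))
  expect_equal(acc_magnitude(const, times, mode = "mean"), 5)
  expect_equal(acc_magnitude(const, times, mode = "max"), 5)
  expect_equal(acc_magnitude(numeric(length(times)), times), 0)
  # Gaussian bump with known integral: windowed mean = integral / width
  mu <- 0.2
  sig <- 0.03
  g <- exp(-(times - mu)^2 / (2 * sig^2))
  closed <- sig * sqrt(2 * pi) *
    (stats::pnorm(0.35, mu, sig) - stats::pnorm(0, mu, sig)) / 0.35
  expect_lt(abs(acc_magnitude(g, times, mode = "mean") - closed) / closed,
            0.01)
  expect_error(acc_magnitude(const, times, window = c(0, 1)), "bounds")
})

test_that("one-way ANOVA matches its algebraic identities and base R", {
  # identical groups: F = 0, p = 1
  a <- oneway_anova(rep(c(1, 2, 3, 4), times = 3),
                    rep(c("g1", "g2", "g3"), each = 4))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(1)
  x <- rnorm(24)
  g <- rep(c("a", "b"), each = 12)
  a2 <- oneway_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
  # three unbalanced groups against stats::oneway.test
  x3 <- rnorm(40)
  g3 <- rep(c("a", "b", "c"), c(10, 12, 18))
  a3 <- oneway_anova(x3, g3)
  ref <- stats::oneway.test(x3 ~ g3, var.equal = TRUE)
  expect_equal(a3$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(a3$p, ref$p.value, tolerance = 1e-10)
  expect_error(oneway_anova(1:5, c("a", "a", "a", "a", "b")),
               "insufficient")
})

test_that("per-pair ANOVAs run across age groups on a cohort table", {
  pp <- fixture_predictors()
  sm <- make_sensitivity("young", pp)
  set.seed(11)
  tabs <- rbind(simulate_acc_table(sm, 10, "4-5m"),
                simulate_acc_table(sm, 10, "8-9m", age_shift = 0.5),
                simulate_acc_table(sm, 10, "10-11m", age_shift = 1.0))
  res <- anova_per_pair(tabs)
  expect_equal(nrow(res), 21L)
  expect_true(all(res$df1 == 2 & res$df2 == 27))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # a strong planted age effect is detected for most pairs
  expect_gt(mean(res$p < 0.05), 0.5)
  res_adj <- anova_per_pair(tabs, adjust = "BH")
  expect_true(all(res_adj$p_adj >= res_adj$p - 1e-12))
})

test_that("mixed models recover planted formant weighting", {
  pp <- fixture_predictors()
  sm_y <- make_sensitivity("young", pp)
  sm_o <- make_sensitivity("old", pp)
  set.seed(21)
  tabs <- rbind(simulate_acc_table(sm_y, 12, "4-5m"),
                simulate_acc_table(sm_o, 12, "10-11m"))
  mods <- fit_acoustic_models(tabs, pp)
  expect_equal(mods$pair$method, "lmer")
  an <- mods$csd$anova
  expect_true("age_group:csd_db" %in% rownames(an))
  # formant model: positive dF1 and dF2 effects, dF1 dominant (young slope)
  fx <- lme4::fixef(mods$formant$fit)
  expect_gt(fx[["dF1"]], fx[["dF2"]])
  expect_gt(fx[["dF1"]], 0)
  expect_gt(fx[["dF2"]], 0)
  # planted age x dF1 interaction is detected
  expect_lt(mods$formant$anova["age_group:dF1", "Pr(>Chisq)"], 0.01)
})

test_that("interaction p-values are uniform under the null", {
  # null data generated from the fitted model's own form: a csd slope and an
  # age main effect but NO age x csd interaction, subject random intercepts,
  # iid residuals
  pp <- fixture_predictors()
  csd <- rep(pp$csd_db, 2)                      # both presentation orders
  pair <- rep(pp$pair, 2)
  gen_group <- function(n_subj, group, shift) {
    rows <- lapply(seq_len(n_subj), function(s) {
      mag <- 1 + 0.2 * csd + shift + rnorm(1, 0, 0.5) +
        rnorm(length(csd), 0, 0.4)
      data.frame(subject = paste0(group, "_s", s), age_group = group,
                 pair = pair, acc_mean_uv = mag, acc_max_uv = mag,
                 from = "x", to = "y", n_trials = 1L)
    })
    do.call(rbind, rows)
  }
  set.seed(31)
  pv <- replicate(150, {
    tabs <- rbind(gen_group(8, "4-5m", 0), gen_group(8, "10-11m", 0.3))
    m <- suppressWarnings(fit_acoustic_models(tabs, pp))
    m$csd$anova["age_group:csd_db", "Pr(>Chisq)"]
  })
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("OLS fallback agrees in fixed-effect signs", {
  pp <- fixture_predictors()
  sm <- make_sensitivity("young", pp)
  set.seed(41)
  tabs <- rbind(simulate_acc_table(sm, 10, "4-5m"),
                simulate_acc_table(sm, 10, "10-11m", age_shift = 0.4))
  mods <- fit_acoustic_models(tabs, pp)
  ols <- fit_acoustic_ols(tabs, mag ~ age_group * dF1 + age_group * dF2, pp)
  fx <- lme4::fixef(mods$formant$fit)
  co <- coef(ols)
  shared <- intersect(names(fx), names(co))
  expect_true(all(sign(fx[shared]) == sign(co[shared])))
  # single subject per group: random intercepts are confounded with the
  # group effect, so every model warns and takes the OLS path
  one <- rbind(simulate_acc_table(sm, 1, "4-5m"),
               simulate_acc_table(sm, 1, "10-11m"))
  w <- capture_warnings(m_one <- fit_acoustic_models(one, pp))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(m_one$formant$method, "ols")
})

test_that("asymmetry table is antisymmetric and recovers planted offsets", {
  pp <- fixture_predictors()
  # perfectly symmetric table: all signed values zero
  sm0 <- make_sensitivity("young", pp, params = list(asym_uv = 0))
  tab0 <- data.frame(subject = "s1", age_group = "g", from = sm0$from,
                     to = sm0$to, pair = sm0$pair, n_trials = 10L,
                     acc_mean_uv = sm0$amplitude_uv,
                     acc_max_uv = sm0$amplitude_uv)
  asym0 <- asymmetry_table(tab0)
  expect_true(all(abs(asym0$signed_uv) < 1e-12))
  expect_equal(asym0$abs_uv, abs(asym0$signed_uv))
  # planted +2 uV when the low-F1 vowel comes second
  sm2 <- make_sensitivity("young", pp, params = list(asym_uv = 2))
  set.seed(51)
  tab2 <- simulate_acc_table(sm2, 15, "4-5m", noise_sd = 0.2)
  asym2 <- asymmetry_table(tab2)
  oq <- asym2[asym2$v1 == "ɔ" | asym2$v2 == "ɔ", ]
  expect_equal(nrow(oq), 6L)
  recovered <- ifelse(oq$v2 == "ɔ", oq$signed_uv, -oq$signed_uv)
  expect_true(all(recovered > 0))
  expect_lt(max(abs(recovered - 2)), 3 * 0.2 / sqrt(15) * sqrt(2) + 0.3)
  # swapping order labels negates the signed column
  tab_sw <- tab2
  tab_sw$from <- tab2$to
  tab_sw$to <- tab2$from
  asym_sw <- asymmetry_table(tab_sw)
  expect_equal(asym_sw$signed_uv[order(asym_sw$pair)],
               -asym2$signed_uv[order(asym2$pair)], tolerance = 1e-12)
})
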