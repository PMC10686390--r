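test_that("zero variance components reduce the mixed model to OLS", {
  eff <- true_effects(sd_patient = 0, sd_eye = 0, sd_spot = 0,
                      sd_resid = 1.2)
  tab <- sim_model_table(n_patients = 8L, n_eyes = 12L, n_visits = 3L,
                         effects = eff, seed = 31)
  fit <- fit_volume_model(tab)
  ols <- lm(sensitivity_db ~ drusen_vol_e3mm3 + hrf_vol_e3mm3 + visit +
              ecc_deg + drusen_vol_e3mm3:visit +
              drusen_vol_e3mm3:ecc_deg, data = tab)
  b_mm <- coef(fit)
  b_ols <- coef(ols)[names(b_mm)]
  expect_lt(max(abs((b_mm - b_ols) / b_ols)), 1e-6)
  expect_true(fit$singular)
})

test_that("null generative effects are not spuriously detected", {
  eff <- true_effects(beta_drusen = 0, beta_hrf = 0, beta_visit = 0,
                      beta_ecc = 0, beta_drusen_visit = 0,
                      beta_drusen_ecc = 0, sd_patient = 0, sd_eye = 0,
                      sd_spot = 0, sd_resid = 0.8)
  tab <- sim_model_table(n_patients = 8L, n_eyes = 12L, n_visits = 3L,
                         effects = eff, seed = 57)
  fit <- fit_volume_model(tab)
  co <- fit$coefficients
  for (term in setdiff(rownames(co), "(Intercept)"))
    expect_lt(abs(co[term, "estimate"]), 3 * co[term, "se"])
  # residual variance close to the generative noise variance
  expect_equal(unname(fit$varcomp["residual"]), 0.8^2, tolerance = 0.1)
})

test_that("generative fixed effects are recovered from model tables", {
  eff <- true_effects()
  ests <- sapply(1:6, function(s) {
    tab <- sim_model_table(n_patients = 12L, n_eyes = 18L, n_visits = 4L,
                           effects = eff, seed = 400 + s, hrf_cov = 0.08)
    coef(fit_volume_model(tab))
  })
  m <- rowMeans(ests)
  expect_equal(unname(m["drusen_vol_e3mm3"]), eff$beta_drusen,
               tolerance = 0.08)
  expect_equal(unname(m["visit"]), eff$beta_visit, tolerance = 0.05)
  expect_equal(unname(m["ecc_deg"]), eff$beta_ecc, tolerance = 0.5)
  expect_equal(unname(m["hrf_vol_e3mm3"]), eff$beta_hrf, tolerance = 1.0)
})

test_that("variance components are recovered within coarse tolerance", {
  eff <- true_effects()
  vcs <- sapply(1:5, function(s) {
    tab <- sim_model_table(n_patients = 14L, n_eyes = 22L, n_visits = 3L,
                           effects = eff, seed = 700 + s)
    fit_volume_model(tab)$varcomp
  })
  m <- rowMeans(vcs)
  expect_lt(abs(m["patient"] - eff$sd_patient^2) / eff$sd_patient^2, 0.5)
  expect_lt(abs(m["eye"] - eff$sd_eye^2) / eff$sd_eye^2, 0.5)
  expect_lt(abs(m["spot"] - eff$sd_spot^2) / eff$sd_spot^2, 0.5)
  expect_lt(abs(m["residual"] - eff$sd_resid^2) / eff$sd_resid^2, 0.5)
})

test_that("presence model flags non-identifiable degenerate input", {
  tab <- sim_model_table(seed = 5)
  tab$drusen_present <- FALSE   # all-zero maps cohort
  expect_error(fit_presence_model(tab), "not identifiable")
})

test_that("presence effects carry the expected signs; nulls stay null", {
  tab <- sim_model_table(n_patients = 12L, n_eyes = 18L, n_visits = 3L,
                         seed = 91, hrf_cov = 0.08)
  fit <- fit_presence_model(tab)
  co <- fit$coefficients
  expect_lt(co["drusen_presentTRUE", "estimate"], 0)
  expect_lt(co["hrf_presentTRUE", "estimate"], 0)
  # beta_drusen = 0 in the generator: presence coefficient consistent with 0
  eff0 <- true_effects(beta_drusen = 0, beta_drusen_visit = 0,
                       beta_drusen_ecc = 0)
  tab0 <- sim_model_table(n_patients = 12L, n_eyes = 18L, n_visits = 3L,
                          effects = eff0, seed = 92)
  co0 <- fit_presence_model(tab0)$coefficients
  expect_lt(abs(co0["drusen_presentTRUE", "estimate"]),
            3 * co0["drusen_presentTRUE", "se"])
})

test_that("sector model drops empty sectors and adjusts pairwise contrasts", {
  tab <- sim_model_table(n_patients = 10L, n_eyes = 16L, n_visits = 2L,
                         seed = 8)
  # default grid only reaches the central and inner subfields
  expect_warning(fit <- fit_sector_model(tab), "dropped")
  k <- length(unique(tab$sector))
  m <- choose(k, 2)
  expect_equal(nrow(fit$contrasts), m)
  expect_equal(fit$contrasts$p_bonferroni,
               pmin(1, m * fit$contrasts$p))
  # foveal depression: sector 1 mean sensitivity below every other sector
  s1 <- fit$contrasts[fit$contrasts$sector_a == 1, ]
  expect_true(all(s1$estimate < 0))
})

test_that("sector contrasts agree with the emmeans reference", {
  skip_if_not_installed("emmeans")
  tab <- sim_model_table(n_patients = 8L, n_eyes = 12L, n_visits = 2L,
                         seed = 13)
  fit <- suppressWarnings(fit_sector_model(tab))
  em <- emmeans::emmeans(fit$model, "sector_f",
                         lmer.df = "asymptotic")
  prs <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "bonferroni"))
  expect_equal(fit$contrasts$estimate, prs$estimate, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$contrasts$p_bonferroni, prs$p.value, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("no sector contrast is significant under a uniform null", {
  eff0 <- true_effects(beta_drusen = 0, beta_hrf = 0, beta_ecc = 0,
                       beta_drusen_visit = 0, beta_drusen_ecc = 0)
  hits <- sapply(1:12, function(s) {
    tab <- sim_model_table(n_patients = 8L, n_eyes = 12L, n_visits = 2L,
                           effects = eff0, seed = 900 + s)
    fit <- suppressWarnings(fit_sector_model(tab))
    any(fit$contrasts$p_bonferroni < 0.05)
  })
  # Bonferroni controls the family-wise rate: allow at most 2/12 hits
  expect_lte(sum(hits), 2L)
})

test_that("learning refits recover a linear visit effect in all subsets", {
  eff <- true_effects(beta_drusen_visit = 0)   # purely linear visit slope
  tab <- sim_model_table(n_patients = 14L, n_eyes = 22L, n_visits = 5L,
                         effects = eff, seed = 44)
  ls <- learning_sensitivity(tab)
  vc <- ls$visit_coef
  expect_true(all(vc$estimable))
  expect_equal(vc$estimate, rep(eff$beta_visit, 3), tolerance = 0.15)
  # each CI covers the generative slope
  expect_true(all(vc$ci_lo <= eff$beta_visit & vc$ci_hi >= eff$beta_visit))
  # single-visit table: later subsets flagged not estimable
  one <- tab[tab$visit == 0, ]
  ls1 <- learning_sensitivity(one)
  expect_false(any(ls1$visit_coef$estimable[2:3]))
})

test_that("AIC comparison follows the definition and refuses row mismatch", {
  tab <- sim_model_table(n_patients = 8L, n_eyes = 12L, n_visits = 3L,
                         seed = 3)
  f1 <- fit_volume_model(tab)
  f2 <- fit_volume_model(tab, include_interactions = FALSE)
  cmp <- compare_models(full = f1, reduced = f2, full2 = f1)
  expect_equal(cmp$dAIC[1], 0)
  # identical model twice: dAIC exactly 0 between the copies
  expect_equal(cmp$AIC[cmp$model == "full"],
               cmp$AIC[cmp$model == "full2"])
  # AIC = 2k - 2 logLik
  expect_equal(cmp$AIC, 2 * cmp$df - 2 * cmp$logLik, tolerance = 1e-8)
  f3 <- fit_volume_model(tab[tab$visit > 0, ])
  expect_error(compare_models(f1, f3), "differing row sets")
})

test_that("a larger generative model wins the AIC comparison", {
  eff <- true_effects(beta_drusen_visit = -0.15, beta_drusen_ecc = -0.1)
  wins <- sapply(1:8, function(s) {
    tab <- sim_model_table(n_patients = 8L, n_eyes = 12L, n_visits = 3L,
                           effects = eff, seed = 60 + s)
    cmp <- compare_models(
      full = fit_volume_model(tab),
      reduced = fit_volume_model(tab, include_interactions = FALSE))
    cmp$model[1] == "full"
  })
  expect_gte(sum(wins), 7L)
})

test_that("sf_fit methods expose the classic modelling surface", {
  tab <- sim_model_table(seed = 2)
  fit <- fit_volume_model(tab)
  expect_s3_class(fit, "sf_fit")
  expect_named(coef(fit))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_length(residuals(fit), fit$n_obs)
  expect_length(fitted(fit), fit$n_obs)
  expect_output(print(fit), "nested mixed model")
  expect_output(print(summary(fit)), "variance components")
  expect_equal(fit$n_obs, nrow(tab))
  expect_true(all(fit$varcomp >= 0))
})
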