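# balanced, noise-free records with given regime means
balanced_records <- function(means = c(T1 = 40, T2 = 36, T3 = 40),
                             n_per = 4) {
  regimes <- rep(names(means), each = n_per)
  data.frame(region = rep(paste0("CR", 1:n_per), times = length(means)),
             year = seq_along(regimes) + 2005L,
             regime = regimes,
             coastal_mdmt = as.numeric(means[regimes]))
}

test_that("on balanced noise-free data the T2 contrast is the mean difference", {
  rec <- balanced_records()
  rec$coastal_mdmt <- rec$coastal_mdmt + rep(c(-1, 1), length.out = nrow(rec))
  f <- fit_lme(rec, 1L)
  con <- f$contrasts
  expect_equal(con$estimate[con$term == "T2 - T1"], -4.0)
  expect_equal(con$estimate[con$term == "T3 - T1"], 0.0)
  expect_equal(f$n_obs, nrow(rec))
})

test_that("a constant response is handled as a degenerate boundary fit", {
  rec <- balanced_records(c(T1 = 7, T2 = 7, T3 = 7))
  for (st in 1:3) {
    f <- fit_lme(rec, st)
    expect_equal(f$coefficients$estimate[1], 7)
    expect_true(all(f$contrasts$estimate == 0))
    expect_equal(f$resid_var, 0)
    expect_true(all(is.na(f$contrasts$p)))
  }
  f2 <- fit_lme(rec, 2L)
  expect_equal(f2$ranef_var, 0)
})

test_that("AIC identity 2k - 2logLik holds for every structure", {
  rec <- simulate_phenology_records(structure = 2L, seed = 5)
  for (st in 1:3) {
    f <- suppressWarnings(fit_lme(rec, st))
    expect_lt(abs(f$aic - (2 * f$k - 2 * f$log_likelihood)), 1e-8)
    expect_equal(f$aic, AIC(f$fit))
  }
  # parameter counts: 3 fixed + sigma; + random variance; 18 fixed + sigma
  ks <- vapply(1:3, function(st)
    as.numeric(suppressWarnings(fit_lme(rec, st))$k), numeric(1))
  expect_equal(ks, c(4, 5, 19))
})

test_that("select_structure picks the minimal AIC with documented tie-breaks", {
  mock <- function(st, aic, k) {
    structure(list(structure = st, response = "coastal_mdmt",
                   fingerprint = "fp", aic = aic, k = k),
              class = "chum_lme")
  }
  # AIC patterns as in the study's model-comparison table
  coastal <- list(mock(1L, 439.87, 4), mock(2L, 426.98, 5), mock(3L, 431.68, 19))
  expect_equal(select_structure(coastal)$structure, 2L)
  riverine <- list(mock(1L, 237.17, 4), mock(2L, 236.39, 5), mock(3L, 233.75, 19))
  expect_equal(select_structure(riverine)$structure, 3L)

  # exact tie: smaller k wins, then lower id
  expect_equal(select_structure(list(mock(2L, 100, 6), mock(3L, 100, 4)))$k, 4)
  expect_equal(select_structure(list(mock(3L, 100, 4), mock(1L, 100, 4)))$structure, 1L)

  # fits on different data are not comparable
  other <- mock(1L, 1, 4); other$fingerprint <- "other"
  expect_error(select_structure(list(coastal[[1]], other)), "not comparable")
})

test_that("design errors are reported before fitting", {
  rec <- balanced_records()
  expect_error(fit_lme(rec[rec$regime == "T1", ], 1L), "2 regimes")
  one_region <- rec[rec$region == "CR1", ]
  expect_error(fit_lme(one_region, 2L), "2 regions")
  expect_error(fit_lme(rec, 4L), "structure id")
})

test_that("significance markers follow the stated (inverted) convention", {
  expect_equal(significance_marker(c(0.0005, 0.005, 0.03, 0.5, 0.07)),
               c("***", "*", "**", "", ""))
  expect_equal(p_value_tier(c(0.0005, 0.005, 0.03, 0.07, 0.5)),
               c("p<0.001", "p<0.01", "p<0.05", "p<0.1", "ns"))
  tiers <- significance_tier(0.03)
  expect_equal(tiers$marker, "**")
  expect_equal(tiers$tier, "p<0.05")
  expect_error(significance_marker(1.2), "\\[0, 1\\]")
  expect_error(significance_marker(-0.1), "\\[0, 1\\]")
})

test_that("contrast estimates and SEs agree with emmeans", {
  skip_if_not_installed("emmeans")
  rec <- simulate_phenology_records(structure = 2L, resid_sd = 3, seed = 13)
  f2 <- fit_lme(rec, 2L)
  em <- emmeans::emmeans(f2$fit, "regime", lmer.df = "asymptotic")
  prs <- as.data.frame(emmeans::contrast(em, method = "revpairwise"))
  t2t1 <- prs[prs$contrast == "T2 - T1", ]
  mine <- f2$contrasts[f2$contrasts$term == "T2 - T1", ]
  expect_equal(mine$estimate, t2t1$estimate, tolerance = 1e-8)
  expect_equal(mine$se, t2t1$SE, tolerance = 1e-6)

  f3 <- fit_lme(rec, 3L)
  em3 <- emmeans::emmeans(f3$fit, "regime", by = "region")
  prs3 <- as.data.frame(emmeans::contrast(em3, method = "revpairwise"))
  t2cr3 <- prs3[prs3$contrast == "T2 - T1" & prs3$region == "CR3", ]
  mine3 <- f3$contrasts[f3$contrasts$term == "T2 - T1" &
                          !is.na(f3$contrasts$region) &
                          f3$contrasts$region == "CR3", ]
  expect_equal(mine3$estimate, t2cr3$estimate, tolerance = 1e-8)
  expect_equal(mine3$se, t2cr3$SE, tolerance = 1e-6)
})

test_that("with zero region variance the random intercept collapses onto the
           fixed-effects likelihood", {
  rec <- simulate_phenology_records(structure = 1L, region_sd = 0,
                                    resid_sd = 2, seed = 3)
  f1 <- fit_lme(rec, 1L)
  f2 <- suppressWarnings(fit_lme(rec, 2L))
  expect_lt(abs(f1$log_likelihood - f2$log_likelihood), 1e-4)
  expect_lt(f2$ranef_var, 1e-6)
})

test_that("the T2 contrast estimator tightens as pooled years grow", {
  bias_at <- function(n_years, reps = 40) {
    seq_regimes <- rep(c("T1", "T2", "T3"), length.out = n_years)
    ests <- vapply(seq_len(reps), function(s) {
      rec <- simulate_phenology_records(
        structure = 1L, regime_sequence = seq_regimes, region_sd = 0,
        resid_sd = 3, seed = s)
      f <- fit_lme(rec, 1L)
      f$contrasts$estimate[f$contrasts$term == "T2 - T1"]
    }, numeric(1))
    c(bias = mean(ests) - (-4), spread = sd(ests))
  }
  res <- sapply(c(5, 20, 80), bias_at)
  expect_lt(abs(res["bias", 3]), 0.5)
  # monte-carlo spread shrinks roughly as 1/sqrt(n)
  expect_true(res["spread", 3] < res["spread", 1] / 2)
})
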