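test_that("lognormal AFT without censoring equals OLS on log-times", {
  cfg <- cohort_config(n_per_group = 150,
                       fold_vmc = c(control = 1, treated = 1.3),
                       fold_death = c(control = 1, treated = 1.3),
                       batch_scale = c(scanner1 = 0.95, scanner2 = 1.05),
                       seed = 41)
  tab <- generate_cohort(cfg)
  fit <- fit_aft(tab, "death", reference = "control", B = 0)
  ols <- lm(log(death_time) ~ relevel(factor(group), "control") +
              factor(batch), data = tab)
  expect_equal(unname(log(fit$effects$beta)), unname(coef(ols)[2]),
               tolerance = 1e-6)
})

test_that("configured fold-changes are recovered with bootstrap CIs", {
  cfg <- cohort_config(n_per_group = 250,
                       fold_vmc = c(control = 1, treated = 1.5),
                       fold_death = c(control = 1, treated = 1.5), seed = 42)
  tab <- generate_cohort(cfg)
  for (ep in c("vmc", "death")) {
    fit <- fit_aft(tab, ep, reference = "control", B = 250, seed = 1)
    expect_lt(abs(fit$effects$beta - 1.5), 0.1)
    expect_lt(fit$effects$lower, 1.5)
    expect_gt(fit$effects$upper, 1.4)
    expect_lt(fit$effects$p, 0.01)
  }
  # remaining lifespan endpoint also scales by 1.5 in this construction
  rem <- fit_aft(tab, "remaining", reference = "control", B = 0)
  expect_lt(abs(rem$effects$beta - 1.5), 0.15)
})

test_that("reference handling is explicit and errors are informative", {
  cfg <- cohort_config(n_per_group = 60, seed = 43)
  tab <- generate_cohort(cfg)
  expect_error(fit_aft(tab, "death"), "reference")
  expect_error(fit_aft(tab, "death", reference = "nope"), "not found")
  bad <- tab
  bad$vmc_time[3] <- bad$death_time[3] + 5
  expect_error(fit_aft(bad, "remaining", reference = "control"),
               "precedes VMC")
})

test_that("censored cohorts still recover the fold-change", {
  cfg <- cohort_config(n_per_group = 300,
                       fold_vmc = c(control = 1, treated = 1.5),
                       fold_death = c(control = 1, treated = 1.5),
                       censor_frac = 0.15, seed = 44)
  tab <- generate_cohort(cfg)
  fit <- fit_aft(tab, "death", reference = "control", B = 0)
  expect_lt(abs(fit$effects$beta - 1.5), 0.12)
})

test_that("effects are transitive across a three-group cohort", {
  cfg <- cohort_config(n_per_group = 250, groups = c("a", "b", "c"),
                       fold_vmc = c(a = 1, b = 1.3, c = 1.8),
                       fold_death = c(a = 1, b = 1.3, c = 1.8), seed = 45)
  tab <- generate_cohort(cfg)
  fit_a <- fit_aft(tab, "death", reference = "a", B = 0)
  fit_b <- fit_aft(tab[tab$group != "a", ], "death", reference = "b", B = 0)
  beta_ca <- fit_a$effects$beta[fit_a$effects$group == "c"]
  beta_ba <- fit_a$effects$beta[fit_a$effects$group == "b"]
  beta_cb <- fit_b$effects$beta[fit_b$effects$group == "c"]
  expect_lt(abs(beta_ca - beta_ba * beta_cb) / beta_ca, 0.05)
})

test_that("decomposition is the exact inverse of reconstruction", {
  d <- decompose_effects(2, 0.5)
  expect_equal(d$delta_mu_s, 0)          # purely disproportional
  expect_equal(d$R_f, 0.25)
  e <- decompose_effects(1.7, 1.7)
  expect_equal(e$R_f, 1)                 # purely proportional
  expect_equal(e$delta_mu_s, log(1.7))
  for (pair in list(c(1.87, 1.78), c(0.3, 2.4), c(1, 1))) {
    dec <- decompose_effects(pair[1], pair[2])
    back <- reconstruct_effects(dec)
    expect_lt(max(abs(back - pair)), 1e-10)
  }
  expect_error(decompose_effects(-1, 2), "> 0")
  # bootstrap propagation gives finite, ordered intervals
  set.seed(46)
  bv <- rnorm(500, log(1.5), 0.05); bd <- rnorm(500, log(1.2), 0.05)
  dd <- decompose_effects(1.5, 1.2, bv, bd)
  expect_lt(dd$ci_R_f[1], dd$ci_R_f[2])
  expect_lt(dd$ci_delta_mu_s[1], dd$delta_mu_s + 0.1)
})

test_that("dose-response profiles order doses and flag regimes", {
  doses <- c(50, 125, 250, 375, 500, 650, 800)
  # constant R_f below 187 and above 500; declining in between
  rf <- ifelse(doses < 187, 1, ifelse(doses <= 500,
                                      1 - 0.002 * (doses - 187), 0.37))
  dmu <- -0.001 * doses
  beta_v <- exp(dmu - log(rf) / 2)
  beta_d <- exp(dmu + log(rf) / 2)
  mk <- function(beta, ep) {
    structure(list(effects = data.frame(group = as.character(doses),
                                        beta = beta),
                   endpoint = ep, reference = "0"), class = "aft_fit")
  }
  prof <- dose_response_profile(mk(beta_v, "vmc"), mk(beta_d, "death"),
                                breakpoints = c(187, 500))
  expect_equal(prof$dose, c(0, doses))
  expect_equal(prof$R_f[prof$dose == 250],
               1 - 0.002 * (250 - 187), tolerance = 1e-10)
  reg <- attr(prof, "regimes")
  expect_false(isTRUE(reg$shared_upstream[reg$regime == 1]))
  # all-null doses: beta 1, R_f 1, delta_mu 0
  null_prof <- dose_response_profile(mk(rep(1, 7), "vmc"),
                                     mk(rep(1, 7), "death"))
  expect_true(all(null_prof$R_f == 1))
  expect_true(all(null_prof$delta_mu_s == 0))
  expect_error(dose_response_profile(mk(beta_v, "vmc"),
                                     structure(list(effects = data.frame(
                                       group = "10", beta = 1),
                                       endpoint = "death",
                                       reference = "ctrl"),
                                       class = "aft_fit")),
               "reference")
})
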