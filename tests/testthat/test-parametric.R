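test_that("closed-form hazards match their printed forms at anchor points", {
  expect_equal(hazard_value("gompertz", c(a = 0.02, b = 0.3), 0), 0.02 * 0.3)
  # weibull with alpha = 1 is the exponential
  expect_equal(hazard_value("weibull", c(alpha = 1, beta = 5), c(1, 7, 30)),
               rep(1 / 5, 3))
  # frailty with sigma = 0 collapses to plain weibull everywhere
  t <- seq(0.5, 60, by = 0.5)
  expect_equal(hazard_value("weibull_frailty", c(3, 20, 0), t),
               hazard_value("weibull", c(3, 20), t))
  expect_error(hazard_value("gompertz", c(-1, 2), 1), "positive")
  expect_error(hazard_value("weibull", c(1, 2, 3), 1), "parameters")
})

test_that("inverse gaussian hazard equals -d log S/dt numerically", {
  p <- c(mu = 20, lambda = 50)
  # grid starts where S is meaningfully below 1, so the finite differences
  # of log S are not dominated by floating-point roundoff
  t <- seq(5, 60, by = 0.5)
  h <- hazard_value("inverse_gaussian", p, t)
  logS <- function(tt) log(survival_value("inverse_gaussian", p, tt))
  eps <- 1e-3  # richardson-extrapolated central differences
  d1 <- -(logS(t + eps) - logS(t - eps)) / (2 * eps)
  d2 <- -(logS(t + eps / 2) - logS(t - eps / 2)) / eps
  hn <- (4 * d2 - d1) / 3
  expect_lt(max(abs(h - hn) / hn), 1e-6)
})

test_that("survival is a proper decreasing distribution for every family", {
  cases <- list(gompertz = c(0.01, 0.15), weibull = c(3, 20),
                weibull_frailty = c(3, 20, 0.8), inverse_gaussian = c(20, 50))
  for (fam in names(cases)) {
    p <- cases[[fam]]
    t <- seq(0.01, 200, length.out = 500)  # 10x the scale
    S <- survival_value(fam, p, t)
    expect_equal(survival_value(fam, p, 0), 1)
    expect_true(all(diff(S) <= 1e-12), info = fam)
    expect_lt(S[length(S)], 1e-4)
    I <- integrate(function(x) density_value(fam, p, x), 1e-8, Inf,
                   rel.tol = 1e-8)$value
    expect_lt(abs(I - 1), 1e-4)
  }
})

test_that("censored log-likelihood matches its closed-form pieces", {
  # single uncensored point under the exponential (weibull alpha = 1)
  expect_equal(log_likelihood("weibull", c(1, 5), 3), log(1 / 5) - 3 / 5)
  # all-censored sample contributes only log S terms
  tms <- c(4, 9, 13)
  expect_equal(log_likelihood("gompertz", c(0.01, 0.2), tms,
                              censored = rep(TRUE, 3)),
               sum(log(survival_value("gompertz", c(0.01, 0.2), tms))))
  # density oracle: sum log f for uncensored data, f = h * S
  set.seed(7); x <- rweibull(50, 2, 10)
  expect_equal(log_likelihood("weibull_frailty", c(2, 10, 0.5), x),
               sum(log(density_value("weibull_frailty", c(2, 10, 0.5), x))),
               tolerance = 1e-10)
  # extreme times stay finite (log-space evaluation)
  expect_true(is.finite(log_likelihood("inverse_gaussian", c(20, 50),
                                       c(2, 500, 2000))))
})

test_that("maximum likelihood recovers generating parameters", {
  set.seed(8)
  f <- fit_parametric(rweibull(1500, 3, 20), family = "weibull")
  expect_true(f$converged)
  expect_lt(abs(coef(f)["alpha"] - 3) / 3, 0.1)
  expect_lt(abs(coef(f)["beta"] - 20) / 20, 0.05)
  # stored loglik equals the recomputed likelihood at the estimates
  expect_equal(f$loglik, log_likelihood("weibull", coef(f), f$times),
               tolerance = 1e-8)
  # censoring handled: censor the top quartile
  set.seed(9)
  y <- rweibull(1500, 3, 20); cens <- y > quantile(y, 0.75)
  y[cens] <- quantile(y, 0.75)
  fc <- fit_parametric(y, cens, family = "weibull")
  expect_lt(abs(coef(fc)["beta"] - 20) / 20, 0.1)
  expect_error(fit_parametric(c(5, 6, 7), family = "weibull"), "10 uncensored")
})

test_that("fits agree with flexsurv on the same data", {
  skip_if_not_installed("flexsurv")
  set.seed(10)
  x <- rweibull(600, 2.5, 15)
  f <- fit_parametric(x, family = "weibull")
  ff <- flexsurv::flexsurvreg(survival::Surv(x) ~ 1, dist = "weibull")
  expect_equal(f$loglik, ff$loglik, tolerance = 1e-5)
  g <- fit_parametric(x, family = "gompertz")
  gf <- flexsurv::flexsurvreg(survival::Surv(x) ~ 1, dist = "gompertz")
  expect_equal(g$loglik, gf$loglik, tolerance = 1e-5)
  # same hazard curve under the parameter translation a_flex = a * b
  expect_equal(unname(coef(g)["a"] * coef(g)["b"]),
               unname(exp(gf$coefficients["rate"])), tolerance = 1e-3)
})

test_that("wiener passage times fit the inverse gaussian first-passage law", {
  tab <- simulate_aging(fast_single(n = 2000, seed = 23))
  f <- fit_parametric(tab$vmc_time, family = "inverse_gaussian")
  expect_lt(abs(coef(f)["mu"] - 2000) / 2000, 0.05)
  expect_lt(abs(coef(f)["lambda"] - 2000^2 / 5) / (2000^2 / 5), 0.05)
})

test_that("frailty fit on frailty-free data does not claim heterogeneity", {
  set.seed(11)
  x <- rweibull(1000, 3, 20)
  f0 <- fit_parametric(x, family = "weibull")
  f1 <- suppressWarnings(fit_parametric(x, family = "weibull_frailty"))
  lr <- 2 * (f1$loglik - f0$loglik)
  # nested null on the sigma = 0 boundary: compare to chi2(1) at 5%
  expect_lt(lr, qchisq(0.95, df = 1))
})

test_that("frailty model wins the AIC comparison when frailty is real", {
  set.seed(12)
  wins <- 0L; n_rep <- 20L
  for (r in seq_len(n_rep)) {
    Z <- rgamma(800, shape = 1, rate = 1)           # sigma^2 = 1
    y <- 20 * (rexp(800) / Z)^(1 / 3)
    fits <- suppressWarnings(list(
      fit_parametric(y, family = "weibull_frailty"),
      fit_parametric(y, family = "weibull"),
      fit_parametric(y, family = "gompertz")))
    aics <- vapply(fits, AIC, numeric(1))
    wins <- wins + (which.min(aics) == 1L)
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("simulate() draws match the fitted family", {
  p <- c(mu = 20, lambda = 50)
  set.seed(13)
  y <- wormspan:::simulate_family("inverse_gaussian", p, 4000)
  ks <- ks.test(y, function(q) ig_cdf(q, 20, 50))
  expect_gt(ks$p.value, 0.01)
  set.seed(14)
  g <- wormspan:::simulate_family("gompertz", c(a = 0.01, b = 0.15), 4000)
  ks2 <- ks.test(g, function(q) 1 - survival_value("gompertz",
                                                   c(0.01, 0.15), q))
  expect_gt(ks2$p.value, 0.01)
})
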