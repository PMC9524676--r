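test_that("exact linear data are recovered exactly", {
  v <- seq(10, 40, by = 1)
  tab <- tiny_table(v = v, d = v + 5)
  fit <- fit_vmc_regression(tab, "additive")
  expect_equal(fit$slope, 1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["(Intercept)"]), 5, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  prop <- fit_vmc_regression(tiny_table(v = v, d = 1.5 * v), "proportional")
  expect_equal(prop$slope, 1.5, tolerance = 1e-8)
  expect_lt(max(abs(residuals(prop))), 1e-8)
  # noiseless d = v: the VMC term explains everything
  pr <- fit_vmc_regression(tiny_table(v = v, d = v), "additive")
  expect_equal(pr$partial_r2, 1, tolerance = 1e-6)
})

test_that("robustness disabled reduces to ordinary least squares", {
  set.seed(31)
  v <- runif(200, 100, 300); d <- 150 + 0.8 * v + rnorm(200, 0, 10)
  tab <- tiny_table(v = v, d = d)
  fit <- fit_vmc_regression(tab, "additive", robust = FALSE)
  ref <- lm(tab$death_time ~ tab$vmc_time)
  expect_equal(unname(fit$slope), unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
})

test_that("remaining-lifespan slope equals additive slope minus one (OLS)", {
  set.seed(32)
  v <- runif(400, 100, 300); d <- 140 + 0.7 * v + rnorm(400, 0, 12)
  tab <- tiny_table(v = v, d = d)
  add <- fit_vmc_regression(tab, "additive", robust = FALSE)
  rem <- fit_vmc_regression(tab, "remaining", robust = FALSE)
  expect_equal(rem$slope, add$slope - 1, tolerance = 1e-8)
  # trivial case: constant offset gives slope 0
  tc <- tiny_table(v = seq(5, 50), d = seq(5, 50) + 7)
  expect_equal(fit_vmc_regression(tc, "remaining")$slope, 0,
               tolerance = 1e-8)
})

test_that("batch terms absorb batch effects in the additive fit", {
  set.seed(33)
  n <- 300
  batch <- rep(c("s1", "s2"), each = n / 2)
  shift <- ifelse(batch == "s1", 0, 60)
  v <- runif(n, 100, 300)
  d <- 150 + 0.8 * v + shift + rnorm(n, 0, 8)
  tab <- tiny_table(v = v, d = d, batch = batch)
  fit <- fit_vmc_regression(tab, "additive", robust = FALSE)
  expect_lt(abs(fit$slope - 0.8), 0.05)
  expect_true(any(grepl("batch", names(coef(fit)))))
  # pooling without batch terms would inflate the slope
  naive <- coef(lm(tab$death_time ~ tab$vmc_time))[2]
  expect_gt(abs(naive - 0.8), abs(fit$slope - 0.8))
})

test_that("multi-group multi-batch designs fit with full rank", {
  tab <- generate_cohort(cohort_config(
    n_per_group = 120, fold_vmc = c(control = 1, treated = 1.4),
    fold_death = c(control = 1, treated = 1.4), seed = 30))
  fit <- fit_vmc_regression(tab, "additive", robust = TRUE)
  expect_false(anyNA(coef(fit)))
  expect_true(any(grepl("group", names(coef(fit)))))
  expect_gt(fit$slope, 0); expect_lt(fit$slope, 1.5)
  rem <- fit_vmc_regression(tab, "remaining", robust = TRUE)
  expect_false(anyNA(coef(rem)))
})

test_that("white test matches the textbook formula and is scale invariant", {
  set.seed(34)
  x <- runif(20); e <- rnorm(20) * (1 + 2 * x)
  w <- white_test(e, data.frame(x))
  aux <- lm(I(e^2) ~ x + I(x^2))
  expect_equal(w$statistic, 20 * summary(aux)$r.squared, tolerance = 1e-8)
  expect_equal(w$df, 2)
  w2 <- white_test(3.7 * e, data.frame(x))
  expect_equal(w$statistic, w2$statistic, tolerance = 1e-10)
  # equal-magnitude residuals carry no information
  expect_equal(white_test(rep(c(-2, 2), 10), data.frame(x))$statistic, 0,
               tolerance = 1e-10)
})

test_that("white test agrees with lmtest's studentized auxiliary form", {
  skip_if_not_installed("lmtest")
  set.seed(35)
  x <- runif(150); y <- 2 + x + rnorm(150) * (1 + x)
  fit <- lm(y ~ x)
  bp <- lmtest::bptest(fit, ~ x + I(x^2))
  w <- white_test(resid(fit), data.frame(x))
  expect_equal(w$statistic, unname(bp$statistic), tolerance = 1e-8)
  expect_equal(w$p.value, unname(bp$p.value), tolerance = 1e-8)
})

test_that("additive noise shows up as heteroskedastic proportional residuals", {
  set.seed(36)
  v <- runif(800, 100, 400)
  d <- v + 150 + rnorm(800, 0, 12)   # additive, homoskedastic
  tab <- tiny_table(v = v, d = d)
  add <- fit_vmc_regression(tab, "additive", robust = FALSE)
  prop <- fit_vmc_regression(tab, "proportional", robust = FALSE)
  expect_gt(prop$white$statistic, add$white$statistic)
  expect_lt(prop$white$p.value, 0.01)
  # squared proportional residuals depend on v (curvature from the missing
  # intercept), while the additive model's do not
  r2 <- residuals(prop)^2
  quad <- summary(lm(r2 ~ v + I(v^2)))$coefficients
  expect_lt(quad["I(v^2)", "Pr(>|t|)"], 0.01)
  a2 <- summary(lm(residuals(add)^2 ~ v + I(v^2)))$coefficients
  expect_gt(a2["I(v^2)", "Pr(>|t|)"], 0.01)
})

test_that("bootstrap slope gives calibrated intervals and tail p-values", {
  set.seed(37)
  v <- runif(300, 100, 300); d <- 150 + 0.8 * v + rnorm(300, 0, 10)
  tab <- tiny_table(v = v, d = d)
  b <- bootstrap_slope(tab, "additive", B = 400, seed = 2, robust = FALSE)
  expect_lt(b$ci[1], 0.8); expect_gt(b$ci[2], 0.8)
  expect_lt(b$p_lt_1, 0.05)       # slope clearly below one
  expect_lt(b$p_ne_0, 0.01)
  expect_true(b$approx["p_ne_0"])  # beyond counting resolution
  expect_error(bootstrap_slope(tab, B = 50), "at least 200")
  same <- tiny_table(v = rep(10, 30), d = rep(20, 30))
  expect_error(bootstrap_slope(same, B = 200), "identical")
})

test_that("partial r2 handles nesting and the trivial extremes", {
  set.seed(38)
  v <- runif(200, 100, 300); d <- 30 + 0.8 * v + rnorm(200, 0, 10)
  dat <- data.frame(v = v, d = d, z = rnorm(200))
  full <- lm(d ~ v + z, data = dat)
  red <- lm(d ~ z, data = dat)
  pr <- partial_r2(full, red)
  expect_gt(pr, 0.5); expect_lte(pr, 1)
  expect_equal(partial_r2(full, full), 0)
  expect_error(partial_r2(red, full), "not nested")
})

test_that("segmented fits recover exact and synthetic broken lines", {
  x <- seq(0, 10, by = 0.25)
  y <- 2 + 1.5 * x
  f <- segmented_fit(x, y, breakpoints = c(3, 7))
  expect_equal(f$slopes, rep(1.5, 3), tolerance = 1e-8)
  expect_lt(f$rss, 1e-16)
  # known breakpoints at 187 and 500, distinct slopes
  set.seed(39)
  dose <- seq(0, 800, by = 20)
  truth <- ifelse(dose < 187, 0.01 * dose,
                  ifelse(dose < 500, 1.87 - 0.002 * (dose - 187),
                         1.244 - 0.004 * (dose - 500)))
  yy <- truth + rnorm(length(dose), 0, 0.01)
  g <- segmented_fit(dose, yy, breakpoints = c(187, 500))
  expect_lt(abs(g$slopes[1] - 0.01) / 0.01, 0.05)
  expect_lt(abs(g$slopes[2] + 0.002) / 0.002, 0.05)
  expect_lt(abs(g$slopes[3] + 0.004) / 0.004, 0.05)
  # automatic search lands near the true breaks
  h <- segmented_fit(dose, yy)
  expect_lt(abs(h$breakpoints[1] - 187), 60)
  expect_error(segmented_fit(x, y, breakpoints = c(9.9)), "2 points")
})
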