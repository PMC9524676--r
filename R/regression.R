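#' Relate movement-cessation times to lifespan within a population
#'
#' Fits one of three batch-adjusted regression models to the fully
#' observed (uncensored) VMC/death pairs of an event table:
#' \describe{
#'   \item{`additive`}{`d_i = beta_v v_i + beta_R R_i (+ beta_cross X_i R_i)
#'     + c`: death time on VMC time with batch intercepts `R_i` and, when
#'     several groups are present, group-by-batch interaction terms `X_i
#'     R_i`.  `beta_v < 1` means individuals ceasing vigorous movement
#'     later have less life remaining afterwards.}
#'   \item{`proportional`}{zero-intercept fit of `d_i` on `v_i` with
#'     per-batch slope adjustments, the model implied by treating the
#'     vigorous span as a fixed fraction of lifespan.}
#'   \item{`remaining`}{`(d_i - v_i)` on `v_i` with the additive model's
#'     adjustment terms; in the single-batch OLS case its slope equals the
#'     additive slope minus one exactly.}
#' }
#' By default coefficients are estimated by Huber M-estimation
#' ([MASS::rlm()]), which downweights outlying individuals; `robust =
#' FALSE` gives ordinary least squares.  A White test of the residuals
#' against the VMC regressor quantifies heteroskedasticity, which is how
#' the additive and proportional descriptions are compared: the
#' mis-specified one leaves residual spread that grows with `v`.
#'
#' @param table An [event_table()].
#' @param model `"additive"`, `"proportional"` or `"remaining"`.
#' @param robust Use Huber M-estimation (default) or OLS.
#' @param maxit,acc Iteration limit and convergence tolerance passed to
#'   [MASS::rlm()].
#' @return An object of class `vmc_regression` with components `slope`
#'   (the VMC coefficient), `coefficients`, `residuals`, `white` (list:
#'   `statistic`, `df`, `p.value`), `partial_r2` (for the VMC term), `fit`
#'   (the underlying `lm`/`rlm`) and `n`; methods: `print`, `summary`,
#'   `coef`, `residuals`.
#' @examples
#' tab <- simulate_aging(aging_model("single", n = 300, seed = 2))
#' fit <- fit_vmc_regression(tab, "additive")
#' fit$slope   # ~1 for the memoryless single-process model
#' @export
fit_vmc_regression <- function(table, model = c("additive", "proportional",
                                                "remaining"),
                               robust = TRUE, maxit = 100, acc = 1e-8) {
  model <- match.arg(model)
  stopifnot(inherits(table, "event_table"))
  full <- observed_pairs(table)
  if (nrow(full) < 3) stop("need at least 3 fully observed individuals")
  dat <- data.frame(v = full$vmc_time, d = full$death_time,
                    batch = factor(full$batch), group = factor(full$group))
  dat$y <- if (model == "remaining") dat$d - dat$v else dat$d
  small <- table(dat$batch)
  if (any(small < 5)) {
    warning("batch(es) with fewer than 5 individuals: ",
            paste(names(small)[small < 5], collapse = ", "))
  }
  multi_batch <- nlevels(dat$batch) > 1
  multi_group <- nlevels(dat$group) > 1
  # group-by-batch adjustment includes the group main effect so the design
  # stays full rank (rlm refuses rank-deficient fits)
  rhs <- if (model == "proportional") {
    if (multi_batch) {
      # per-batch slope offsets relative to the reference batch; built as
      # explicit dummies because `0 + v + v:batch` expands over all levels
      # and is rank deficient
      lv <- levels(dat$batch)[-1]
      cols <- paste0("v_x_", make.names(lv))
      for (i in seq_along(lv)) dat[[cols[i]]] <- dat$v * (dat$batch == lv[i])
      paste(c("0 + v", cols), collapse = " + ")
    } else "0 + v"
  } else if (multi_batch && multi_group) {
    "v + group * batch"
  } else if (multi_batch) {
    "v + batch"
  } else if (multi_group) {
    "v + group"
  } else "v"
  fml <- stats::as.formula(paste("y ~", rhs))
  fit <- fit_lm_or_rlm(fml, dat, robust, maxit, acc)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design matrix (aliased coefficients)")
  }
  res <- stats::residuals(fit)
  wts <- if (robust) fit$w else rep(1, nrow(dat))
  reduced_rhs <- if (model == "proportional") {
    "1"
  } else if (multi_batch && multi_group) {
    "group * batch"
  } else if (multi_batch) {
    "batch"
  } else if (multi_group) {
    "group"
  } else "1"
  red <- stats::lm(stats::as.formula(paste("y ~", reduced_rhs)),
                   data = dat, weights = wts)
  sse_full <- sum(wts * res^2)
  sse_red <- sum(wts * stats::residuals(red)^2)
  pr2 <- if (sse_red > 0) max(0, (sse_red - sse_full) / sse_red) else 0
  wt <- white_test(res, dat["v"])
  out <- list(model = model, slope = unname(stats::coef(fit)["v"]),
              coefficients = stats::coef(fit), residuals = res,
              white = wt, partial_r2 = pr2, fit = fit, robust = robust,
              formula = fml, n = nrow(dat), data = dat)
  class(out) <- "vmc_regression"
  out
}

fit_lm_or_rlm <- function(fml, dat, robust, maxit = 100, acc = 1e-8) {
  ols <- stats::lm(fml, data = dat)
  if (!robust) return(ols)
  # an exact fit has zero residual scale, where the Huber IRLS cannot
  # iterate (and equals OLS anyway)
  if (sum(stats::residuals(ols)^2) <=
      1e-20 * max(sum(dat$y^2), 1)) {
    ols$w <- rep(1, nrow(dat))
    return(ols)
  }
  MASS::rlm(fml, data = dat, maxit = maxit, acc = acc)
}

#' @export
print.vmc_regression <- function(x, ...) {
  cat("VMC-lifespan regression (", x$model, ", ",
      if (x$robust) "Huber M-estimation" else "OLS", ", n = ", x$n, ")\n",
      sep = "")
  cat("  VMC slope:", format(x$slope, digits = 4), "\n")
  cat("  partial R^2 (VMC term):", format(x$partial_r2, digits = 3), "\n")
  cat("  White test:", format(x$white$statistic, digits = 4),
      "on", x$white$df, "df, p =", format.pval(x$white$p.value, digits = 3),
      "\n")
  invisible(x)
}

#' @export
summary.vmc_regression <- function(object, ...) summary(object$fit, ...)

#' @export
coef.vmc_regression <- function(object, ...) object$coefficients

#' @export
residuals.vmc_regression <- function(object, ...) object$residuals

#' White test for heteroskedastic residuals
#'
#' Regresses squared residuals on the regressors, their squares and
#' pairwise cross-products; the statistic is `n R^2` of that auxiliary
#' regression, asymptotically chi-squared with as many degrees of freedom
#' as (non-collinear) auxiliary regressors.  Invariant to rescaling the
#' residuals.
#'
#' @param residuals Residual vector.
#' @param regressors Data frame or matrix of the model's continuous
#'   regressors.
#' @return List with `statistic`, `df` and `p.value`.
#' @examples
#' set.seed(1); x <- runif(200); e <- rnorm(200)
#' white_test(e, data.frame(x))$p.value  # no heteroskedasticity
#' @export
white_test <- function(residuals, regressors) {
  X <- as.matrix(as.data.frame(regressors))
  n <- length(residuals)
  if (nrow(X) != n) stop("residuals and regressors differ in length")
  aux <- cbind(X, X^2)
  p <- ncol(X)
  if (p > 1) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      aux <- cbind(aux, X[, i] * X[, j])
    }
  }
  if (n <= ncol(aux) + 1) stop("too few observations for the auxiliary regression")
  e2 <- residuals^2
  afit <- stats::lm(e2 ~ aux)
  cf <- stats::coef(afit)[-1]
  if (anyNA(cf)) {
    warning("collinear auxiliary regressors dropped from the White test")
  }
  df <- sum(!is.na(cf))
  tss <- sum((e2 - mean(e2))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(afit)^2) / tss else 0
  stat <- n * r2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Bootstrap inference for the VMC-lifespan slope
#'
#' Case-resampling bootstrap stratified by batch: individuals are resampled
#' with replacement within each batch, the chosen regression model is refit
#' and the VMC slope recorded.  Reports the percentile 95% confidence
#' interval, the one-sided bootstrap p-value for `beta_v < 1` and the
#' two-sided p-value for `beta_v != 0`.  When no resample falls on the far
#' side of the hypothesized value the p-value is below the `1/B`
#' resolution of counting; it is then approximated from a normal fit to
#' the bootstrap distribution and flagged as approximate.
#'
#' @param table An [event_table()].
#' @inheritParams fit_vmc_regression
#' @param B Number of bootstrap resamples (`>= 200`).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @return An object of class `slope_boot` with components `slope`
#'   (point estimate), `ci`, `p_lt_1`, `p_ne_0`, `approx` (logical flags),
#'   `draws` and `n_redrawn`.
#' @export
bootstrap_slope <- function(table, model = c("additive", "proportional",
                                             "remaining"),
                            B = 2000, seed = 1L, robust = TRUE,
                            conf = 0.95) {
  model <- match.arg(model)
  if (B < 200) stop("B must be at least 200")
  if (stats::var(observed_pairs(table)$vmc_time) == 0) {
    stop("all VMC times identical: slope not estimable")
  }
  point <- fit_vmc_regression(table, model, robust = robust)
  dat <- point$data
  set.seed(seed)
  idx_by_batch <- split(seq_len(nrow(dat)), dat$batch)
  draws <- numeric(B)
  n_redrawn <- 0
  for (b in seq_len(B)) {
    repeat {
      idx <- unlist(lapply(idx_by_batch, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      if (stats::var(dat$v[idx]) > 0) break
      n_redrawn <- n_redrawn + 1
    }
    bfit <- tryCatch(
      fit_lm_or_rlm(point$formula, dat[idx, , drop = FALSE], robust),
      error = function(e) NULL)
    draws[b] <- if (is.null(bfit)) NA else unname(stats::coef(bfit)["v"])
  }
  if (n_redrawn > 0) {
    warning(n_redrawn, " degenerate resample(s) redrawn")
  }
  draws <- draws[is.finite(draws)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
  mB <- mean(draws); sB <- stats::sd(draws)
  tail_p <- function(count_p, normal_p) {
    if (count_p < 1 / length(draws)) list(p = normal_p, approx = TRUE)
    else list(p = count_p, approx = FALSE)
  }
  lt1 <- tail_p(mean(draws >= 1),
                stats::pnorm(1, mB, sB, lower.tail = FALSE))
  ne0 <- tail_p(2 * min(mean(draws <= 0), mean(draws >= 0)),
                2 * stats::pnorm(-abs(mB) / sB))
  out <- list(model = model, slope = point$slope, ci = ci,
              p_lt_1 = lt1$p, p_ne_0 = min(ne0$p, 1),
              approx = c(p_lt_1 = lt1$approx, p_ne_0 = ne0$approx),
              draws = draws, B = B, n_redrawn = n_redrawn, conf = conf)
  class(out) <- "slope_boot"
  out
}

#' @export
print.slope_boot <- function(x, ...) {
  cat(sprintf("Bootstrap slope (%s model, B = %d): %.4f, %d%% CI (%.4f, %.4f)\n",
              x$model, x$B, x$slope, round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(sprintf("  p(beta_v < 1) = %s%s, p(beta_v != 0) = %s%s\n",
              format.pval(x$p_lt_1, digits = 3),
              if (x$approx["p_lt_1"]) " (normal approx.)" else "",
              format.pval(x$p_ne_0, digits = 3),
              if (x$approx["p_ne_0"]) " (normal approx.)" else ""))
  invisible(x)
}

#' Partial coefficient of determination
#'
#' `(SSE_reduced - SSE_full) / SSE_reduced` for a reduced model nested in
#' the full model, computed on robust-weighted residuals when the full fit
#' is a Huber M-estimate (the full fit's final weights are applied to both
#' models so the comparison is at matched weighting).
#'
#' @param full,reduced Fitted models (`vmc_regression`, `lm` or `rlm`);
#'   the reduced model's terms must be a subset of the full model's.
#' @return The partial R-squared, in `[0, 1]`.
#' @export
partial_r2 <- function(full, reduced) {
  get_fit <- function(x) if (inherits(x, "vmc_regression")) x$fit else x
  ffit <- get_fit(full); rfit <- get_fit(reduced)
  ft <- attr(stats::terms(ffit), "term.labels")
  rt <- attr(stats::terms(rfit), "term.labels")
  if (!all(rt %in% ft)) stop("reduced model is not nested in the full model")
  w <- if (!is.null(ffit$w)) ffit$w else rep(1, length(stats::residuals(ffit)))
  X <- stats::model.matrix(rfit)
  yv <- stats::model.response(stats::model.frame(rfit))
  refit <- stats::lm.wfit(X, yv, w)
  sse_f <- sum(w * stats::residuals(ffit)^2)
  sse_r <- sum(w * refit$residuals^2)
  if (sse_r <= 0) return(0)
  max(0, min(1, (sse_r - sse_f) / sse_r))
}

#' Continuous piecewise-linear (segmented) least squares
#'
#' Fits a continuous broken-line model of `y` on `x` with the given
#' breakpoints, or, when `breakpoints = NULL`, grid-searches breakpoint
#' locations over quantiles of `x` to minimize the residual sum of
#' squares.  Used for tri-phasic dose-response profiles where an
#' intervention acts through different routes in different dose regimes.
#'
#' @param x,y Numeric vectors (dose and effect).
#' @param breakpoints Increasing breakpoint locations inside `range(x)`,
#'   or `NULL` to search.
#' @param n_segments Number of segments when searching (default 3).
#' @return An object of class `segmented_fit` with `breakpoints`, `slopes`
#'   and `intercepts` (one per segment), `rss`, `fitted` and
#'   `coefficients`.
#' @examples
#' x <- seq(0, 10, by = 0.25)
#' y <- ifelse(x < 4, x, 4 + 3 * (x - 4))
#' segmented_fit(x, y, breakpoints = 4)$slopes  # 1, 3
#' @export
segmented_fit <- function(x, y, breakpoints = NULL, n_segments = 3) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  o <- order(x); x <- x[o]; y <- y[o]
  if (is.null(breakpoints)) {
    n_bp <- n_segments - 1
    cand <- unique(stats::quantile(x, seq(0.1, 0.9, length.out = 12),
                                   names = FALSE, type = 7))
    combos <- utils::combn(cand, n_bp, simplify = FALSE)
    best <- NULL
    for (bp in combos) {
      f <- tryCatch(segmented_fit(x, y, breakpoints = bp),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
    }
    if (is.null(best)) stop("no breakpoint placement leaves >= 2 points per segment")
    return(best)
  }
  breakpoints <- sort(breakpoints)
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly increasing")
  seg <- findInterval(x, breakpoints)
  if (any(table(factor(seg, levels = 0:length(breakpoints))) < 2)) {
    stop("each segment needs at least 2 points")
  }
  basis <- cbind(1, x)
  for (b in breakpoints) basis <- cbind(basis, pmax(x - b, 0))
  fit <- stats::lm.fit(basis, y)
  cf <- fit$coefficients
  slopes <- cumsum(cf[-1])
  intercepts <- numeric(length(slopes))
  intercepts[1] <- cf[1]
  if (length(breakpoints)) {
    for (s in seq_along(breakpoints)) {
      intercepts[s + 1] <- intercepts[s] +
        (slopes[s] - slopes[s + 1]) * breakpoints[s]
    }
  }
  out <- list(breakpoints = breakpoints, slopes = unname(slopes),
              intercepts = unname(intercepts),
              rss = sum(fit$residuals^2), fitted = unname(fit$fitted.values),
              coefficients = cf, x = x, y = y)
  class(out) <- "segmented_fit"
  out
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented linear fit with breakpoints at",
      paste(signif(x$breakpoints, 4), collapse = ", "), "\n")
  cat("  slopes:", paste(signif(x$slopes, 4), collapse = ", "), "\n")
  cat("  RSS:", format(x$rss, digits = 5), "\n")
  invisible(x)
}

#' @export
plot.segmented_fit <- function(x, xlab = "x", ylab = "y", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$x, x$fitted, col = 2, lwd = 2)
  graphics::abline(v = x$breakpoints, lty = 3)
  invisible(x)
}
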