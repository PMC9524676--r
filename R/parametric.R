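#' Parametric hazard families
#'
#' Closed-form hazard, survival and density for the four families used to
#' model worm mortality and movement-cessation times:
#' \describe{
#'   \item{`gompertz`}{`h(t) = a b exp(b t)`, parameters `a, b > 0`.}
#'   \item{`weibull`}{`h(t) = (alpha/beta) (t/beta)^(alpha-1)`.}
#'   \item{`weibull_frailty`}{Weibull baseline with unit-mean gamma frailty
#'     of variance `sigma^2` acting multiplicatively on the hazard; the
#'     population hazard is
#'     `h(t) = (alpha/beta)(t/beta)^(alpha-1) / (1 + sigma^2 (t/beta)^alpha)`,
#'     which rises and then decelerates as frail individuals are culled.}
#'   \item{`inverse_gaussian`}{first-passage law of a drifted Wiener
#'     process, mean `mu` and shape `lambda`; survival
#'     `S(t) = Phi(sqrt(lambda/t)(1 - t/mu)) -
#'       exp(2 lambda/mu) Phi(-sqrt(lambda/t)(1 + t/mu))`.}
#' }
#' Parameter vectors are named: `c(a=, b=)`, `c(alpha=, beta=)`,
#' `c(alpha=, beta=, sigma=)`, `c(mu=, lambda=)`.
#'
#' @param family Family name.
#' @param params Named (or positionally ordered) parameter vector.
#' @param t Positive times (`t >= 0` allowed for Gompertz).
#' @return Numeric vector of rates / probabilities / densities.
#' @examples
#' hazard_value("gompertz", c(a = 0.01, b = 0.15), 0)   # a*b
#' survival_value("weibull", c(alpha = 3, beta = 20), 20) # exp(-1)
#' @name parametric_families
NULL

ws_families <- c("gompertz", "weibull", "weibull_frailty", "inverse_gaussian")

ws_param_names <- list(
  gompertz = c("a", "b"),
  weibull = c("alpha", "beta"),
  weibull_frailty = c("alpha", "beta", "sigma"),
  inverse_gaussian = c("mu", "lambda"))

check_params <- function(family, params) {
  family <- match.arg(family, ws_families)
  nm <- ws_param_names[[family]]
  if (length(params) != length(nm)) {
    stop(family, " needs ", length(nm), " parameters (",
         paste(nm, collapse = ", "), ")")
  }
  params <- stats::setNames(as.numeric(params), nm)
  strict <- setdiff(nm, "sigma")     # sigma = 0 collapses frailty to Weibull
  if (any(!is.finite(params)) || any(params[strict] <= 0) ||
      ("sigma" %in% nm && params["sigma"] < 0)) {
    stop("invalid parameters for ", family,
         ": scale and shape parameters must be positive (sigma >= 0)")
  }
  params
}

# log hazard, vectorized over t
log_hazard_fn <- function(family, params, t) {
  switch(family,
    gompertz = log(params["a"]) + log(params["b"]) + params["b"] * t,
    weibull = log(params["alpha"] / params["beta"]) +
      (params["alpha"] - 1) * log(t / params["beta"]),
    weibull_frailty = {
      H0 <- (t / params["beta"])^params["alpha"]
      log(params["alpha"] / params["beta"]) +
        (params["alpha"] - 1) * log(t / params["beta"]) -
        log1p(params["sigma"]^2 * H0)
    },
    inverse_gaussian = log_dens_fn("inverse_gaussian", params, t) -
      log_surv_fn("inverse_gaussian", params, t))
}

# log survival, computed in log space to avoid underflow
log_surv_fn <- function(family, params, t) {
  switch(family,
    gompertz = -params["a"] * expm1(params["b"] * t),
    weibull = -(t / params["beta"])^params["alpha"],
    weibull_frailty = {
      H0 <- (t / params["beta"])^params["alpha"]
      s2 <- params["sigma"]^2
      if (s2 == 0) -H0 else -log1p(s2 * H0) / s2
    },
    inverse_gaussian = {
      mu <- params["mu"]; lam <- params["lambda"]
      rt <- sqrt(lam / t)
      la <- stats::pnorm(rt * (1 - t / mu), log.p = TRUE)
      lb <- 2 * lam / mu + stats::pnorm(-rt * (1 + t / mu), log.p = TRUE)
      # S = exp(la) - exp(lb), with la > lb guaranteed since S > 0
      la + log1p(-exp(pmin(lb - la, 0)))
    })
}

log_dens_fn <- function(family, params, t) {
  if (family == "inverse_gaussian") {
    mu <- params["mu"]; lam <- params["lambda"]
    0.5 * (log(lam) - log(2 * pi) - 3 * log(t)) -
      lam * (t - mu)^2 / (2 * mu^2 * t)
  } else {
    log_hazard_fn(family, params, t) + log_surv_fn(family, params, t)
  }
}

#' @rdname parametric_families
#' @export
hazard_value <- function(family, params, t) {
  family <- match.arg(family, ws_families)
  params <- check_params(family, params)
  if (family != "gompertz" && any(t <= 0)) stop("t must be > 0")
  if (family == "gompertz" && any(t < 0)) stop("t must be >= 0")
  unname(exp(log_hazard_fn(family, params, t)))
}

#' @rdname parametric_families
#' @export
survival_value <- function(family, params, t) {
  family <- match.arg(family, ws_families)
  params <- check_params(family, params)
  out <- ifelse(t <= 0, 0, log_surv_fn(family, params, pmax(t, 1e-300)))
  unname(exp(out))
}

#' @rdname parametric_families
#' @export
density_value <- function(family, params, t) {
  family <- match.arg(family, ws_families)
  params <- check_params(family, params)
  if (any(t <= 0)) stop("t must be > 0")
  unname(exp(log_dens_fn(family, params, t)))
}

#' Censored survival log-likelihood
#'
#' `sum over uncensored of log h(t_i) + sum over all of log S(t_i)`,
#' evaluated in log space so that extreme times never produce `-Inf` from
#' rounding alone.
#'
#' @inheritParams parametric_families
#' @param times Positive event / censoring times.
#' @param censored Logical right-censoring flags.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(family, params, times,
                           censored = rep(FALSE, length(times))) {
  family <- match.arg(family, ws_families)
  params <- check_params(family, params)
  stopifnot(length(times) >= 1, length(censored) == length(times))
  if (any(times <= 0)) stop("times must be positive")
  censored <- as.logical(censored)
  ll <- sum(log_surv_fn(family, params, times))
  if (any(!censored)) {
    ll <- ll + sum(log_hazard_fn(family, params, times[!censored]))
  }
  unname(ll)
}

# moment / quantile based starting values on the natural scale
start_values <- function(family, times, censored) {
  obs <- times[!censored]
  m <- mean(obs); s <- stats::sd(obs); if (!is.finite(s) || s == 0) s <- m / 4
  base <- switch(family,
    gompertz = {
      b0 <- 1 / s
      a0 <- log(2) / max(expm1(b0 * stats::median(obs)), 1e-8)
      c(a = a0, b = b0)
    },
    weibull = {
      alpha0 <- max((s / m)^-1.086, 0.2)   # CV ~ alpha^-1.086 approximation
      c(alpha = alpha0, beta = m / gamma(1 + 1 / alpha0))
    },
    weibull_frailty = {
      alpha0 <- max((s / m)^-1.086, 0.2)
      c(alpha = alpha0, beta = m / gamma(1 + 1 / alpha0), sigma = 0.3)
    },
    inverse_gaussian = c(mu = m, lambda = max(m^3 / s^2, 1e-8)))
  scales <- list(1, c(0.5, 2), c(2, 0.5), c(1.5, 1.5), c(0.6, 0.6))
  lapply(scales, function(sc) {
    sc <- rep_len(sc, length(base))
    out <- base * sc
    if (family == "weibull_frailty") out["sigma"] <- base["sigma"] / sc[1]
    out
  })
}

#' Fit a parametric hazard family by censored maximum likelihood
#'
#' Maximizes the censored log-likelihood by BFGS in log-parameter space
#' (which keeps all parameters positive) from five moment/quantile-based
#' starting points, keeping the best converged solution.  The approximate
#' covariance of the estimates comes from the inverse Hessian at the
#' optimum, mapped back to the natural scale by the delta method.
#'
#' @inheritParams log_likelihood
#' @param family One of `"gompertz"`, `"weibull"`, `"weibull_frailty"`,
#'   `"inverse_gaussian"`.
#' @return An object of class `parametric_fit` with components `family`,
#'   `par` (named estimates), `loglik`, `converged`, `vcov`, `n` and
#'   `n_events`; methods: `print`, `summary`, `coef`, `logLik`, `vcov`,
#'   `predict` (hazard/survival/density/cumhaz at new times) and
#'   `simulate`.
#' @examples
#' set.seed(1)
#' fit <- fit_parametric(rweibull(500, 3, 20), family = "weibull")
#' coef(fit)
#' AIC(fit)
#' @export
fit_parametric <- function(times, censored = rep(FALSE, length(times)),
                           family = c("gompertz", "weibull",
                                      "weibull_frailty", "inverse_gaussian")) {
  family <- match.arg(family)
  censored <- as.logical(censored)
  stopifnot(length(censored) == length(times))
  if (any(times <= 0) || any(!is.finite(times))) {
    stop("times must be positive and finite")
  }
  if (sum(!censored) < 10) stop("need at least 10 uncensored events")
  nm <- ws_param_names[[family]]
  negll <- function(logp) {
    p <- exp(logp)
    if (any(!is.finite(p))) return(1e12)
    ll <- tryCatch(log_likelihood(family, p, times, censored),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }
  best <- NULL
  for (st in start_values(family, times, censored)) {
    opt <- tryCatch(
      stats::optim(log(pmax(st, 1e-12)), negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed for family ", family)
  par <- stats::setNames(exp(best$par), nm)
  hess <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  vc <- NULL
  converged <- best$convergence == 0
  if (!is.null(hess)) {
    vlog <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vlog)) {
      D <- diag(par, nrow = length(par))
      vc <- D %*% vlog %*% D
      dimnames(vc) <- list(nm, nm)
      if (any(diag(vc) < 0)) converged <- FALSE
    }
  }
  out <- list(family = family, par = par, loglik = -best$value,
              converged = converged, vcov = vc,
              n = length(times), n_events = sum(!censored),
              times = times, censored = censored)
  class(out) <- "parametric_fit"
  if (!converged) {
    warning("fit for family ", family,
            " did not fully converge; parameters returned anyway")
  }
  out
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat("Parametric survival fit:", x$family, "\n")
  print(signif(x$par, 5))
  cat("logLik:", format(x$loglik, digits = 7),
      " AIC:", format(stats::AIC(x), digits = 7),
      " n =", x$n, paste0("(", x$n_events, " events)"),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
summary.parametric_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0)) else
    rep(NA_real_, length(object$par))
  tab <- data.frame(estimate = object$par, se = se,
                    lower = object$par - 1.96 * se,
                    upper = object$par + 1.96 * se)
  out <- list(family = object$family, table = tab, loglik = object$loglik,
              aic = stats::AIC(object), converged = object$converged)
  class(out) <- "summary.parametric_fit"
  out
}

#' @export
print.summary.parametric_fit <- function(x, ...) {
  cat("Family:", x$family, "\n")
  print(signif(as.matrix(x$table), 5))
  cat("logLik:", x$loglik, " AIC:", x$aic, "\n")
  invisible(x)
}

#' @export
coef.parametric_fit <- function(object, ...) object$par

#' @export
vcov.parametric_fit <- function(object, ...) object$vcov

#' @export
logLik.parametric_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par),
            nobs = object$n, class = "logLik")
}

#' @export
predict.parametric_fit <- function(object, times,
                                   type = c("hazard", "survival",
                                            "density", "cumhaz"), ...) {
  type <- match.arg(type)
  switch(type,
    hazard = hazard_value(object$family, object$par, times),
    survival = survival_value(object$family, object$par, times),
    density = density_value(object$family, object$par, times),
    cumhaz = -log(survival_value(object$family, object$par, times)))
}

#' @export
simulate.parametric_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_family(object$family, object$par, nsim)
}

# random event times from each family
simulate_family <- function(family, params, n) {
  params <- check_params(family, params)
  switch(family,
    gompertz = log1p(stats::rexp(n) / params["a"]) / params["b"],
    weibull = stats::rweibull(n, shape = params["alpha"],
                              scale = params["beta"]),
    weibull_frailty = {
      s2 <- params["sigma"]^2
      Z <- if (s2 > 0) stats::rgamma(n, shape = 1 / s2, rate = 1 / s2) else 1
      params["beta"] * (stats::rexp(n) / Z)^(1 / params["alpha"])
    },
    inverse_gaussian = rinvgauss_ws(n, params["mu"], params["lambda"]))
}

# Michael-Schucany-Haas inverse Gaussian sampler
rinvgauss_ws <- function(n, mu, lambda) {
  y <- stats::rchisq(n, df = 1)
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}
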