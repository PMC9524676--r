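#' Accelerated failure time effects of interventions
#'
#' Quantifies how each non-reference group in an event table rescales an
#' endpoint's timescale, via the log-linear AFT model
#' `log(y_i) = beta_X X_i + beta_R R_i` with group dummies `X_i` and batch
#' dummies `R_i`.  The reported effect for group `g` is the fold-change
#' `beta_g = exp(coefficient)`: a long-lived mutant that doubles lifespan
#' has `beta = 2` on the `death` endpoint.  Point estimates come from the
#' censored parametric AFT likelihood ([survival::survreg()]); with no
#' censoring and the default lognormal family they coincide with ordinary
#' least squares on log-times.  Confidence intervals and p-values against
#' `beta = 1` come from a case-resampling bootstrap stratified by
#' group-by-batch cell.
#'
#' @param table An [event_table()].
#' @param endpoint `"vmc"`, `"death"` or `"remaining"` (death minus VMC;
#'   requires VMC observed, errors if any observed death precedes VMC).
#' @param reference Reference group label (must be given explicitly; it is
#'   never inferred from label order).
#' @param dist AFT error family: `"lognormal"` (default) or `"weibull"`.
#' @param B Bootstrap resamples (`0` skips the bootstrap and falls back to
#'   the asymptotic normal intervals of the AFT fit).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return An object of class `aft_fit`: list with `effects` (data frame:
#'   `group`, `beta`, `lower`, `upper`, `p`, `p_approx`), `endpoint`,
#'   `reference`, `dist`, `fit` (the `survreg` object) and `boot` (matrix
#'   of bootstrap log-coefficients, one column per group).
#' @examples
#' cfg <- cohort_config(n_per_group = 150,
#'                      fold_vmc = c(control = 1, treated = 1.5),
#'                      fold_death = c(control = 1, treated = 1.5), seed = 3)
#' fit <- fit_aft(generate_cohort(cfg), "death", reference = "control",
#'                B = 200)
#' fit$effects   # beta ~ 1.5
#' @export
fit_aft <- function(table, endpoint = c("vmc", "death", "remaining"),
                    reference, dist = c("lognormal", "weibull"),
                    B = 1000, seed = 1L, conf = 0.95) {
  endpoint <- match.arg(endpoint)
  dist <- match.arg(dist)
  stopifnot(inherits(table, "event_table"))
  if (missing(reference)) {
    stop("`reference` group must be given explicitly")
  }
  groups <- unique(as.character(table$group))
  if (!reference %in% groups) stop("reference group not found: ", reference)
  dat <- aft_endpoint_data(table, endpoint)
  cnt <- table(dat$group)
  if (any(cnt < 20)) {
    warning("group(s) with fewer than 20 usable individuals: ",
            paste(names(cnt)[cnt < 20], collapse = ", "))
  }
  dat$group <- stats::relevel(factor(dat$group), ref = reference)
  dat$batch <- factor(dat$batch)
  fml <- if (nlevels(dat$batch) > 1) {
    survival::Surv(time, event) ~ group + batch
  } else {
    survival::Surv(time, event) ~ group
  }
  fit <- survival::survreg(fml, data = dat, dist = dist)
  cf <- stats::coef(fit)
  gl <- setdiff(levels(dat$group), reference)
  gcoef <- cf[paste0("group", gl)]
  draws <- NULL
  if (B > 0) {
    set.seed(seed)
    strata <- split(seq_len(nrow(dat)), interaction(dat$group, dat$batch,
                                                    drop = TRUE))
    draws <- matrix(NA_real_, B, length(gl),
                    dimnames = list(NULL, gl))
    for (b in seq_len(B)) {
      idx <- unlist(lapply(strata, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      bf <- tryCatch(
        suppressWarnings(
          survival::survreg(fml, data = dat[idx, , drop = FALSE],
                            dist = dist)),
        error = function(e) NULL)
      if (!is.null(bf)) {
        bc <- stats::coef(bf)[paste0("group", gl)]
        draws[b, ] <- bc
      }
    }
  }
  alpha <- (1 - conf) / 2
  eff <- lapply(gl, function(g) {
    est <- unname(gcoef[paste0("group", g)])
    if (!is.null(draws)) {
      dg <- draws[, g]; dg <- dg[is.finite(dg)]
      ci <- stats::quantile(dg, c(alpha, 1 - alpha), names = FALSE)
      cnt_p <- 2 * min(mean(dg <= 0), mean(dg >= 0))
      if (cnt_p < 1 / length(dg)) {
        p <- 2 * stats::pnorm(-abs(mean(dg)) / stats::sd(dg))
        approx <- TRUE
      } else {
        p <- cnt_p; approx <- FALSE
      }
    } else {
      se <- sqrt(diag(stats::vcov(fit)))[paste0("group", g)]
      z <- stats::qnorm(1 - alpha)
      ci <- est + c(-z, z) * se
      p <- 2 * stats::pnorm(-abs(est) / se)
      approx <- FALSE
    }
    data.frame(group = g, beta = exp(est), lower = exp(ci[1]),
               upper = exp(ci[2]), p = min(p, 1), p_approx = approx,
               stringsAsFactors = FALSE)
  })
  out <- list(effects = do.call(rbind, eff), endpoint = endpoint,
              reference = reference, dist = dist, fit = fit,
              boot = draws, seed = as.integer(seed), conf = conf,
              n = nrow(dat))
  class(out) <- "aft_fit"
  out
}

# endpoint-specific (time, event) pairs from an event table
aft_endpoint_data <- function(table, endpoint) {
  if (endpoint == "vmc") {
    keep <- !is.na(table$vmc_time)
    data.frame(time = table$vmc_time[keep],
               event = !table$vmc_censored[keep],
               group = table$group[keep], batch = table$batch[keep])
  } else if (endpoint == "death") {
    keep <- !is.na(table$death_time)
    data.frame(time = table$death_time[keep],
               event = !table$death_censored[keep],
               group = table$group[keep], batch = table$batch[keep])
  } else {
    keep <- !is.na(table$vmc_time) & !is.na(table$death_time) &
      !table$vmc_censored
    obs <- keep & !table$death_censored
    if (any(table$death_time[obs] < table$vmc_time[obs])) {
      bad <- which(obs & table$death_time < table$vmc_time)
      stop("death precedes VMC for individuals: ",
           paste(utils::head(table$individual_id[bad], 10), collapse = ", "))
    }
    rem <- table$death_time[keep] - table$vmc_time[keep]
    pos <- rem > 0
    data.frame(time = rem[pos], event = !table$death_censored[keep][pos],
               group = table$group[keep][pos], batch = table$batch[keep][pos])
  }
}

#' @export
print.aft_fit <- function(x, ...) {
  cat("AFT fold-changes (endpoint:", x$endpoint,
      "; reference:", x$reference, "; family:", x$dist, ")\n")
  eff <- x$effects
  eff$beta <- signif(eff$beta, 4)
  eff$lower <- signif(eff$lower, 4)
  eff$upper <- signif(eff$upper, 4)
  eff$p <- format.pval(eff$p, digits = 3)
  print(eff[, c("group", "beta", "lower", "upper", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.aft_fit <- function(object, ...) {
  stats::setNames(object$effects$beta, object$effects$group)
}

#' Decompose a pair of fold-changes into proportional and disproportional parts
#'
#' An intervention that rescales VMC times by `beta_vmc` and death times by
#' `beta_death` is summarized by the shared log-time shift
#' `delta_mu_s = (log beta_vmc + log beta_death) / 2` (the proportional
#' component: how much the whole life history is stretched) and the
#' disproportionality ratio `R_f = beta_death / beta_vmc` (how much more
#' the intervention acts on death than on VMC; `R_f = 1` is a purely
#' proportional effect).  The map is exactly invertible; see
#' [reconstruct_effects()].  When paired bootstrap draws of the two
#' fold-changes are supplied (from [fit_aft()] runs on the same table with
#' the same seed, so resample `b` uses the same individuals in both),
#' percentile confidence intervals are propagated to both components.
#'
#' @param beta_vmc,beta_death Positive fold-changes.
#' @param boot_vmc,boot_death Optional equal-length vectors of paired
#'   bootstrap draws of the log fold-changes (as stored in
#'   `fit_aft()$boot`).
#' @param conf Confidence level for propagated intervals.
#' @return List of class `effect_decomposition` with `delta_mu_s`, `R_f`
#'   and, when draws are given, `ci_delta_mu_s` and `ci_R_f`.
#' @examples
#' decompose_effects(2, 0.5)  # delta_mu_s = 0: purely disproportional
#' @export
decompose_effects <- function(beta_vmc, beta_death,
                              boot_vmc = NULL, boot_death = NULL,
                              conf = 0.95) {
  if (beta_vmc <= 0 || beta_death <= 0) stop("fold-changes must be > 0")
  out <- list(delta_mu_s = (log(beta_vmc) + log(beta_death)) / 2,
              R_f = beta_death / beta_vmc,
              beta_vmc = beta_vmc, beta_death = beta_death)
  if (!is.null(boot_vmc) && !is.null(boot_death)) {
    stopifnot(length(boot_vmc) == length(boot_death))
    ok <- is.finite(boot_vmc) & is.finite(boot_death)
    dmu <- (boot_vmc[ok] + boot_death[ok]) / 2
    lrf <- boot_death[ok] - boot_vmc[ok]
    alpha <- (1 - conf) / 2
    out$ci_delta_mu_s <- stats::quantile(dmu, c(alpha, 1 - alpha),
                                         names = FALSE)
    out$ci_R_f <- exp(stats::quantile(lrf, c(alpha, 1 - alpha),
                                      names = FALSE))
  }
  class(out) <- "effect_decomposition"
  out
}

#' Reconstruct fold-changes from a decomposition
#'
#' Inverse of [decompose_effects()]:
#' `beta_vmc = exp(delta_mu_s - log(R_f)/2)`,
#' `beta_death = exp(delta_mu_s + log(R_f)/2)`.
#'
#' @param delta_mu_s Shared log-time shift (or an `effect_decomposition`).
#' @param R_f Disproportionality ratio.
#' @return Named vector `c(beta_vmc, beta_death)`.
#' @export
reconstruct_effects <- function(delta_mu_s, R_f) {
  if (inherits(delta_mu_s, "effect_decomposition")) {
    R_f <- delta_mu_s$R_f
    delta_mu_s <- delta_mu_s$delta_mu_s
  }
  if (R_f <= 0) stop("R_f must be > 0")
  c(beta_vmc = exp(delta_mu_s - log(R_f) / 2),
    beta_death = exp(delta_mu_s + log(R_f) / 2))
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat(sprintf("delta_mu_s = %.4f  (proportional log-time shift)\n",
              x$delta_mu_s))
  cat(sprintf("R_f        = %.4f  (disproportionality, beta_death/beta_vmc)\n",
              x$R_f))
  if (!is.null(x$ci_delta_mu_s)) {
    cat(sprintf("  CI delta_mu_s: (%.4f, %.4f);  CI R_f: (%.4f, %.4f)\n",
                x$ci_delta_mu_s[1], x$ci_delta_mu_s[2],
                x$ci_R_f[1], x$ci_R_f[2]))
  }
  invisible(x)
}

#' Dose-response profile of paired AFT effects
#'
#' Combines two [fit_aft()] results for the same dosed cohort - one on the
#' VMC endpoint, one on death - into an ordered table of per-dose
#' fold-changes and their [decompose_effects()] components.  Group labels
#' must be numeric doses sharing the fits' common zero-dose reference.
#' When breakpoints are supplied the profile is cut into dose regimes and
#' each regime is flagged as `shared_upstream` when `R_f` is flat in dose
#' (slope not significant at `alpha`) while `delta_mu_s` still changes -
#' the signature of an intervention acting through a factor upstream of
#' both aging processes.
#'
#' @param aft_vmc,aft_death `aft_fit` objects for the `vmc` and `death`
#'   endpoints with identical groups and reference.
#' @param breakpoints Optional dose breakpoints defining regimes.
#' @param alpha Significance level for the regime slope tests.
#' @return A data frame of class `dose_response` with columns `dose`,
#'   `beta_vmc`, `beta_death`, `delta_mu_s`, `R_f`; regime summaries, when
#'   requested, are in `attr(, "regimes")`.
#' @export
dose_response_profile <- function(aft_vmc, aft_death, breakpoints = NULL,
                                  alpha = 0.05) {
  stopifnot(inherits(aft_vmc, "aft_fit"), inherits(aft_death, "aft_fit"))
  if (aft_vmc$reference != aft_death$reference) {
    stop("the two fits must share the same reference group")
  }
  ref_dose <- suppressWarnings(as.numeric(aft_vmc$reference))
  if (!isTRUE(ref_dose == 0)) {
    stop("reference group must be the zero dose (label coercible to 0)")
  }
  gv <- aft_vmc$effects$group
  gd <- aft_death$effects$group
  if (!setequal(gv, gd)) stop("the two fits cover different dose groups")
  doses <- suppressWarnings(as.numeric(gv))
  if (anyNA(doses)) stop("group labels must be numeric doses")
  if (length(doses) < 2) stop("need at least 2 non-zero dose levels")
  bv <- aft_vmc$effects$beta[match(gv, aft_vmc$effects$group)]
  bd <- aft_death$effects$beta[match(gv, aft_death$effects$group)]
  out <- data.frame(dose = c(0, doses), beta_vmc = c(1, bv),
                    beta_death = c(1, bd))
  out <- out[order(out$dose), ]
  out$delta_mu_s <- (log(out$beta_vmc) + log(out$beta_death)) / 2
  out$R_f <- out$beta_death / out$beta_vmc
  rownames(out) <- NULL
  if (!is.null(breakpoints)) {
    seg <- findInterval(out$dose, sort(breakpoints))
    regimes <- lapply(sort(unique(seg)), function(s) {
      sub <- out[seg == s, ]
      if (nrow(sub) < 3) {
        return(data.frame(regime = s, n = nrow(sub), rf_slope = NA,
                          rf_p = NA, dmu_p = NA, shared_upstream = NA))
      }
      # an exactly constant series is flat by construction (p = 1); fitting
      # it would only produce a perfect-fit warning
      slope_test <- function(yv) {
        if (stats::var(yv) < 1e-24) return(c(slope = 0, p = 1))
        # noiseless series fit exactly; the perfect-fit note is expected
        cf <- suppressWarnings(
          summary(stats::lm(yv ~ sub$dose)))$coefficients
        c(slope = cf[2, "Estimate"], p = cf[2, "Pr(>|t|)"])
      }
      frf <- slope_test(log(sub$R_f))
      fdm <- slope_test(sub$delta_mu_s)
      data.frame(regime = s, n = nrow(sub),
                 rf_slope = frf["slope"], rf_p = frf["p"], dmu_p = fdm["p"],
                 shared_upstream = frf["p"] > alpha & fdm["p"] <= alpha)
    })
    attr(out, "regimes") <- do.call(rbind, regimes)
  }
  class(out) <- c("dose_response", "data.frame")
  out
}
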