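#' Configure a Wiener first-passage simulation
#'
#' Parameterizes the stochastic decline models used throughout the package.
#' Each individual is a biased random walk started at displacement
#' `x0 = x0_factor * drift_mean` that drifts toward zero with per-step
#' increments `N(-drift * dt, noise_var * dt)`.  Crossing `threshold1`
#' marks vigorous movement cessation (VMC); crossing `threshold2 <
#' threshold1` marks death.  In the `single_process` architecture one walk
#' crosses both thresholds sequentially; in the `two_process` architecture
#' walk A (crossing `threshold1`) sets the VMC time and an independent walk
#' B (crossing `threshold2`) sets the death time, with the per-step
#' increments of A and B sharing a common noise component whose weight is
#' `coupling_w`.
#'
#' Inter-individual heterogeneity ("frailty") multiplies each individual's
#' drift by a unit-mean gamma variate with shape `frailty_shape` (variance
#' `1/frailty_shape`), so the population mean drift stays `drift_mean`.
#' With `flip_frailty` the relative aging rate of individuals is inverted at
#' the moment of VMC: the post-VMC drift becomes
#' `drift_mean^2 / pre-VMC drift`, so previously slow decliners become
#' fast decliners and vice versa.  With `shared_frailty` both walks of the
#' two-process architecture are scaled by the same frailty draw, which is
#' the hierarchical ("shared upstream factor") model.
#'
#' @param n_individuals Number of walkers.
#' @param dt Time step (arbitrary units).
#' @param drift_mean Population-average decline rate, `mu > 0`.
#' @param noise_var Per-unit-time increment variance `sigma^2 >= 0`.
#' @param x0_factor Initial displacement as a multiple of `drift_mean`.
#' @param threshold1 Position whose first crossing defines VMC.
#' @param threshold2 Position (`< threshold1`) whose first crossing defines
#'   death.
#' @param frailty_shape `NULL` for no frailty, else the gamma shape `k > 0`
#'   of the unit-mean frailty distribution (coefficient of variation
#'   `1/sqrt(k)`).
#' @param flip_frailty Invert relative aging rates at VMC
#'   (single-process only).
#' @param architecture `"single_process"` or `"two_process"`.
#' @param coupling_w Shared-noise weight `w` in `[0, 1]` (two-process only):
#'   increments of walks A and B have correlation exactly `w` while their
#'   means and total variances do not depend on `w`.
#' @param shared_frailty Apply one frailty draw to both walks (two-process).
#' @param drift_mean_b Mean drift of walk B (two-process); defaults to
#'   `drift_mean`.
#' @param max_steps Step budget per walker; walkers that have not crossed
#'   by then are right-censored.  Default: 20x the deterministic crossing
#'   time of `threshold2`.
#' @param literal_coupling Use the prefixed increment form
#'   `(1-w) N(mu dt, (1-w) s2 dt) + w N(0, w s2 dt)`, whose mean and
#'   variance do depend on `w`, instead of the variance-preserving form.
#' @param drop_reversed Drop (rather than flag) two-process walkers whose
#'   death walk crosses before their VMC walk.
#' @param seed Integer seed; identical configuration and seed give a
#'   bit-identical event table.
#' @return An object of class `wiener_config`.
#' @seealso [simulate_aging()], [aging_model()], [sweep_coupling()]
#' @export
wiener_config <- function(n_individuals = 1000,
                          dt = 100,
                          drift_mean = 1,
                          noise_var = 4000,
                          x0_factor = 4e5,
                          threshold1 = 2e5,
                          threshold2 = 0,
                          frailty_shape = NULL,
                          flip_frailty = FALSE,
                          architecture = c("single_process", "two_process"),
                          coupling_w = 0,
                          shared_frailty = FALSE,
                          drift_mean_b = drift_mean,
                          max_steps = NULL,
                          literal_coupling = FALSE,
                          drop_reversed = FALSE,
                          seed = 1L) {
  architecture <- match.arg(architecture)
  if (dt <= 0) stop("dt must be > 0")
  if (noise_var < 0) stop("noise_var must be >= 0")
  if (drift_mean <= 0) stop("drift_mean must be > 0")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  x0 <- x0_factor * drift_mean
  if (!(threshold2 < threshold1 && threshold1 < x0)) {
    stop("thresholds must satisfy threshold2 < threshold1 < x0 = ",
         "x0_factor * drift_mean")
  }
  if (coupling_w < 0 || coupling_w > 1) stop("coupling_w must lie in [0, 1]")
  if (!is.null(frailty_shape) && frailty_shape <= 0) {
    stop("frailty_shape must be > 0")
  }
  if (is.null(max_steps)) {
    max_steps <- ceiling(20 * (x0 - threshold2) / (drift_mean * dt))
  }
  cfg <- list(n_individuals = as.integer(n_individuals), dt = dt,
              drift_mean = drift_mean, noise_var = noise_var,
              x0_factor = x0_factor, x0 = x0,
              threshold1 = threshold1, threshold2 = threshold2,
              frailty_shape = frailty_shape, flip_frailty = flip_frailty,
              architecture = architecture, coupling_w = coupling_w,
              shared_frailty = shared_frailty, drift_mean_b = drift_mean_b,
              max_steps = as.integer(max_steps),
              literal_coupling = literal_coupling,
              drop_reversed = drop_reversed, seed = as.integer(seed))
  class(cfg) <- "wiener_config"
  cfg
}

#' @export
print.wiener_config <- function(x, ...) {
  cat("Wiener first-passage configuration (", x$architecture, ")\n", sep = "")
  cat(sprintf("  n = %d, dt = %g, drift = %g, noise var = %g\n",
              x$n_individuals, x$dt, x$drift_mean, x$noise_var))
  cat(sprintf("  x0 = %g, threshold1 = %g, threshold2 = %g\n",
              x$x0, x$threshold1, x$threshold2))
  if (!is.null(x$frailty_shape)) {
    cat(sprintf("  gamma frailty: shape %g (CV %.2f)%s%s\n", x$frailty_shape,
                1 / sqrt(x$frailty_shape),
                if (x$flip_frailty) ", flipped at VMC" else "",
                if (x$shared_frailty) ", shared across walks" else ""))
  }
  if (x$architecture == "two_process") {
    cat(sprintf("  coupling w = %g\n", x$coupling_w))
  }
  cat(sprintf("  max_steps = %d, seed = %d\n", x$max_steps, x$seed))
  invisible(x)
}

#' Named model variants of the decline simulators
#'
#' Convenience presets for the five canonical process architectures plus
#' the tunable-coupling variant:
#' \describe{
#'   \item{`single`}{one Wiener walk crossing two thresholds, no frailty.
#'     Death-on-VMC regression slope is ~1 and remaining-lifespan-on-VMC
#'     slope ~0 (strong Markov property).}
#'   \item{`single_frailty`}{as `single` with gamma-distributed individual
#'     drift rates; slow decliners reach both thresholds late, so
#'     remaining lifespan correlates positively with VMC age.}
#'   \item{`flip`}{as `single_frailty` but each individual's relative rate
#'     of aging is inverted at VMC; remaining lifespan then correlates
#'     negatively with VMC age.}
#'   \item{`two_indep`}{independent walks for VMC and death
#'     (`coupling_w = 0`, no frailty); VMC and death times are
#'     uncorrelated.}
#'   \item{`two_shared`}{independent walks whose drift rates are scaled by
#'     one shared frailty draw: the hierarchical model.  VMC and death
#'     times correlate positively while remaining lifespan still declines
#'     with VMC age, the joint signature seen in worm cohorts.}
#'   \item{`coupled`}{two walks with shared per-step noise of weight `w`
#'     and no frailty, used by [sweep_coupling()].}
#' }
#'
#' @param model Variant name (see Details).
#' @param n Number of walkers.
#' @param seed Integer seed.
#' @param w Coupling weight for the `coupled` variant.
#' @param frailty_shape Gamma shape for the frailty variants; defaults to
#'   `1/0.3^2` (CV 0.3) for the single-process variants and 4 for
#'   `two_shared`.
#' @param ... Further arguments passed to [wiener_config()].
#' @return A `wiener_config`.
#' @examples
#' tab <- simulate_aging(aging_model("single", n = 200, seed = 1))
#' head(tab)
#' @export
aging_model <- function(model = c("single", "single_frailty", "flip",
                                  "two_indep", "two_shared", "coupled"),
                        n = 1000, seed = 1L, w = 0.8,
                        frailty_shape = NULL, ...) {
  model <- match.arg(model)
  cfg <- switch(model,
    single = wiener_config(n_individuals = n, seed = seed, ...),
    single_frailty = wiener_config(
      n_individuals = n, seed = seed,
      frailty_shape = if (is.null(frailty_shape)) 1 / 0.3^2 else frailty_shape,
      ...),
    flip = wiener_config(
      n_individuals = n, seed = seed,
      frailty_shape = if (is.null(frailty_shape)) 1 / 0.3^2 else frailty_shape,
      flip_frailty = TRUE, ...),
    two_indep = wiener_config(
      n_individuals = n, seed = seed, architecture = "two_process",
      coupling_w = 0, noise_var = 2.5e5, threshold1 = 1.44e5, ...),
    two_shared = wiener_config(
      n_individuals = n, seed = seed, architecture = "two_process",
      coupling_w = 0, noise_var = 2.5e5, threshold1 = 1.44e5,
      frailty_shape = if (is.null(frailty_shape)) 4 else frailty_shape,
      shared_frailty = TRUE, ...),
    coupled = wiener_config(
      n_individuals = n, seed = seed, architecture = "two_process",
      coupling_w = w, noise_var = 2.5e5, threshold1 = 1.44e5, ...))
  cfg$model <- model
  cfg
}

#' Sample per-individual drift rates under gamma frailty
#'
#' Frailty is parameterized as `drift_mean * Z` with `Z` a unit-mean gamma
#' variate of shape `k` (scale `1/k`), so rates are centered on the
#' population average and their coefficient of variation is `1/sqrt(k)`.
#' Draws come from the current RNG stream.
#'
#' @param n Number of rates.
#' @param shape Gamma shape `k > 0`.
#' @param drift_mean Population mean rate.
#' @return Numeric vector of `n` positive rates.
#' @examples
#' set.seed(1)
#' rates <- sample_frailty(1e4, shape = 4)
#' mean(rates)   # ~1
#' sd(rates)     # ~1/sqrt(4)
#' @export
sample_frailty <- function(n, shape, drift_mean = 1) {
  if (is.null(shape) || !is.finite(shape) || shape <= 0) {
    stop("frailty shape must be a positive number")
  }
  drift_mean * stats::rgamma(n, shape = shape, rate = shape)
}

#' Simulate an event table from a decline model
#'
#' Runs the discrete-time Wiener first-passage simulation described in
#' [wiener_config()] and returns the crossing times as an [event_table()].
#' Walkers that have not crossed a threshold within `max_steps` steps are
#' right-censored at `max_steps * dt`.  Times are the first step at which
#' the walk position falls below the threshold, in the same units as `dt`.
#'
#' For the two-process architecture the table carries an extra logical
#' column `order_reversed` flagging walkers whose death walk crossed before
#' their VMC walk (the two walks are distinct processes, so this can
#' happen); set `drop_reversed = TRUE` in the configuration to discard them
#' instead.
#'
#' @param config A [wiener_config()].
#' @return An [event_table()] with the configuration stored in
#'   `attr(, "config")`.
#' @examples
#' tab <- simulate_aging(aging_model("single", n = 200, seed = 42))
#' with(tab, coef(lm(death_time ~ vmc_time)))  # slope ~ 1
#' @export
simulate_aging <- function(config) {
  stopifnot(inherits(config, "wiener_config"))
  if (config$noise_var == 0 && config$drift_mean <= 0) {
    stop("non-positive drift with zero noise: walkers can never cross")
  }
  set.seed(config$seed)
  n <- config$n_individuals
  frail <- if (is.null(config$frailty_shape)) rep(1, n) else
    stats::rgamma(n, shape = config$frailty_shape, rate = config$frailty_shape)
  res <- if (config$architecture == "single_process") {
    sim_single_walk(config, frail)
  } else {
    sim_two_walks(config, frail)
  }
  cap <- config$max_steps * config$dt
  vmc_cens <- is.na(res$t1)
  death_cens <- is.na(res$t2)
  if (mean(death_cens) > 0.5) {
    warning("max_steps exhausted for more than half of the walkers; ",
            "increase max_steps or adjust drift/noise")
  }
  tab <- data.frame(
    individual_id = sprintf("sim%05d", seq_len(n)),
    group = "sim", batch = "sim",
    vmc_time = ifelse(vmc_cens, cap, res$t1), vmc_censored = vmc_cens,
    wmc_time = NA_real_, wmc_censored = NA,
    death_time = ifelse(death_cens, cap, res$t2), death_censored = death_cens,
    stringsAsFactors = FALSE)
  if (config$architecture == "two_process") {
    reversed <- !vmc_cens & !death_cens & res$t2 < res$t1
    if (config$drop_reversed) {
      tab <- tab[!reversed, , drop = FALSE]
    } else {
      tab$order_reversed <- reversed
    }
  }
  tab <- event_table(tab, check_order = FALSE)
  cfg <- unclass(config)
  cfg$frailty_shape <- if (is.null(cfg$frailty_shape)) NA else cfg$frailty_shape
  attr(tab, "config") <- cfg
  tab
}

# single walk crossing threshold1 then threshold2; optional drift flip at VMC
sim_single_walk <- function(cfg, frail) {
  n <- cfg$n_individuals
  drift <- cfg$drift_mean * frail
  x <- rep(cfg$x0, n)
  t1 <- rep(NA_real_, n); t2 <- rep(NA_real_, n)
  active <- seq_len(n)
  sd_step <- sqrt(cfg$noise_var * cfg$dt)
  th1 <- cfg$threshold1; th2 <- cfg$threshold2; dt <- cfg$dt
  for (k in seq_len(cfg$max_steps)) {
    na <- length(active)
    inc <- if (sd_step > 0) stats::rnorm(na, -drift[active] * dt, sd_step) else
      -drift[active] * dt
    xa <- x[active] + inc
    x[active] <- xa
    hit1 <- is.na(t1[active]) & xa < th1
    if (any(hit1)) {
      ids <- active[hit1]
      t1[ids] <- k * dt
      if (cfg$flip_frailty) drift[ids] <- cfg$drift_mean^2 / drift[ids]
    }
    done <- xa < th2
    if (any(done)) {
      t2[active[done]] <- k * dt
      active <- active[!done]
      if (!length(active)) break
    }
  }
  list(t1 = t1, t2 = t2)
}

# two walks; increments share a noise component of weight w
sim_two_walks <- function(cfg, frail) {
  n <- cfg$n_individuals
  driftA <- cfg$drift_mean * (if (cfg$shared_frailty) frail else rep(1, n))
  driftB <- cfg$drift_mean_b * (if (cfg$shared_frailty) frail else rep(1, n))
  xA <- rep(cfg$x0, n); xB <- rep(cfg$x0, n)
  t1 <- rep(NA_real_, n); t2 <- rep(NA_real_, n)
  active <- seq_len(n)
  w <- cfg$coupling_w; dt <- cfg$dt; s2 <- cfg$noise_var
  th1 <- cfg$threshold1; th2 <- cfg$threshold2
  if (cfg$literal_coupling) {
    # printed prefixed form: (1-w) N(mu dt, (1-w) s2 dt) + w N(0, w s2 dt)
    sd_own <- sqrt((1 - w)^3 * s2 * dt)
    sd_shared <- sqrt(w^3 * s2 * dt)
    drift_scale <- 1 - w
  } else {
    # variance-preserving form: N(mu dt, (1-w) s2 dt) + N(0, w s2 dt)
    sd_own <- sqrt((1 - w) * s2 * dt)
    sd_shared <- sqrt(w * s2 * dt)
    drift_scale <- 1
  }
  for (k in seq_len(cfg$max_steps)) {
    na <- length(active)
    shared <- if (sd_shared > 0) stats::rnorm(na, 0, sd_shared) else 0
    muA <- drift_scale * driftA[active] * dt
    muB <- drift_scale * driftB[active] * dt
    incA <- (if (sd_own > 0) stats::rnorm(na, -muA, sd_own) else -muA) + shared
    incB <- (if (sd_own > 0) stats::rnorm(na, -muB, sd_own) else -muB) + shared
    xa <- xA[active] + incA; xA[active] <- xa
    xb <- xB[active] + incB; xB[active] <- xb
    hit1 <- is.na(t1[active]) & xa < th1
    if (any(hit1)) t1[active[hit1]] <- k * dt
    hit2 <- is.na(t2[active]) & xb < th2
    if (any(hit2)) t2[active[hit2]] <- k * dt
    done <- !is.na(t1[active]) & !is.na(t2[active])
    if (any(done)) {
      active <- active[!done]
      if (!length(active)) break
    }
  }
  list(t1 = t1, t2 = t2)
}

#' Sweep the inter-process coupling weight
#'
#' Re-runs the two-process simulation across a grid of coupling weights
#' `w`, recording for each the ordinary-least-squares slope of death time on
#' VMC time, the slope of remaining lifespan (death - VMC) on VMC time and
#' the Pearson correlation of the two event times.  Each run uses seed
#' `config$seed + index - 1` so the sweep is reproducible and the runs are
#' independent.  By default the sweep runs without frailty, so the `w = 0`
#' column reduces to the fully independent two-process model.
#'
#' @param config A two-process [wiener_config()] (the template; its
#'   `coupling_w` is overridden).
#' @param w_list Increasing vector of coupling weights in `[0, 1]`.
#' @return A data frame of class `coupling_sweep` with columns `w`,
#'   `slope_death_on_vmc`, `slope_remaining_on_vmc`, `corr` and `n_used`,
#'   with the per-run seeds in `attr(, "seeds")`.
#' @export
sweep_coupling <- function(config, w_list = seq(0, 1, by = 0.2)) {
  stopifnot(inherits(config, "wiener_config"))
  if (config$architecture != "two_process") {
    stop("sweep_coupling requires a two-process configuration")
  }
  if (length(w_list) == 0) stop("w_list must be non-empty")
  if (any(w_list < 0 | w_list > 1)) stop("w values must lie in [0, 1]")
  w_list <- sort(unique(w_list))
  seeds <- config$seed + seq_along(w_list) - 1L
  rows <- lapply(seq_along(w_list), function(i) {
    cfg <- config
    cfg$coupling_w <- w_list[i]
    cfg$seed <- seeds[i]
    tab <- simulate_aging(cfg)
    ok <- !tab$vmc_censored & !tab$death_censored
    v <- tab$vmc_time[ok]; d <- tab$death_time[ok]
    data.frame(w = w_list[i],
               slope_death_on_vmc = unname(stats::coef(stats::lm(d ~ v))[2]),
               slope_remaining_on_vmc =
                 unname(stats::coef(stats::lm(I(d - v) ~ v))[2]),
               corr = stats::cor(v, d),
               n_used = length(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- seeds
  class(out) <- c("coupling_sweep", "data.frame")
  out
}
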