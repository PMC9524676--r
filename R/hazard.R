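#' Cumulative hazard of right-censored event times
#'
#' Nelson-Aalen estimator: at each distinct event time `t_j` with `d_j`
#' events among `n_j` individuals still at risk, the cumulative hazard
#' increases by `d_j / n_j` (ties aggregated).  `type = "km"` instead
#' returns `-log` of the Kaplan-Meier survival estimate; the two agree
#' asymptotically but the Nelson-Aalen increments differentiate more
#' stably.
#'
#' @param times Positive event or censoring times.
#' @param censored Logical vector; `TRUE` marks right-censored times.
#' @param type `"nelson-aalen"` (default) or `"km"`.
#' @return An object of class `cumhaz`: a data frame with columns `time`,
#'   `n_risk`, `n_event`, `cumhaz` and `se` (one row per distinct event
#'   time), carrying the input times in attributes for downstream
#'   smoothing.
#' @examples
#' ch <- cumulative_hazard(c(1, 2, 3))
#' ch$cumhaz  # 1/3, 1/3 + 1/2, 1/3 + 1/2 + 1
#' @export
cumulative_hazard <- function(times, censored = rep(FALSE, length(times)),
                              type = c("nelson-aalen", "km")) {
  type <- match.arg(type)
  stopifnot(length(times) == length(censored))
  keep <- is.finite(times)
  times <- times[keep]; censored <- as.logical(censored)[keep]
  if (!length(times)) stop("no finite event times")
  if (any(times <= 0)) stop("event times must be positive")
  if (all(censored)) stop("all observations are censored: no events to estimate from")
  tj <- sort(unique(times[!censored]))
  n_risk <- vapply(tj, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(tj, function(t) sum(times == t & !censored), numeric(1))
  inc <- switch(type,
    "nelson-aalen" = n_event / n_risk,
    "km" = -log(1 - n_event / n_risk))
  if (type == "km" && any(!is.finite(inc))) {
    # last event time can exhaust the risk set; fall back to the NA increment
    inc[!is.finite(inc)] <- (n_event / n_risk)[!is.finite(inc)]
  }
  out <- data.frame(time = tj, n_risk = n_risk, n_event = n_event,
                    cumhaz = cumsum(inc),
                    se = sqrt(cumsum(n_event / n_risk^2)))
  attr(out, "times") <- times
  attr(out, "censored") <- censored
  attr(out, "type") <- type
  class(out) <- c("cumhaz", "data.frame")
  out
}

#' Smoothed hazard rate from a cumulative hazard
#'
#' Differentiates a [cumulative_hazard()] step function by Epanechnikov
#' kernel smoothing of its increments:
#' `h(t) = sum_j K((t - t_j)/b) dH_j / b`.  The default grid spans 200
#' evenly spaced points between the 1st and 99th percentiles of the
#' observed event times (the hazard outside the observed range, where too
#' few events occur, is left unestimated), and the default bandwidth is
#' one twentieth of the event-time range.
#'
#' @param ch A `cumhaz` object.
#' @param grid Evaluation times; default as described above.
#' @param bandwidth Kernel half-width, same units as `time`; must exceed
#'   the grid spacing.
#' @return An object of class `hazard_curve`: a data frame with columns
#'   `time`, `cumhaz` (step-interpolated), `hazard`, `n_risk` and `se`
#'   (pointwise standard error of the smoothed hazard).
#' @examples
#' set.seed(1)
#' hz <- hazard_rate(cumulative_hazard(rexp(2000, rate = 0.2)))
#' mean(hz$hazard)  # ~0.2
#' @export
hazard_rate <- function(ch, grid = NULL, bandwidth = NULL) {
  stopifnot(inherits(ch, "cumhaz"))
  ev <- ch$time
  if (is.null(grid)) {
    qs <- stats::quantile(ev, c(0.01, 0.99), names = FALSE, type = 7)
    grid <- seq(qs[1], qs[2], length.out = 200)
  }
  if (min(grid) < min(ev) - 1e-9 || max(grid) > max(ev) + 1e-9) {
    stop("grid must lie within the observed event-time range")
  }
  if (is.null(bandwidth)) bandwidth <- diff(range(ev)) / 20
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  spacing <- if (length(grid) > 1) max(diff(grid)) else 0
  if (bandwidth < spacing) {
    stop("bandwidth (", signif(bandwidth, 4),
         ") is smaller than the grid spacing (", signif(spacing, 4), ")")
  }
  dH <- diff(c(0, ch$cumhaz))
  dV <- diff(c(0, ch$se^2))
  h <- numeric(length(grid)); v <- numeric(length(grid))
  for (i in seq_along(grid)) {
    u <- (grid[i] - ev) / bandwidth
    k <- ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0) / bandwidth
    h[i] <- sum(k * dH)
    v[i] <- sum(k^2 * dV)
  }
  h <- pmax(h, 0)
  Hgrid <- stats::approx(c(0, ev), c(0, ch$cumhaz), xout = grid,
                         method = "constant", rule = 2)$y
  ngrid <- stats::approx(ev, ch$n_risk, xout = grid,
                         method = "constant", rule = 2)$y
  out <- data.frame(time = grid, cumhaz = Hgrid, hazard = h,
                    n_risk = ngrid, se = sqrt(v))
  attr(out, "bandwidth") <- bandwidth
  attr(out, "type") <- attr(ch, "type")
  class(out) <- c("hazard_curve", "data.frame")
  out
}

#' One-call hazard estimation
#'
#' Convenience wrapper chaining [cumulative_hazard()] and [hazard_rate()].
#'
#' @inheritParams cumulative_hazard
#' @inheritParams hazard_rate
#' @return A `hazard_curve`.
#' @export
hazard_estimate <- function(times, censored = rep(FALSE, length(times)),
                            grid = NULL, bandwidth = NULL,
                            type = c("nelson-aalen", "km")) {
  hazard_rate(cumulative_hazard(times, censored, type = match.arg(type)),
              grid = grid, bandwidth = bandwidth)
}

#' Clock-reset hazard of death
#'
#' Estimates the hazard of death as a function of the time elapsed since a
#' per-individual milestone (VMC or WMC) rather than chronological age:
#' milestone times are subtracted from death times and the resulting
#' durations are treated as (possibly right-censored) event times.
#' Individuals whose milestone itself is censored or unobserved cannot
#' contribute a duration and are dropped with a warning.
#'
#' @param table An [event_table()].
#' @param origin `"vmc"` or `"wmc"`: the milestone that restarts the clock.
#' @inheritParams hazard_rate
#' @return A `hazard_curve` over durations.
#' @export
clock_reset_hazard <- function(table, origin = c("vmc", "wmc"),
                               grid = NULL, bandwidth = NULL) {
  origin <- match.arg(origin)
  stopifnot(inherits(table, "event_table"))
  o_time <- table[[paste0(origin, "_time")]]
  o_cens <- table[[paste0(origin, "_censored")]]
  usable <- !is.na(o_time) & !is.na(o_cens) & !o_cens & !is.na(table$death_time)
  if (sum(!usable)) {
    warning(sum(!usable), " individuals without an observed ", origin,
            " time were dropped")
  }
  dur <- table$death_time[usable] - o_time[usable]
  cens <- table$death_censored[usable]
  neg <- which(!cens & dur < 0)
  if (length(neg)) {
    stop("negative ", origin, "-to-death durations for individuals: ",
         paste(utils::head(table$individual_id[usable][neg], 10),
               collapse = ", "))
  }
  hazard_estimate(dur[dur > 0 | cens], cens[dur > 0 | cens],
                  grid = grid, bandwidth = bandwidth)
}

#' Fold change of a hazard curve between two ages
#'
#' @param curve A `hazard_curve`.
#' @param t_start,t_end Times within the curve's grid.
#' @return `h(t_end) / h(t_start)`.
#' @export
hazard_fold_change <- function(curve, t_start, t_end) {
  stopifnot(inherits(curve, "hazard_curve"))
  rng <- range(curve$time)
  if (t_start < rng[1] || t_end > rng[2]) {
    stop("t_start and t_end must lie within the estimated grid [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  h <- stats::approx(curve$time, curve$hazard, xout = c(t_start, t_end))$y
  if (h[1] <= 0) stop("hazard is zero at t_start; fold change undefined")
  h[2] / h[1]
}

#' State-occupancy fractions of lifespan
#'
#' For fully observed individuals, the fractions of life spent moving
#' vigorously (`[0, vmc)`), moving weakly (`[vmc, wmc)`) and alive but
#' non-moving (`[wmc, death)`).  When WMC was not scored the last two
#' states are merged into a single post-vigorous fraction.
#'
#' @param table An [event_table()].
#' @return A list of class `span_summary` with elements `per_individual`
#'   (data frame of fractions, summing to 1 per row) and `mean` (named
#'   population means).
#' @examples
#' tab <- event_table(data.frame(
#'   individual_id = "a", group = "g", batch = "b",
#'   vmc_time = 6, vmc_censored = FALSE, wmc_time = 9, wmc_censored = FALSE,
#'   death_time = 10, death_censored = FALSE))
#' summarize_spans(tab)$per_individual  # 0.6, 0.3, 0.1
#' @export
summarize_spans <- function(table) {
  stopifnot(inherits(table, "event_table"))
  full <- observed_pairs(table)
  if (nrow(full) < nrow(table)) {
    warning(nrow(table) - nrow(full),
            " individuals with censored or missing times were dropped")
  }
  if (!nrow(full)) stop("no fully observed individuals")
  has_wmc <- !is.na(full$wmc_time) & !is.na(full$wmc_censored) &
    !full$wmc_censored
  if (all(has_wmc)) {
    per <- data.frame(
      individual_id = full$individual_id,
      frac_vigorous = full$vmc_time / full$death_time,
      frac_weak = (full$wmc_time - full$vmc_time) / full$death_time,
      frac_nonmoving = (full$death_time - full$wmc_time) / full$death_time)
    means <- colMeans(per[, -1])
  } else {
    per <- data.frame(
      individual_id = full$individual_id,
      frac_vigorous = full$vmc_time / full$death_time,
      frac_postvigorous = 1 - full$vmc_time / full$death_time)
    means <- colMeans(per[, -1])
  }
  out <- list(per_individual = per, mean = means)
  class(out) <- "span_summary"
  out
}

#' @export
print.span_summary <- function(x, ...) {
  cat("State occupancy (fractions of lifespan), population means:\n")
  print(round(x$mean, 3))
  invisible(x)
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat("Hazard curve on", nrow(x), "grid points,",
      "bandwidth", signif(attr(x, "bandwidth"), 4),
      paste0("(", attr(x, "type"), ")"), "\n")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.hazard_curve <- function(x, log = "", xlab = "time",
                              ylab = "hazard rate", type = "l", ...) {
  graphics::plot(x$time, x$hazard, type = type, log = log,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
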