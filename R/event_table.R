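#' Event tables of behavioral aging milestones
#'
#' An `event_table` is a data frame holding one row per individual with the
#' observed (or right-censored) ages at vigorous movement cessation (VMC),
#' weak movement cessation (WMC) and death, together with group (genotype /
#' intervention) and batch (device / replicate) labels.  All times share one
#' unit (hours for empirical-style cohorts, arbitrary units for simulator
#' output) and are counted from the start of adulthood.
#'
#' Required columns: `individual_id`, `group`, `batch`, `vmc_time`,
#' `vmc_censored`, `wmc_time`, `wmc_censored`, `death_time`,
#' `death_censored`.  `wmc_time` may be `NA` when the weak-movement
#' transition was not scored.  Extra columns (for example the
#' `order_reversed` flag added by the two-process simulator) are preserved.
#'
#' @param x A data frame with the required columns.
#' @param check_order Validate `vmc_time <= wmc_time <= death_time` on rows
#'   where the relevant times are observed and uncensored.
#' @return An object of class `event_table` (a data frame).
#' @examples
#' tab <- event_table(data.frame(
#'   individual_id = c("w1", "w2"), group = "wt", batch = "b1",
#'   vmc_time = c(200, 240), vmc_censored = FALSE,
#'   wmc_time = c(280, 300), wmc_censored = FALSE,
#'   death_time = c(310, 330), death_censored = FALSE))
#' summary(tab)
#' @export
event_table <- function(x, check_order = TRUE) {
  if (!is.data.frame(x)) stop("`x` must be a data frame")
  req <- c("individual_id", "group", "batch",
           "vmc_time", "vmc_censored", "wmc_time", "wmc_censored",
           "death_time", "death_censored")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("vmc_time", "wmc_time", "death_time")) {
    if (!is.numeric(x[[col]])) {
      xn <- suppressWarnings(as.numeric(x[[col]]))
      if (any(is.na(xn) & !is.na(x[[col]]))) {
        stop("non-numeric values in column ", col)
      }
      x[[col]] <- xn
    }
  }
  for (col in c("vmc_censored", "wmc_censored", "death_censored")) {
    x[[col]] <- as.logical(x[[col]])
  }
  bad <- which(!is.na(x$death_time) & x$death_time <= 0)
  if (length(bad)) stop("non-positive death_time on rows: ",
                        paste(utils::head(bad, 10), collapse = ", "))
  if (check_order) {
    viol <- order_violations(x)
    if (length(viol)) {
      stop("event-time ordering violated (vmc <= wmc <= death) on rows: ",
           paste(utils::head(viol, 20), collapse = ", "))
    }
  }
  class(x) <- c("event_table", "data.frame")
  x
}

# rows with observed, uncensored times out of order
order_violations <- function(x) {
  v <- x$vmc_time; w <- x$wmc_time; d <- x$death_time
  ok_vd <- !is.na(v) & !is.na(d) & !x$vmc_censored & !x$death_censored
  ok_vw <- !is.na(v) & !is.na(w) & !x$vmc_censored & !x$wmc_censored
  ok_wd <- !is.na(w) & !is.na(d) & !x$wmc_censored & !x$death_censored
  bad <- (ok_vd & d < v) | (ok_vw & w < v) | (ok_wd & d < w)
  which(bad)
}

#' @export
print.event_table <- function(x, ...) {
  cat("Event table:", nrow(x), "individuals,",
      nlevels(factor(x$group)), "group(s),",
      nlevels(factor(x$batch)), "batch(es)\n")
  cfg <- attr(x, "config")
  if (!is.null(cfg$model)) cat("Simulated from model:", cfg$model, "\n")
  NextMethod()
  invisible(x)
}

#' @export
summary.event_table <- function(object, ...) {
  obs <- function(t, c) t[!is.na(t) & !c]
  out <- list(
    n = nrow(object),
    groups = table(object$group),
    batches = table(object$batch),
    vmc = summary(obs(object$vmc_time, object$vmc_censored)),
    death = summary(obs(object$death_time, object$death_censored)),
    n_censored_death = sum(object$death_censored, na.rm = TRUE)
  )
  class(out) <- "summary.event_table"
  out
}

#' @export
print.summary.event_table <- function(x, ...) {
  cat("Event table with", x$n, "individuals;",
      x$n_censored_death, "death time(s) right-censored\n")
  cat("VMC times (observed):\n"); print(x$vmc)
  cat("Death times (observed):\n"); print(x$death)
  invisible(x)
}

#' Read an event table from delimited text
#'
#' Reads a comma-separated event table with the schema described in
#' [event_table()] and validates it.  Ordering violations are reported with
#' the offending row numbers.
#'
#' @param path Path to a CSV file.
#' @param check_order Validate event-time ordering (default `TRUE`).
#' @return An [event_table()].
#' @export
read_event_table <- function(path, check_order = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(x) == 0) stop("input file has a header but no rows: ", path)
  sidecar <- paste0(path, ".json")
  tab <- event_table(x, check_order = check_order)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(tab, "config") <- meta$config
    attr(tab, "truth") <- meta$truth
  }
  tab
}

#' Write an event table to delimited text
#'
#' Writes the table as CSV.  Unless `sidecar = FALSE`, a JSON sidecar
#' (`<path>.json`) records the generating configuration and any simulation
#' ground truth so that a round trip through disk is lossless.
#'
#' @param x An [event_table()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "event_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  if (sidecar) {
    meta <- list(config = attr(x, "config"), truth = attr(x, "truth"))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

# internal: extract fully observed (uncensored) vmc/death pairs
observed_pairs <- function(table, require_wmc = FALSE) {
  keep <- !is.na(table$vmc_time) & !is.na(table$death_time) &
    !table$vmc_censored & !table$death_censored
  if (require_wmc) keep <- keep & !is.na(table$wmc_time) & !table$wmc_censored
  table[keep, , drop = FALSE]
}
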