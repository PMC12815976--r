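#' Geometric mean
#'
#' `exp(mean(log(x)))`. Nonpositive values are an error, never silently
#' dropped.
#'
#' @param x positive numeric vector.
#' @return the geometric mean.
#' @export
#' @examples
#' geometric_mean(c(1, 100))  # 10
geometric_mean <- function(x) {
  if (!length(x)) stop("empty input", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive finite values", call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Percentiles by linear interpolation
#'
#' Quantiles interpolate linearly between order statistics
#' (`stats::quantile` type 7, the R default), fixed here so prediction-interval
#' bands are bit-reproducible; the 50th percentile equals the median.
#'
#' @param x non-empty numeric vector.
#' @param probs probabilities (default the 5th, 50th and 95th).
#' @return named numeric vector of quantiles.
#' @export
percentiles <- function(x, probs = c(0.05, 0.50, 0.95)) {
  if (!length(x)) stop("empty input", call. = FALSE)
  stats::quantile(x, probs = probs, type = 7, names = TRUE)
}

#' Per-cycle exposure metrics of one profile
#'
#' Within a cycle window: `cmax` is the maximum concentration, `cmin` the
#' trough at the window end (immediately before the next dose), and
#' `weekly_auc` the trapezoidal AUC over the window normalized to a 7-day
#' week (`AUC * 7 / window length`) — the only AUC scale comparable across
#' regimens whose intervals differ.
#'
#' @param profile tibble with `time`, `conc` (one subject), and a `cycle`
#'   column if windows carry cycle labels.
#' @param window one row of the `windows` table from [expand_regimen()]
#'   (fields `cycle`, `start`, `end`).
#' @return a one-row tibble `cycle`, `cmax`, `cmin`, `weekly_auc`.
#' @export
cycle_metrics <- function(profile, window) {
  sel <- profile$time >= window$start & profile$time <= window$end
  if ("cycle" %in% names(profile)) sel <- sel & profile$cycle == window$cycle
  t <- profile$time[sel]
  c <- profile$conc[sel]
  if (!length(t) || min(t) > window$start || max(t) < window$end) {
    stop(sprintf("profile grid does not cover cycle %d [%g, %g]",
                 window$cycle, window$start, window$end), call. = FALSE)
  }
  o <- order(t)
  t <- t[o]; c <- c[o]
  tibble::tibble(
    cycle = window$cycle,
    cmax = max(c),
    cmin = c[length(c)],
    weekly_auc = trapz(t, c) * 7 / (window$end - window$start)
  )
}

#' Exposure metrics for every subject and cycle of a simulation
#'
#' @param sim a `popsim` from [simulate_population()].
#' @return tibble `subject_id`, `regimen`, `cycle`, `cmax`, `cmin`,
#'   `weekly_auc`.
#' @export
exposure_metrics <- function(sim) {
  stopifnot(inherits(sim, "popsim"))
  w <- sim$windows
  len <- stats::setNames(w$end - w$start, w$cycle)
  pr <- sim$profiles
  out <- dplyr::summarise(
    dplyr::group_by(pr, .data$subject_id, .data$cycle),
    cmax = max(.data$conc),
    cmin = .data$conc[which.max(.data$time)],
    auc = trapz(.data$time, .data$conc),
    .groups = "drop"
  )
  out$weekly_auc <- out$auc * 7 / len[as.character(out$cycle)]
  out$auc <- NULL
  out$regimen <- sim$regimen
  out[c("subject_id", "regimen", "cycle", "cmax", "cmin", "weekly_auc")]
}

#' Population summary of exposure metrics
#'
#' One row per regimen x cycle x metric with the geometric mean, the 5th,
#' 50th and 95th percentiles (the 90% prediction interval is `[p5, p95]`),
#' and the arithmetic mean and SD.
#'
#' @param metrics tibble from [exposure_metrics()] (possibly several regimens
#'   bound together).
#' @param cycles cycles to keep (default the first and the steady-state
#'   seventh).
#' @return tibble `regimen`, `cycle`, `metric`, `geo_mean`, `p5`, `p50`,
#'   `p95`, `mean`, `sd`.
#' @export
summarize_exposure <- function(metrics, cycles = c(1L, 7L)) {
  m <- metrics[metrics$cycle %in% cycles, ]
  if (!nrow(m)) stop("no metrics in the requested cycles", call. = FALSE)
  long <- tidyr_pivot(m)
  dplyr::summarise(
    dplyr::group_by(long, .data$regimen, .data$cycle, .data$metric),
    geo_mean = geometric_mean(.data$value),
    p5 = unname(percentiles(.data$value, 0.05)),
    p50 = unname(percentiles(.data$value, 0.50)),
    p95 = unname(percentiles(.data$value, 0.95)),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    .groups = "drop"
  )
}

## minimal long-format reshape (metric columns -> rows), keeps dplyr-only deps
tidyr_pivot <- function(m) {
  mets <- c("cmax", "cmin", "weekly_auc")
  dplyr::bind_rows(lapply(mets, function(nm) {
    tibble::tibble(regimen = m$regimen, cycle = m$cycle,
                   metric = nm, value = m[[nm]])
  }))
}

#' Write an exposure summary table
#'
#' Comma-delimited text mirroring the per-cycle exposure layout (regimen,
#' cycle, metric, geometric mean, 90% PI bounds, mean, median, SD).
#'
#' @param summary tibble from [summarize_exposure()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_exposure_summary <- function(summary, path) {
  out <- summary
  num <- vapply(out, is.numeric, TRUE) & names(out) != "cycle"
  out[num] <- lapply(out[num], function(x) signif(x, 8))  # stable bytes
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
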