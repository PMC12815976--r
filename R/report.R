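#' Median / 90% PI ribbon figure for one cycle
#'
#' Plots, for a single cycle, the population median concentration (solid
#' line) with the 5th-95th percentile band (shaded) against time after that
#' cycle's dose, plus a horizontal reference line at the minimum effective
#' concentration.
#'
#' @param sim a `popsim` from [simulate_population()].
#' @param cycle cycle index to plot.
#' @param mec minimum effective concentration (ug/mL, default 6).
#' @return a ggplot object.
#' @export
plot_cycle_ribbon <- function(sim, cycle, mec = 6) {
  stopifnot(inherits(sim, "popsim"))
  w <- sim$windows[sim$windows$cycle == cycle, ]
  if (!nrow(w)) stop(sprintf("no cycle %s in this simulation", cycle), call. = FALSE)
  pr <- sim$profiles[sim$profiles$cycle == cycle, ]
  if (!nrow(pr)) stop("empty profile set", call. = FALSE)
  band <- dplyr::summarise(
    dplyr::group_by(pr, .data$time),
    p5 = unname(percentiles(.data$conc, 0.05)),
    p50 = unname(percentiles(.data$conc, 0.50)),
    p95 = unname(percentiles(.data$conc, 0.95)),
    .groups = "drop"
  )
  band$t_after <- band$time - w$start
  ggplot2::ggplot(band, ggplot2::aes(x = .data$t_after)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = mec, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Time after dose (days)",
      y = expression(paste("Concentration (", mu, "g/mL)")),
      title = sprintf("%s - cycle %d", sim$regimen, cycle),
      subtitle = sprintf("Median and 90%% prediction interval; dashed line: MEC %g ug/mL", mec)
    ) +
    ggplot2::theme_minimal()
}

#' Export a NONMEM-style simulation dataset
#'
#' Rectangular event/observation dataset: dose rows (`EVID = 1`,
#' `RATE = AMT/duration`, `CMT = 1`) and observation rows (`EVID = 0`,
#' `DV = "."`), with covariate columns `WT`, `ALB`, `TUM`, `ADA`, `SEX`
#' (1 = male, 0 = female), sorted by `ID` then `TIME` with dose rows
#' preceding same-time observations. `TIME` is in days.
#'
#' @param population tibble from [generate_population()].
#' @param reg a [regimen()].
#' @param resolution observation-grid spacing, days.
#' @param infusion_duration infusion length, days.
#' @param path optional file; when given, written as comma-delimited text
#'   with `"."` for missing `DV`.
#' @return the dataset as a data frame (invisibly if `path` is given).
#' @export
export_nonmem_dataset <- function(population, reg, resolution = 0.1,
                                  infusion_duration = 1 / 24, path = NULL) {
  ev <- expand_regimen(reg, infusion_duration)
  grid <- time_grid(ev$windows, ev$doses, resolution)
  obs_times <- unique(grid$time)
  one <- function(i) {
    p <- population[i, ]
    cov <- data.frame(WT = p$weight, ALB = p$albumin, TUM = p$tumor_size,
                      ADA = as.integer(p$ada), SEX = as.integer(p$sex == "male"))
    dose <- data.frame(ID = p$subject_id, TIME = ev$doses$time,
                       AMT = ev$doses$amount,
                       RATE = ifelse(ev$doses$duration > 0,
                                     ev$doses$amount / ev$doses$duration, 0),
                       EVID = 1L, CMT = 1L, DV = NA_real_, cov,
                       PRIO = 0L)
    obs <- data.frame(ID = p$subject_id, TIME = obs_times, AMT = 0, RATE = 0,
                      EVID = 0L, CMT = 1L, DV = NA_real_, cov, PRIO = 1L)
    all <- rbind(dose, obs)
    all <- all[order(all$TIME, all$PRIO), ]  # dose rows first at equal TIME
    all$PRIO <- NULL
    all
  }
  out <- do.call(rbind, lapply(seq_len(nrow(population)), one))
  rownames(out) <- NULL
  if (!is.null(path)) {
    txt <- out
    txt$DV <- ifelse(is.na(txt$DV), ".", as.character(txt$DV))
    utils::write.csv(txt, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Recover dose events from a NONMEM-style dataset
#'
#' Inverse of the event part of [export_nonmem_dataset()] for one subject:
#' `EVID = 1` rows become dose events (`duration = AMT/RATE`; bolus when
#' `RATE = 0`), enabling re-simulation directly from the exported rows.
#'
#' @param dataset data frame from [export_nonmem_dataset()].
#' @param id subject `ID` to extract.
#' @return tibble `time`, `amount`, `duration`.
#' @export
doses_from_nonmem <- function(dataset, id) {
  d <- dataset[dataset$ID == id & dataset$EVID == 1L, ]
  if (!nrow(d)) stop(sprintf("no dose rows for ID %s", id), call. = FALSE)
  tibble::tibble(time = d$TIME, amount = d$AMT,
                 duration = ifelse(d$RATE > 0, d$AMT / d$RATE, 0))
}

#' Throughput benchmark
#'
#' Runs a simulation closure, counts the observations it produced and
#' reports observations per second of wall time. Hardware-dependent and
#' purely informational — not a correctness metric.
#'
#' @param run a function of no arguments returning either a `popsim`, a
#'   profiles tibble, or a number of observations.
#' @return list `n_observations`, `wall_seconds`, `obs_per_sec`.
#' @export
benchmark_throughput <- function(run) {
  t0 <- proc.time()[["elapsed"]]
  out <- run()
  secs <- proc.time()[["elapsed"]] - t0
  n <- if (inherits(out, "popsim")) nrow(out$profiles)
       else if (is.data.frame(out)) nrow(out)
       else as.numeric(out)
  if (secs <= 0) stop("run completed below timer resolution; enlarge the problem",
                      call. = FALSE)
  list(n_observations = n, wall_seconds = secs, obs_per_sec = n / secs)
}
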