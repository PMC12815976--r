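#' Define a dosing regimen
#'
#' A regimen is an ordered list of blocks, each giving a dose amount (mg), a
#' dosing interval (days) and a number of doses. Dose `k+1` is scheduled one
#' interval *of its own block* after dose `k`, so "two loading doses followed
#' by q6w maintenance" places the first maintenance dose 42 days after the
#' second loading dose.
#'
#' @param name regimen label.
#' @param blocks data frame with columns `amount` (mg), `interval` (days),
#'   `n_doses`.
#' @return an object of class `regimen`.
#' @export
regimen <- function(name, blocks) {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) == 0L) abort_field("blocks", "must contain at least one block")
  need <- c("amount", "interval", "n_doses")
  if (!all(need %in% names(blocks))) {
    abort_field("blocks", paste("must have columns", paste(need, collapse = ", ")))
  }
  if (any(blocks$amount <= 0)) abort_field("amount", "dose amounts must be > 0")
  if (any(blocks$interval <= 0)) abort_field("interval", "intervals must be > 0")
  if (any(blocks$n_doses < 1 | blocks$n_doses %% 1 != 0)) {
    abort_field("n_doses", "must be positive integers")
  }
  structure(list(name = name, blocks = blocks,
                 total_doses = sum(blocks$n_doses)),
            class = "regimen")
}

#' Expand a regimen into dose events and cycle windows
#'
#' @param reg a [regimen()].
#' @param infusion_duration infusion length in days (default 1 hour; 0 =
#'   bolus).
#' @return a list with `doses` (tibble `time`, `amount`, `duration`) and
#'   `windows` (tibble `cycle`, `start`, `end`). Window `k` spans dose `k` to
#'   dose `k+1`; the last window spans one final interval. Windows partition
#'   `[0, last_end)` contiguously.
#' @export
#' @examples
#' expand_regimen(regimen("1200 mg q3w",
#'                        data.frame(amount = 1200, interval = 21, n_doses = 7)))
expand_regimen <- function(reg, infusion_duration = 1 / 24) {
  stopifnot(inherits(reg, "regimen"))
  if (infusion_duration < 0) abort_field("infusion_duration", "must be >= 0")
  amount <- rep(reg$blocks$amount, reg$blocks$n_doses)
  interval <- rep(reg$blocks$interval, reg$blocks$n_doses)
  ## dose k arrives interval[k] after dose k-1; first dose at time 0
  time <- cumsum(c(0, interval[-1L]))
  n <- length(time)
  doses <- tibble::tibble(time = time, amount = amount,
                          duration = rep(infusion_duration, n))
  ## window k runs to the next dose; the last one spans its own interval
  end <- c(time[-1L], time[n] + interval[n])
  windows <- tibble::tibble(cycle = seq_len(n), start = time, end = end)
  list(doses = doses, windows = windows)
}

#' The four built-in atezolizumab regimens
#'
#' The standard 1200 mg q3w schedule and three extended-interval schedules:
#' two loading doses (840 mg q2w, 1200 mg q3w, or 1680 mg q4w) followed by
#' five maintenance doses of 840 mg q6w — seven cycles each, reaching
#' approximate steady state by cycle 7.
#'
#' @return a named list of four [regimen()] objects.
#' @export
builtin_regimens <- function() {
  blk <- function(amount, interval, n) {
    data.frame(amount = amount, interval = interval, n_doses = n)
  }
  regs <- list(
    regimen("1200 mg q3w", blk(1200, 21, 7)),
    regimen("840 mg q2w x2, 840 mg q6w x5",
            rbind(blk(840, 14, 2), blk(840, 42, 5))),
    regimen("1200 mg q3w x2, 840 mg q6w x5",
            rbind(blk(1200, 21, 2), blk(840, 42, 5))),
    regimen("1680 mg q4w x2, 840 mg q6w x5",
            rbind(blk(1680, 28, 2), blk(840, 42, 5)))
  )
  stats::setNames(regs, vapply(regs, `[[`, "", "name"))
}
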