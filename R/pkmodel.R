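#' Structural (typical) two-compartment parameters
#'
#' Clearance `cl` (L/day), central volume `v1` (L), inter-compartmental
#' clearance `q` (L/day) and peripheral volume `v2` (L). `q = 0` degenerates
#' to a one-compartment model (the engine selects the one-compartment branch).
#'
#' @param cl,v1,q,v2 numeric scalars; all positive (`q` may be 0).
#' @return an object of class `structural_params`.
#' @export
structural_params <- function(cl, v1, q, v2) {
  for (f in c("cl", "v1", "v2")) {
    x <- get(f)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      abort_field(f, "must be a positive finite scalar")
    }
  }
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    abort_field("q", "must be a finite scalar >= 0")
  }
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2), class = "structural_params")
}

#' Define a covariate effect on a PK parameter
#'
#' Continuous covariates use the power model
#' `param * (x / reference) ^ value`; binary covariates use the proportional
#' model `param * (1 + value)` when the flag is set. For categorical columns
#' (e.g. `sex`), supply `level` to define which value raises the flag.
#'
#' @param parameter one of `"cl"`, `"v1"`, `"q"`, `"v2"`.
#' @param covariate population column name (e.g. `"weight"`).
#' @param kind `"power"` or `"proportional"`.
#' @param value exponent (power) or fractional shift (proportional, > -1).
#' @param reference reference covariate value (power only, > 0).
#' @param level for proportional effects on a categorical column, the level
#'   that activates the shift.
#' @return an object of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter, covariate,
                             kind = c("power", "proportional"),
                             value, reference = NULL, level = NULL) {
  kind <- match.arg(kind)
  if (!parameter %in% c("cl", "v1", "q", "v2")) {
    abort_field("parameter", "must be one of cl, v1, q, v2")
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    abort_field("value", "must be a finite numeric scalar")
  }
  if (kind == "power") {
    if (is.null(reference) || !is.numeric(reference) || reference <= 0) {
      abort_field("reference", "power effects require a positive reference")
    }
  } else if (value <= -1) {
    abort_field("value", "proportional shift must be > -1")
  }
  structure(list(parameter = parameter, covariate = covariate, kind = kind,
                 value = value, reference = reference, level = level),
            class = "covariate_effect")
}

#' Apply covariate effects to the typical parameters
#'
#' Effects compose multiplicatively, so the result is independent of the
#' order in which they are listed. A patient at all reference values (and
#' with no binary flags set) recovers the structural parameters exactly.
#'
#' @param structural a [structural_params()].
#' @param effects list of [covariate_effect()]s.
#' @param patient a named list or one-row data frame holding every covariate
#'   the effects reference.
#' @return a `structural_params` with covariate-scaled values.
#' @export
apply_covariates <- function(structural, effects, patient) {
  out <- unclass(structural)
  for (e in effects) {
    if (!e$covariate %in% names(patient)) {
      stop(sprintf("patient lacks covariate `%s`", e$covariate), call. = FALSE)
    }
    x <- patient[[e$covariate]]
    if (e$kind == "power") {
      if (!is.numeric(x) || any(x <= 0)) {
        stop(sprintf("covariate `%s` must be positive for a power effect",
                     e$covariate), call. = FALSE)
      }
      out[[e$parameter]] <- out[[e$parameter]] * (x / e$reference) ^ e$value
    } else {
      flag <- if (!is.null(e$level)) as.character(x) == e$level else as.logical(x)
      if (anyNA(flag)) {
        stop(sprintf("covariate `%s` is not interpretable as a flag", e$covariate),
             call. = FALSE)
      }
      out[[e$parameter]] <- out[[e$parameter]] * ifelse(flag, 1 + e$value, 1)
    }
  }
  structure(out, class = "structural_params")
}

#' Specify log-normal inter-individual variability
#'
#' Individual parameters are `typical * exp(eta)` with
#' `eta ~ MVN(0, Omega)`, `Omega = D R D`, `D = diag(sqrt(omega_sq))`.
#' Parameters absent from `omega_sq` carry no variability.
#'
#' @param omega_sq named numeric vector of log-scale variances, names among
#'   `cl`, `v1`, `q`, `v2`.
#' @param correlation optional correlation matrix over `names(omega_sq)`
#'   (default identity); must be symmetric PSD with unit diagonal.
#' @return an object of class `iiv_spec`.
#' @export
iiv_spec <- function(omega_sq = c(cl = 0, v1 = 0), correlation = NULL) {
  if (is.null(names(omega_sq)) || !all(names(omega_sq) %in% c("cl", "v1", "q", "v2"))) {
    abort_field("omega_sq", "must be named with parameters among cl, v1, q, v2")
  }
  if (any(omega_sq < 0)) abort_field("omega_sq", "variances must be >= 0")
  p <- length(omega_sq)
  if (is.null(correlation)) {
    correlation <- diag(p)
    dimnames(correlation) <- list(names(omega_sq), names(omega_sq))
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-12)) {
    abort_field("correlation", "must be symmetric with unit diagonal")
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    abort_field("correlation", "must be positive semidefinite")
  }
  structure(list(omega_sq = omega_sq, correlation = correlation), class = "iiv_spec")
}

## n draws of eta, an n x p matrix (columns named as omega_sq)
draw_etas <- function(iiv, n) {
  om <- iiv$omega_sq
  p <- length(om)
  eta <- matrix(0, n, p, dimnames = list(NULL, names(om)))
  pos <- which(om > 0)
  if (length(pos)) {
    d <- sqrt(om[pos])
    sigma <- diag(d, length(pos)) %*% iiv$correlation[pos, pos, drop = FALSE] %*%
      diag(d, length(pos))
    ch <- suppressWarnings(chol(sigma, pivot = TRUE))
    piv <- attr(ch, "pivot")
    z <- matrix(stats::rnorm(n * length(pos)), n)
    eta[, pos[piv]] <- z %*% ch
  }
  eta
}

#' Realize individual parameters for one subject
#'
#' Scales `typical` by `exp(eta)` with a fresh multivariate-normal draw from
#' the current RNG stream, then populates the micro/macro rate constants via
#' [macro_constants()].
#'
#' @param typical a [structural_params()] (already covariate-scaled).
#' @param iiv an [iiv_spec()].
#' @return a one-row tibble of individual parameters (see
#'   [individual_params()]).
#' @export
apply_iiv <- function(typical, iiv) {
  eta <- draw_etas(iiv, 1L)
  par <- unclass(typical)
  for (nm in colnames(eta)) par[[nm]] <- unname(par[[nm]] * exp(eta[1L, nm]))
  mk <- macro_constants(par$cl, par$v1, par$q, par$v2)
  tibble::tibble(cl = par$cl, v1 = par$v1, q = par$q, v2 = par$v2,
                 k10 = mk$k10, k12 = mk$k12, k21 = mk$k21,
                 alpha = mk$alpha, beta = mk$beta)
}

#' Micro and macro rate constants of the two-compartment model
#'
#' `k10 = cl/v1`, `k12 = q/v1`, `k21 = q/v2`; `alpha >= beta` are the roots
#' of `s^2 - (k10 + k12 + k21) s + k10 k21 = 0`. When `q = 0` the model is
#' one-compartment: `k12 = k21 = 0`, `alpha = k10`, `beta = 0` (the engine
#' branches on this). Vectorized.
#'
#' @param cl,v1,q,v2 parameter vectors (recycled).
#' @return a list with `k10`, `k12`, `k21`, `alpha`, `beta` (1/day).
#' @export
macro_constants <- function(cl, v1, q, v2) {
  k10 <- cl / v1
  k12 <- ifelse(q > 0, q / v1, 0)
  k21 <- ifelse(q > 0, q / v2, 0)
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  ## q = 0: collapse exactly onto the one-compartment constants
  alpha <- ifelse(q > 0, alpha, k10)
  beta <- ifelse(q > 0, beta, 0)
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Realize individual parameters for a whole population
#'
#' For each subject: covariate-scale the structural parameters, multiply by
#' log-normal IIV drawn from the `"iiv"` substream of `seed`, and derive the
#' rate constants. The draw depends only on the population, model and seed —
#' not on any dosing regimen — so the same subjects carry identical
#' parameters across regimens.
#'
#' @param population tibble from [generate_population()].
#' @param model list with elements `structural` ([structural_params()]),
#'   `effects` (list of [covariate_effect()]) and `iiv` ([iiv_spec()]).
#' @param seed master seed.
#' @return tibble with `subject_id`, `cl`, `v1`, `q`, `v2`, `k10`, `k12`,
#'   `k21`, `alpha`, `beta`.
#' @export
individual_params <- function(population, model, seed = 20260101L) {
  n <- nrow(population)
  eta <- with_substream(seed, "iiv", draw_etas(model$iiv, n))
  cl <- v1 <- q <- v2 <- numeric(n)
  for (i in seq_len(n)) {
    typ <- apply_covariates(model$structural, model$effects, population[i, ])
    cl[i] <- typ$cl; v1[i] <- typ$v1; q[i] <- typ$q; v2[i] <- typ$v2
  }
  for (nm in colnames(eta)) {
    assign(nm, get(nm) * exp(eta[, nm]))
  }
  mk <- macro_constants(cl, v1, q, v2)
  tibble::tibble(subject_id = population$subject_id,
                 cl = cl, v1 = v1, q = q, v2 = v2,
                 k10 = mk$k10, k12 = mk$k12, k21 = mk$k21,
                 alpha = mk$alpha, beta = mk$beta)
}
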