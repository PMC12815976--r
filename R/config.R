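#' Path to the shipped default configuration
#'
#' A fully worked YAML run configuration: population demographics, the
#' two-compartment model with covariate effects and IIV (structural values
#' transcribed from the published atezolizumab population-PK model — see the
#' file's comments for the citation), the four built-in regimens, grid
#' resolution, seed and the 6 ug/mL minimum effective concentration.
#'
#' @return path to `default_config.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "atezosim",
              mustWork = TRUE)
}

#' Read a run configuration
#'
#' Parses the YAML configuration into validated package objects.
#'
#' @param path YAML file (default the shipped configuration).
#' @return an object of class `run_config`: list with `population`
#'   ([population_spec()]), `model` (`structural`, `effects`, `iiv`),
#'   `regimens` (named list of [regimen()]), `resolution`,
#'   `infusion_duration`, `mec`, `seed`.
#' @export
read_run_config <- function(path = default_config_path()) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  for (block in c("population", "model")) {
    if (is.null(cfg[[block]])) abort_field(block, "missing from config")
  }
  seed <- cfg$seed %||% 20260101L
  pop_args <- cfg$population
  pop_args$seed <- pop_args$seed %||% seed
  pop <- do.call(population_spec, pop_args)

  st <- cfg$model$structural
  structural <- structural_params(st$cl, st$v1, st$q %||% 0, st$v2 %||% 1)
  effects <- lapply(cfg$model$covariate_effects %||% list(), function(e) {
    covariate_effect(e$parameter, e$covariate, e$kind, e$value,
                     reference = e$reference, level = e$level)
  })
  om <- unlist(cfg$model$omega_sq %||% list(cl = 0))
  corr <- cfg$model$correlation
  if (!is.null(corr)) corr <- matrix(unlist(corr), length(om), byrow = TRUE)
  iiv <- iiv_spec(om, corr)

  builtins <- builtin_regimens()
  regs <- lapply(cfg$regimens %||% as.list(names(builtins)), function(r) {
    if (is.character(r)) {
      if (!r %in% names(builtins)) {
        stop(sprintf("unknown regimen '%s'; built-ins: %s", r,
                     paste(names(builtins), collapse = "; ")), call. = FALSE)
      }
      builtins[[r]]
    } else {
      blocks <- do.call(rbind, lapply(r$blocks, function(b) {
        data.frame(amount = b$amount, interval = b$interval, n_doses = b$n_doses)
      }))
      regimen(r$name, blocks)
    }
  })
  names(regs) <- vapply(regs, `[[`, "", "name")

  mec <- cfg$mec %||% 6
  if (mec <= 0) abort_field("mec", "must be > 0")
  structure(list(
    population = pop,
    model = list(structural = structural, effects = effects, iiv = iiv),
    regimens = regs,
    resolution = cfg$grid$resolution %||% 0.1,
    infusion_duration = cfg$infusion_duration_days %||% 1 / 24,
    mec = mec,
    seed = seed
  ), class = "run_config")
}
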