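#' Specify a virtual patient population
#'
#' Parameterizes the demographic generator: ages uniform on
#' `[age_min, age_max]`, sex a Bernoulli draw, body weight linear in age with
#' sex-specific intercept and Gaussian noise, albumin and baseline tumor size
#' log-normal, and anti-drug-antibody (ADA) status Bernoulli. Defaults encode
#' the reference oncology population used throughout the package: 1000
#' subjects aged 20-80 with even odds of either sex,
#' `weight = 65 + 0.75 (age - 40) + N(0, 3.5)` kg for females and
#' `85 + 0.75 (age - 40) + N(0, 10)` kg for males, albumin with natural-scale
#' median 42 g/L, tumor size with log-scale location 4.2 (median ~66.7 mm),
#' and a 40% ADA formation probability.
#'
#' The log-scale standard deviations of albumin (0.10) and tumor size (0.70)
#' are calibrated so that the extremes of a 1000-subject draw match the
#' reference population's reported min-max ranges.
#'
#' @param n_subjects number of virtual patients (>= 1).
#' @param age_min,age_max age bounds in years.
#' @param p_male probability a subject is male.
#' @param weight_intercept_f,weight_intercept_m weight at age 40, kg.
#' @param weight_age_slope kg per year of age.
#' @param weight_sd_f,weight_sd_m SD of the Gaussian weight noise, kg.
#' @param albumin_log_median natural-scale median albumin, g/L.
#' @param albumin_log_sd log-scale SD of albumin.
#' @param tumor_log_location log-scale location of tumor size, ln(mm).
#' @param tumor_log_sd log-scale SD of tumor size.
#' @param p_ada probability of ADA formation.
#' @param seed master RNG seed for [generate_population()].
#' @return an object of class `population_spec`.
#' @seealso [generate_population()]
#' @export
population_spec <- function(n_subjects = 1000L,
                            age_min = 20, age_max = 80,
                            p_male = 0.5,
                            weight_intercept_f = 65, weight_intercept_m = 85,
                            weight_age_slope = 0.75,
                            weight_sd_f = 3.5, weight_sd_m = 10,
                            albumin_log_median = 42, albumin_log_sd = 0.10,
                            tumor_log_location = 4.2, tumor_log_sd = 0.70,
                            p_ada = 0.40,
                            seed = 20260101L) {
  spec <- list(
    n_subjects = n_subjects, age_min = age_min, age_max = age_max,
    p_male = p_male,
    weight_intercept_f = weight_intercept_f,
    weight_intercept_m = weight_intercept_m,
    weight_age_slope = weight_age_slope,
    weight_sd_f = weight_sd_f, weight_sd_m = weight_sd_m,
    albumin_log_median = albumin_log_median, albumin_log_sd = albumin_log_sd,
    tumor_log_location = tumor_log_location, tumor_log_sd = tumor_log_sd,
    p_ada = p_ada, seed = seed
  )
  validate_population_spec(spec)
  structure(spec, class = "population_spec")
}

validate_population_spec <- function(spec) {
  num1 <- function(field) {
    x <- spec[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort_field(field, "must be a finite numeric scalar")
    }
    x
  }
  if (num1("n_subjects") < 1 || spec$n_subjects %% 1 != 0) {
    abort_field("n_subjects", "must be a positive integer")
  }
  if (num1("age_min") >= num1("age_max")) {
    abort_field("age_min", "must be strictly less than `age_max`")
  }
  for (p in c("p_male", "p_ada")) {
    if (num1(p) < 0 || spec[[p]] > 1) abort_field(p, "must lie in [0, 1]")
  }
  for (s in c("weight_sd_f", "weight_sd_m", "albumin_log_sd", "tumor_log_sd")) {
    if (num1(s) < 0) abort_field(s, "must be >= 0")
  }
  if (num1("albumin_log_median") <= 0) abort_field("albumin_log_median", "must be > 0")
  num1("weight_intercept_f"); num1("weight_intercept_m"); num1("weight_age_slope")
  num1("tumor_log_location"); num1("seed")
  invisible(spec)
}

#' Sex- and age-dependent body weight
#'
#' `weight = intercept(sex) + slope * (age - 40) + noise`, with the realized
#' Gaussian noise passed explicitly so the formula is deterministic and
#' testable. Vectorized over all three arguments.
#'
#' @param age age in years.
#' @param sex `"male"` or `"female"` (recycled).
#' @param noise realized Gaussian draw in kg (default 0 gives the typical
#'   weight).
#' @param spec a [population_spec()] supplying intercepts and slope.
#' @return weight in kg.
#' @export
#' @examples
#' sample_weight(40, "female")  # 65
#' sample_weight(60, "female")  # 80
sample_weight <- function(age, sex, noise = 0, spec = population_spec()) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop(sprintf("unknown sex category: %s", paste(unique(sex[bad]), collapse = ", ")),
         call. = FALSE)
  }
  intercept <- ifelse(sex == "male", spec$weight_intercept_m, spec$weight_intercept_f)
  intercept + spec$weight_age_slope * (age - 40) + noise
}

#' Draw albumin and baseline tumor size
#'
#' Both covariates are log-normal: `albumin = exp(N(ln median, sd))` and
#' `tumor = exp(N(location, sd))`, so the natural-scale medians are
#' `albumin_log_median` and `exp(tumor_log_location)` irrespective of the
#' log-scale SDs.
#'
#' @param n number of draws.
#' @param spec a [population_spec()].
#' @return a list with numeric vectors `albumin` (g/L) and `tumor_size` (mm).
#' @export
sample_covariates <- function(n, spec = population_spec()) {
  list(
    albumin = exp(stats::rnorm(n, log(spec$albumin_log_median), spec$albumin_log_sd)),
    tumor_size = exp(stats::rnorm(n, spec$tumor_log_location, spec$tumor_log_sd))
  )
}

#' Generate the virtual patient population
#'
#' Draws `n_subjects` virtual patients under the demographic model of
#' [population_spec()]. Each quantity (age, sex, weight noise, albumin, tumor
#' size, ADA) uses its own RNG substream derived from the master seed, so the
#' table is reproducible column-by-column. Weight draws below 20 kg are
#' resampled (attribute `weight_resamples` counts occurrences; practically
#' zero at the default noise scales).
#'
#' @param spec a [population_spec()].
#' @return a tibble with columns `subject_id`, `age` (years), `sex`
#'   (`"male"`/`"female"`), `weight` (kg), `albumin` (g/L), `tumor_size`
#'   (mm), `ada` (logical).
#' @export
#' @examples
#' pop <- generate_population(population_spec(n_subjects = 5, seed = 1))
#' pop
generate_population <- function(spec = population_spec()) {
  validate_population_spec(spec)
  n <- as.integer(spec$n_subjects)
  seed <- spec$seed

  age <- with_substream(seed, "age", stats::runif(n, spec$age_min, spec$age_max))
  sex <- with_substream(seed, "sex",
                        ifelse(stats::runif(n) < spec$p_male, "male", "female"))
  ada <- with_substream(seed, "ada", stats::runif(n) < spec$p_ada)

  resamples <- 0L
  weight <- with_substream(seed, "weight", {
    sd <- ifelse(sex == "male", spec$weight_sd_m, spec$weight_sd_f)
    w <- sample_weight(age, sex, stats::rnorm(n, 0, sd), spec)
    while (any(low <- w <= 20)) {  # guard against non-physical weights
      resamples <- resamples + sum(low)
      w[low] <- sample_weight(age[low], sex[low],
                              stats::rnorm(sum(low), 0, sd[low]), spec)
    }
    w
  })

  albumin <- with_substream(seed, "albumin",
                            exp(stats::rnorm(n, log(spec$albumin_log_median),
                                             spec$albumin_log_sd)))
  tumor <- with_substream(seed, "tumor",
                          exp(stats::rnorm(n, spec$tumor_log_location,
                                           spec$tumor_log_sd)))

  out <- tibble::tibble(
    subject_id = seq_len(n),
    age = age, sex = sex, weight = weight,
    albumin = albumin, tumor_size = tumor, ada = ada
  )
  attr(out, "weight_resamples") <- resamples
  out
}

population_columns <- c("subject_id", "age", "sex", "weight",
                        "albumin", "tumor_size", "ada")

#' Write / read a population table
#'
#' Plain comma-delimited text with a header row; `sex` is encoded
#' `male`/`female` and `ada` as 0/1. `read_population()` validates the header
#' and every row, reporting the first offending line.
#'
#' @param population a population tibble from [generate_population()].
#' @param path file path.
#' @return `write_population()` returns `path` invisibly; `read_population()`
#'   returns the population tibble.
#' @export
write_population <- function(population, path) {
  stopifnot(all(population_columns %in% names(population)))
  out <- population[population_columns]
  out$ada <- as.integer(out$ada)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  if (!file.size(path) > 0) {
    stop(sprintf("population file '%s' is empty", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(population_columns, names(raw))
  if (length(missing)) {
    stop(sprintf("population file '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("subject_id", "age", "weight", "albumin", "tumor_size", "ada")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stop(sprintf("parse error in '%s', column `%s`, line %d (+1 for header)",
                   path, col, which(is.na(v))[1L]), call. = FALSE)
    }
    raw[[col]] <- v
  }
  bad_sex <- !raw$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop(sprintf("parse error in '%s', column `sex`, line %d (+1 for header)",
                 path, which(bad_sex)[1L]), call. = FALSE)
  }
  tibble::tibble(
    subject_id = as.integer(raw$subject_id),
    age = raw$age, sex = raw$sex, weight = raw$weight,
    albumin = raw$albumin, tumor_size = raw$tumor_size,
    ada = raw$ada != 0
  )
}
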