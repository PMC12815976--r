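# Shared fixtures. The PK parameter values here are arbitrary documented
# test values (CL 0.2 L/day, V1 3 L, Q 0.5 L/day, V2 4 L) chosen for
# convenient magnitudes; correctness of the machinery never depends on the
# shipped default configuration.

test_structural <- function() structural_params(cl = 0.2, v1 = 3, q = 0.5, v2 = 4)

# one-row individual-parameter table from raw values
make_params <- function(cl = 0.2, v1 = 3, q = 0.5, v2 = 4, id = 1L) {
  mk <- macro_constants(cl, v1, q, v2)
  tibble::tibble(subject_id = id, cl = cl, v1 = v1, q = q, v2 = v2,
                 k10 = mk$k10, k12 = mk$k12, k21 = mk$k21,
                 alpha = mk$alpha, beta = mk$beta)
}

# random positive two-compartment parameter set (uses the caller's RNG state)
random_params <- function(id = 1L) {
  make_params(cl = runif(1, 0.05, 0.6), v1 = runif(1, 1, 8),
              q = runif(1, 0.05, 2), v2 = runif(1, 1, 10), id = id)
}

# a small model (structural + effects + IIV) with documented arbitrary values
test_model <- function(omega_cl = 0.09, omega_v1 = 0.04) {
  list(
    structural = test_structural(),
    effects = list(
      covariate_effect("cl", "weight", "power", value = 0.75, reference = 80),
      covariate_effect("cl", "ada", "proportional", value = 0.2),
      covariate_effect("v1", "weight", "power", value = 0.6, reference = 80)
    ),
    iiv = iiv_spec(c(cl = omega_cl, v1 = omega_v1))
  )
}

# a patient sitting at every reference covariate value, no flags set
reference_patient <- function() {
  list(subject_id = 1L, age = 50, sex = "male", weight = 80,
       albumin = 40, tumor_size = 60, ada = FALSE)
}

tiny_population <- function(n = 5, seed = 42) {
  generate_population(population_spec(n_subjects = n, seed = seed))
}
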