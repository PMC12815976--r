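test_that("closed form reduces to monoexponential decay when q = 0", {
  p <- make_params(cl = 0.3, v1 = 2, q = 0, v2 = 1)
  doses <- tibble::tibble(time = 0, amount = 100, duration = 0)
  t <- seq(0, 30, by = 0.5)
  expect_equal(conc_closed_form(p, doses, t), 100 / 2 * exp(-0.15 * t),
               tolerance = 1e-14)
})

test_that("concentration is zero before the first dose and never negative", {
  set.seed(31)
  p <- random_params()
  ev <- expand_regimen(builtin_regimens()[[1]])
  expect_equal(conc_closed_form(p, ev$doses, c(-1, -1e-9)), c(0, 0))
  grid <- time_grid(ev$windows, ev$doses, 0.25)
  expect_true(all(conc_closed_form(p, ev$doses, grid$time) >= 0))
})

test_that("profiles superpose over doses and scale linearly in dose", {
  set.seed(17)
  p <- random_params()
  tau <- 21
  t <- seq(0, 84, by = 0.25)
  d1 <- tibble::tibble(time = 0, amount = 500, duration = 1 / 24)
  d2 <- tibble::tibble(time = tau, amount = 500, duration = 1 / 24)
  both <- rbind(d1, d2)
  expect_equal(conc_closed_form(p, both, t),
               conc_closed_form(p, d1, t) + conc_closed_form(p, d2, t),
               tolerance = 1e-12)
  # doubling every dose doubles the profile pointwise
  doubled <- both; doubled$amount <- doubled$amount * 2
  expect_equal(conc_closed_form(p, doubled, t),
               2 * conc_closed_form(p, both, t), tolerance = 1e-12)
})

test_that("closed form agrees with the ODE oracle on built-in regimens", {
  # spot check at fine tolerance; the full 100-set sweep runs in the
  # acceptance suite
  set.seed(57)
  regs <- builtin_regimens()
  for (i in 1:5) {
    p <- random_params()
    reg <- regs[[(i %% 4) + 1]]
    ev <- expand_regimen(reg)
    grid <- time_grid(ev$windows, ev$doses, 1)
    cc <- conc_closed_form(p, ev$doses, grid$time)
    oo <- ode_oracle(p, ev$doses, grid$time, rtol = 1e-10, atol = 1e-10)
    expect_lt(max(abs(cc - oo)) / max(oo), 1e-6)
  }
})

test_that("the ODE oracle conserves mass", {
  set.seed(71)
  p <- random_params()
  ev <- expand_regimen(builtin_regimens()[["1200 mg q3w"]])
  t <- c(0.5, 5, 21, 63, 126, 147)
  full <- ode_oracle(p, ev$doses, t, full = TRUE)
  infused <- vapply(t, function(ti) {
    done <- pmin(pmax(ti - ev$doses$time, 0), ev$doses$duration)
    sum(ev$doses$amount * done / ev$doses$duration)
  }, 0)
  # infused amount = central + peripheral + eliminated (CL * integral of C)
  expect_equal(full$a1 + full$a2 + full$eliminated, infused, tolerance = 1e-6)
})

test_that("single-dose AUC to infinity equals dose over clearance", {
  set.seed(83)
  for (i in 1:20) {
    p <- random_params()
    # analytic AUC of the biexponential: (D/V1)(A/alpha + B/beta) = D/CL
    A <- (p$alpha - p$k21) / (p$alpha - p$beta)
    B <- (p$k21 - p$beta) / (p$alpha - p$beta)
    D <- 1200
    auc <- (D / p$v1) * (A / p$alpha + B / p$beta)
    expect_equal(auc, D / p$cl, tolerance = 1e-12)
  }
  # numerically: everything infused is eventually eliminated
  p <- make_params()
  doses <- tibble::tibble(time = 0, amount = 1200, duration = 1 / 24)
  full <- ode_oracle(p, doses, 3000, full = TRUE)
  expect_equal(full$eliminated, 1200, tolerance = 1e-6 * 1200)
})

test_that("geometric-series steady-state trough matches 50-dose brute force", {
  set.seed(97)
  for (i in 1:10) {
    # the 50-dose brute force converges to 1e-9 only once the slow phase has
    # turned over: its truncation error is ~exp(-49 beta tau), so require
    # beta * tau >= 0.5
    tau <- sample(c(14, 21, 28, 42), 1)
    repeat {
      p <- random_params()
      if (p$beta * tau >= 0.5) break
    }
    ss <- steady_state_trough(p, 840, tau, duration = 1 / 24)
    brute <- tibble::tibble(time = seq(0, 49 * tau, by = tau), amount = 840,
                            duration = 1 / 24)
    bt <- conc_closed_form(p, brute, 50 * tau)
    expect_lt(abs(ss - bt) / bt, 1e-9)
  }
})

test_that("near-confluent roots are handled smoothly", {
  # k12 -> 0 squeezes beta toward min(k10, k21); force alpha ~ beta via
  # k10 = k21 and tiny q/v1
  p <- make_params(cl = 0.2, v1 = 1, q = 1e-13, v2 = 5e-13)
  doses <- tibble::tibble(time = 0, amount = 100, duration = 1 / 24)
  t <- seq(0, 30, by = 0.5)
  c1 <- conc_closed_form(p, doses, t)
  ref <- conc_closed_form(make_params(cl = 0.2, v1 = 1, q = 0, v2 = 1), doses, t)
  expect_equal(c1, ref, tolerance = 1e-4)
  expect_true(all(is.finite(c1)))
})

test_that("population simulation is deterministic and degenerate-safe", {
  pop <- tiny_population(n = 8, seed = 13)
  model <- test_model()
  reg <- builtin_regimens()[["1200 mg q3w"]]
  s1 <- simulate_population(pop, model, reg, resolution = 0.5, seed = 7)
  s2 <- simulate_population(pop, model, reg, resolution = 0.5, seed = 7)
  expect_identical(s1$profiles, s2$profiles)

  # zero IIV + identical covariates: all profiles identical
  pop0 <- pop
  pop0$weight <- 80; pop0$ada <- FALSE; pop0$sex <- "male"
  pop0$albumin <- 40; pop0$tumor_size <- 60
  model0 <- test_model(omega_cl = 0, omega_v1 = 0)
  s0 <- simulate_population(pop0, model0, reg, resolution = 0.5, seed = 7)
  ref <- s0$profiles$conc[s0$profiles$subject_id == 1]
  for (id in unique(s0$profiles$subject_id)) {
    expect_identical(s0$profiles$conc[s0$profiles$subject_id == id], ref)
  }
  # observation count = subjects x grid points
  ev <- expand_regimen(reg)
  npt <- nrow(time_grid(ev$windows, ev$doses, 0.5))
  expect_equal(nrow(s0$profiles), 8 * npt)
})

test_that("the observation grid covers every cycle with its endpoints", {
  ev <- expand_regimen(builtin_regimens()[["840 mg q2w x2, 840 mg q6w x5"]])
  grid <- time_grid(ev$windows, ev$doses, 0.1)
  for (k in 1:7) {
    tk <- grid$time[grid$cycle == k]
    expect_equal(min(tk), ev$windows$start[k])
    expect_equal(max(tk), ev$windows$end[k])
    expect_true(all(diff(tk) > 0))
    # end-of-infusion time present so Cmax sits on the grid
    expect_true(any(abs(tk - (ev$doses$time[k] + ev$doses$duration[k])) < 1e-12))
  }
})
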