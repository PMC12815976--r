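test_that("the shipped configuration parses into valid objects", {
  cfg <- read_run_config()
  expect_s3_class(cfg, "run_config")
  expect_s3_class(cfg$population, "population_spec")
  expect_length(cfg$regimens, 4L)
  expect_equal(cfg$mec, 6)
  expect_equal(cfg$resolution, 0.1)
  expect_gt(cfg$model$structural$cl, 0)
  expect_error(read_run_config("no-such-file.yaml"), "not found")
})

test_that("config rejects unknown regimen names", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("population: {n_subjects: 5}",
               "model: {structural: {cl: 0.2, v1: 3, q: 0.5, v2: 4}}",
               "regimens: ['no such regimen']"), bad)
  expect_error(read_run_config(bad), "unknown regimen")
})

test_that("NONMEM export has the documented row structure", {
  pop <- tiny_population(n = 1, seed = 20)
  reg <- builtin_regimens()[["1200 mg q3w"]]
  ds <- export_nonmem_dataset(pop, reg, resolution = 2)
  ev <- expand_regimen(reg)
  n_obs <- length(unique(time_grid(ev$windows, ev$doses, 2)$time))
  expect_equal(nrow(ds), 7 + n_obs)  # 7 dose rows + observation rows
  dose_rows <- ds[ds$EVID == 1, ]
  expect_equal(dose_rows$RATE, dose_rows$AMT * 24)  # 1-hour infusions
  expect_equal(dose_rows$CMT, rep(1L, 7))
  # sorted by TIME with dose rows preceding same-time observations
  expect_true(all(diff(ds$TIME) >= 0))
  same_t <- ds$TIME %in% dose_rows$TIME
  first_at <- tapply(seq_len(nrow(ds))[same_t], ds$TIME[same_t], min)
  expect_true(all(ds$EVID[first_at] == 1))
  # covariates ride along on every row
  expect_true(all(c("WT", "ALB", "TUM", "ADA", "SEX") %in% names(ds)))
  # written file uses '.' for missing DV
  path <- withr::local_tempfile(fileext = ".csv")
  export_nonmem_dataset(pop, reg, resolution = 2, path = path)
  txt <- utils::read.csv(path, colClasses = "character")
  expect_true(all(txt$DV == "."))
})

test_that("re-simulating from exported event rows reproduces the profile", {
  pop <- tiny_population(n = 2, seed = 25)
  model <- test_model()
  reg <- builtin_regimens()[["840 mg q2w x2, 840 mg q6w x5"]]
  sim <- simulate_population(pop, model, reg, resolution = 0.5, seed = 11)
  ds <- export_nonmem_dataset(pop, reg, resolution = 0.5)
  for (id in pop$subject_id) {
    doses <- doses_from_nonmem(ds, id)
    pr <- sim$profiles[sim$profiles$subject_id == id, ]
    redo <- conc_closed_form(sim$params[sim$params$subject_id == id, ],
                             doses, pr$time)
    expect_equal(redo, pr$conc, tolerance = 1e-12)
  }
})

test_that("ribbon figures carry the median, band and MEC line", {
  pop <- tiny_population(n = 10, seed = 33)
  sim <- simulate_population(pop, test_model(), builtin_regimens()[[2]],
                             resolution = 0.5, seed = 12)
  fig <- plot_cycle_ribbon(sim, 1, mec = 6)
  expect_s3_class(fig, "ggplot")
  geoms <- vapply(fig$layers, function(l) class(l$geom)[1], "")
  expect_true("GeomRibbon" %in% geoms)
  expect_true("GeomLine" %in% geoms)
  expect_true("GeomHline" %in% geoms)
  expect_equal(
    unique(ggplot2::layer_data(fig, which(geoms == "GeomHline"))$yintercept), 6)
  # x-range equals the cycle-1 window length (14 d for the q2w regimen)
  expect_equal(range(ggplot2::layer_data(fig, which(geoms == "GeomLine"))$x),
               c(0, 14))
  # zero-IIV: band collapses onto the median
  pop0 <- pop; pop0$weight <- 80; pop0$ada <- FALSE; pop0$sex <- "male"
  sim0 <- simulate_population(pop0, test_model(omega_cl = 0, omega_v1 = 0),
                              builtin_regimens()[[2]], resolution = 0.5, seed = 12)
  f0 <- plot_cycle_ribbon(sim0, 1)
  rb <- ggplot2::layer_data(f0, which(geoms == "GeomRibbon"))
  expect_equal(rb$ymin, rb$ymax, tolerance = 1e-12)
  expect_error(plot_cycle_ribbon(sim, 99), "no cycle")
})

test_that("throughput benchmark reports counts and rate", {
  b <- benchmark_throughput(function() {
    Sys.sleep(0.05)
    tibble::tibble(x = 1:1000)
  })
  expect_equal(b$n_observations, 1000)
  expect_gt(b$wall_seconds, 0)
  expect_equal(b$obs_per_sec, b$n_observations / b$wall_seconds)
  # repeated runs count identically
  pop <- tiny_population(n = 3, seed = 40)
  run <- function() simulate_population(pop, test_model(), builtin_regimens()[[1]],
                                        resolution = 1, seed = 2)
  expect_equal(benchmark_throughput(run)$n_observations,
               benchmark_throughput(run)$n_observations)
})

test_that("a reduced pipeline writes tables and figures deterministically", {
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 404",
    "population: {n_subjects: 25}",
    "model:",
    "  structural: {cl: 0.2, v1: 3.28, q: 0.546, v2: 3.63}",
    "  covariate_effects:",
    "    - {parameter: cl, covariate: weight, kind: power, reference: 77, value: 0.75}",
    "  omega_sq: {cl: 0.09}",
    "grid: {resolution: 0.5}"), cfgfile)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  m1 <- suppressMessages(run_pipeline(cfgfile, outdir = out1))
  m2 <- suppressMessages(run_pipeline(cfgfile, outdir = out2))
  expect_length(list.files(out1, pattern = "^summary_.*csv$"), 4L)
  expect_length(list.files(file.path(out1, "figures"), pattern = "png$"), 8L)
  expect_length(list.files(file.path(out1, "figures"), pattern = "pdf$"), 8L)
  # byte-identical tables across runs with one seed
  for (f in c("population.csv", sprintf("summary_%d.csv", 1:4))) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }
  # identical first cycle for the two q3w-loaded regimens
  s_q3w <- m1$summaries[["1200 mg q3w"]]
  s_mix <- m1$summaries[["1200 mg q3w x2, 840 mg q6w x5"]]
  drop_reg <- function(x) x[x$cycle == 1, setdiff(names(x), "regimen")]
  expect_equal(drop_reg(s_q3w), drop_reg(s_mix),
               tolerance = 1e-12, ignore_attr = TRUE)
})
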