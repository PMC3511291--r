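test_that("unit populations reproduce the requested TOP distribution", {
  pop <- sample_unit_population(100000, mu_top = 42.4, sd_top = 23,
                                mu_tcp = 10.2, sd_tcp = 4,
                                unit_volume = 0.01, seed = 1)
  # re-drawing only the TCP keeps the TOP marginal exactly normal
  expect_lt(abs(mean(pop$top) - 42.4), 0.25)         # 3*sd/sqrt(n) scale
  expect_lt(abs(sd(pop$top) - 23), 0.25)
  expect_true(all(pop$tcp < pop$top))
  expect_false(any(pop$is_open))
  expect_equal(pop$n_units * pop$unit_volume, 1000)
})

test_that("population sampling is deterministic and handles degenerate SDs", {
  a <- sample_unit_population(500, 30, 1e-6, 10, 1, 0.1, seed = 7)
  b <- sample_unit_population(500, 30, 1e-6, 10, 1, 0.1, seed = 7)
  expect_identical(a, b)
  expect_equal(a$top, rep(30, 500), tolerance = 1e-4)
})

test_that("population sampling rejects infeasible configurations", {
  expect_error(sample_unit_population(10, 30, -1, 10, 1, 0.1, seed = 1),
               "sd_top and sd_tcp")
  expect_error(sample_unit_population(10, 30, 5, 10, 1, 0, seed = 1),
               "unit_volume")
  expect_error(sample_unit_population(10, 30, 5, 10, 1, 0.1),
               "seed")
  # mu_tcp far above mu_top: the hysteresis constraint cannot be met quickly
  expect_error(sample_unit_population(10, 10, 1, 30, 1, 0.1, seed = 1),
               "configuration error")
})

test_that("ventilator settings validate the manoeuvre protocol", {
  expect_error(ventilator_settings(peep_schedule = c(10, 5)),
               "strictly increasing")
  expect_error(ventilator_settings(sample_rate = 10), "25 Hz")
  expect_error(ventilator_settings(peep_schedule = numeric(0)),
               "at least one")
})

test_that("simulated manoeuvres are reproducible and mass-consistent", {
  rec1 <- sim_small(noise = 0.02, seed = 3)
  rec2 <- sim_small(noise = 0.02, seed = 3)
  expect_identical(rec1, rec2)

  rec <- sim_small(noise = 0)
  truth <- attr(rec, "truth")
  # end-expiratory volume is non-decreasing across PEEP steps (hysteresis)
  expect_true(all(truth$trapped_per_step >= 0))
  # the volume channel tracks the committed unit state at end-expiration
  expect_equal(rec$volume_ml[nrow(rec)],
               truth$eev_per_level[length(truth$eev_per_level)],
               tolerance = 0.02 * truth$vt)
  # volume never exceeds capacity, pressure never below PEEP at end-exp
  expect_true(max(rec$volume_ml) <= truth$capacity)
  ends <- which(diff(c(rec$peep_cmH2O, Inf)) != 0)
  expect_true(all(rec$paw_cmH2O[ends] >= rec$peep_cmH2O[ends] - 1e-9))
})

test_that("a single PEEP level reaches a breath-to-breath steady state", {
  rec <- simulate_rm(small_population(),
                     small_settings(peep_schedule = 8, breaths_per_level = 10),
                     noise_sd_frac = 0, seed = 1)
  eev <- attr(rec, "truth")$eev_per_breath
  # constant up to the unit-volume quantisation of the committed state
  expect_lt(max(abs(diff(eev[3:10]))), 0.01 * attr(rec, "truth")$vt)
})

test_that("auto-PEEP raises the end-expiratory pressure floor", {
  rec <- simulate_rm(small_population(),
                     small_settings(peep_schedule = c(5, 10),
                                    breaths_per_level = 4),
                     noise_sd_frac = 0, auto_peep = 3, seed = 1)
  ends <- which(diff(c(rec$peep_cmH2O, Inf)) != 0)
  expect_true(all(rec$paw_cmH2O[ends] >= rec$peep_cmH2O[ends] + 3 - 1e-9))
})

test_that("ventilation of an already-open lung is reported as infeasible", {
  # every TOP below the lowest PEEP forces TCP below it too (hysteresis), so
  # no unit can ever close and the delivered volume cannot be accommodated
  pop <- sample_unit_population(2000, mu_top = 3, sd_top = 0.5,
                                mu_tcp = 1, sd_tcp = 0.3,
                                unit_volume = 0.5, seed = 2)
  expect_error(simulate_rm(pop, small_settings(), noise_sd_frac = 0, seed = 1),
               "infeasible ventilation")
  # tidal volume beyond total capacity is rejected up front
  tiny <- sample_unit_population(10, 40, 5, 10, 2, 0.5, seed = 1)
  expect_error(simulate_rm(tiny, small_settings(), noise_sd_frac = 0, seed = 1),
               "infeasible ventilation")
})

test_that("quasi-static inflation converges to the error-function curve", {
  pop <- small_population(seed = 5, n_units = 100000, unit_volume = 0.01)
  grid <- seq(0, 110, length.out = 223)
  qs <- quasi_static_inflation(pop, grid)
  truth <- model_volume(grid, recruit_params(pop$mu_top, pop$sd_top,
                                             pop$n_units * pop$unit_volume))
  expect_lt(max(abs(qs$volume - truth)),
            0.01 * pop$n_units * pop$unit_volume)
})

test_that("waveform CSV round trip preserves the record", {
  rec <- sim_small(noise = 0.02, seed = 9,
                   settings = small_settings(breaths_per_level = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(rec, path)
  back <- read_waveform_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_s3_class(back, "waveform_record")
})
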