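test_that("breath segmentation recovers the simulated breath count and volumes", {
  rec <- sim_small(noise = 0)
  br <- segment_breaths(rec)
  expect_equal(nrow(br), 4 * 6)
  expect_equal(unique(br$peep_cmH2O), c(5, 10, 15, 20))
  vt <- attr(rec, "truth")$vt
  # steady-state breaths deliver the set tidal volume
  expect_lt(max(abs(br$inspired_ml[br$insp_start > 1] - vt)) / vt, 0.01)
  expect_true(all(br$insp_start < br$insp_end & br$insp_end < br$exp_end))
  # segmentation is robust at the default 2% measurement noise
  brn <- segment_breaths(sim_small(noise = 0.02, seed = 4))
  expect_equal(nrow(brn), 4 * 6)
})

test_that("segmentation fails informatively on flowless records", {
  rec <- data.frame(time_s = seq(0, 1, by = 0.02),
                    paw_cmH2O = 5, flow_ml_s = 0, volume_ml = 0,
                    peep_cmH2O = 5)
  class(rec) <- c("waveform_record", "data.frame")
  expect_error(segment_breaths(rec), "no breaths detected")
  expect_error(segment_breaths(rec[0, ]), "empty")
})

test_that("the representative breath averages the last two breaths", {
  rec <- sim_small(noise = 0)
  br <- segment_breaths(rec)
  rb <- select_representative_breath(br, rec, peep = 10)
  last2 <- br[br$peep_cmH2O == 10, ][5:6, ]
  # at steady state the mean of the last two equals either one
  expect_equal(rb$inspired_ml, last2$inspired_ml[2],
               tolerance = 0.005)
  expect_false(rb$single_breath)
  # "last" mode returns the final breath exactly
  rb_last <- select_representative_breath(br, rec, peep = 10,
                                          method = "last")
  expect_equal(rb_last$inspired_ml, last2$inspired_ml[2])
  # a single available breath is returned with a warning flag
  one <- br[br$peep_cmH2O == 15, ][1, ]
  expect_warning(rb1 <- select_representative_breath(one, rec, peep = 15),
                 "only one breath")
  expect_true(rb1$single_breath)
  expect_error(select_representative_breath(br[0, ], rec, peep = 15),
               "missing level")
})

test_that("trapped-volume estimates match the simulator ground truth", {
  rec <- sim_small(noise = 0)
  br <- segment_breaths(rec)
  truth <- attr(rec, "truth")$trapped_per_step
  est <- trapped_volumes(rec, br, include_washin = FALSE)
  expect_equal(length(est), 3L)
  expect_lt(max(abs(est - truth) / truth), 0.05)
  # with the wash-in increment, the first entry is the level-1 gain
  est_w <- trapped_volumes(rec, br)
  expect_equal(unname(est_w[-1]), unname(est))
  expect_equal(unname(est_w[1]), attr(rec, "truth")$eev_per_level[1],
               tolerance = 0.05 * attr(rec, "truth")$eev_per_level[1])
  expect_error(estimate_trapped_volume(rec, br[0, ]), "empty")
})

test_that("negative trapped estimates are clamped to zero with a warning", {
  fake <- data.frame(insp_start = 1, insp_end = 2, exp_end = 3,
                     peep_cmH2O = 10, inspired_ml = 100, expired_ml = 104)
  expect_warning(est <- estimate_trapped_volume(NULL, fake), "clamped")
  expect_equal(est, 0)
})

test_that("a population that cannot stay open traps no volume at any step", {
  # all TCP above the top PEEP: every opened unit closes again each breath
  pop <- sample_unit_population(20000, mu_top = 35, sd_top = 5,
                                mu_tcp = 28, sd_tcp = 2,
                                unit_volume = 0.05, seed = 3)
  rec <- simulate_rm(pop, small_settings(), noise_sd_frac = 0, seed = 1)
  # a sliver of units has TOP (hence TCP) below 20 and stays open; the
  # trapped gain per step is bounded by that sliver (~0.1% of capacity)
  expect_true(all(abs(attr(rec, "truth")$trapped_per_step) < 2))
  br <- segment_breaths(rec)
  est <- suppressWarnings(trapped_volumes(rec, br, include_washin = FALSE))
  expect_true(all(abs(est) < 2))
})

test_that("PV-curve offsets stack additively over the PEEP increments", {
  rec <- sim_small(noise = 0)
  br <- segment_breaths(rec)
  # without the wash-in term, offsets are the running sum of the
  # preceding increments and the first level carries no offset
  cv0 <- build_pv_curves(rec, br, include_washin = FALSE)
  tv <- trapped_volumes(rec, br, include_washin = FALSE)
  off0 <- vapply(cv0[c(1, 3, 5, 7)], `[[`, numeric(1), "offset")
  expect_identical(off0[1], 0)
  expect_equal(unname(off0), unname(c(0, cumsum(tv))))
  # with the wash-in term, additivity still holds increment by increment
  cvw <- build_pv_curves(rec, br)
  tvw <- trapped_volumes(rec, br)
  offw <- vapply(cvw[c(1, 3, 5, 7)], `[[`, numeric(1), "offset")
  expect_equal(unname(diff(offw)), unname(tvw[-1]))
  expect_equal(unname(offw[1]), unname(tvw[1]))
})

test_that("curves are monotone and carry both limbs per level", {
  rec <- sim_small(noise = 0)
  br <- segment_breaths(rec)
  cv <- build_pv_curves(rec, br, resistance = 0.02)
  expect_length(cv, 8L)
  for (c1 in cv) {
    d <- diff(c1$pressure)
    if (c1$limb == "inflation") {
      expect_true(all(d > 0))
      expect_true(all(diff(c1$volume) > -1e-6))
    } else {
      expect_true(all(d < 0))
    }
    expect_gte(min(c1$volume), 0)
    expect_gte(length(c1$pressure), 3L)
  }
})

test_that("without hysteretic retention the inflation curves lie on the
           static recruitment curve", {
  # all TCP above the top PEEP: no trapped volume, so every inflation limb
  # retraces the quasi-static error-function curve of the population
  pop <- sample_unit_population(50000, mu_top = 35, sd_top = 5,
                                mu_tcp = 28, sd_tcp = 2,
                                unit_volume = 0.02, seed = 3)
  rec <- simulate_rm(pop, small_settings(), noise_sd_frac = 0, seed = 1)
  br <- segment_breaths(rec)
  # trapped estimates in this configuration are ~0 and may clamp at 0
  cv <- suppressWarnings(build_pv_curves(rec, br, resistance = 0.02))
  cap <- pop$n_units * pop$unit_volume
  truth <- recruit_params(pop$mu_top, pop$sd_top, cap)
  for (c1 in cv) {
    if (c1$limb != "inflation") next
    expect_lt(max(abs(c1$volume - model_volume(c1$pressure, truth))),
              0.01 * cap)
  }
})

test_that("PV curves can be written as CSV", {
  rec <- sim_small(noise = 0, settings = small_settings(breaths_per_level = 3))
  br <- segment_breaths(rec)
  cv <- build_pv_curves(rec, br)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pv_csv(cv, path)
  back <- utils::read.csv(path)
  expect_named(back, c("limb", "peep_cmH2O", "pressure_cmH2O", "volume_ml"))
  expect_equal(nrow(back), sum(vapply(cv, function(x) length(x$pressure),
                                      numeric(1))))
})

test_that("pv_curve validates its invariants", {
  expect_error(pv_curve("inflation", 5, c(1, 2), c(1, 2)), "3 points")
  expect_error(pv_curve("inflation", 5, c(1, 2, 2.5, 2), 1:4),
               "strictly increasing")
  expect_error(pv_curve("deflation", 5, c(3, 2, 2.5), 1:3),
               "strictly decreasing")
  expect_error(pv_curve("inflation", 5, 1:3, c(-5, 1, 2)), "non-negative")
})
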