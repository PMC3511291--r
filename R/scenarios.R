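# Scenario configurations: a YAML-serialisable bundle of population
# parameters and ventilator settings describing one manoeuvre.

#' Scenario configurations for the simulated manoeuvres
#'
#' A scenario bundles the ground-truth unit-population parameters and the
#' ventilator settings for one step-wise PEEP manoeuvre. `healthy_scenario()`
#' describes a healthy anaesthetised 24-kg subject with mild atelectasis:
#' TOP ~ N(42, 19) cmH2O (the scale of baseline-PEEP fits in healthy lungs)
#' and a recruitable capacity of 1000 ml (about 42 ml/kg).
#' `ards_scenario()` shifts the TOP distribution up by 15 cmH2O and widens
#' it by 5 cmH2O (more collapse, more heterogeneity). Both use
#' TCP ~ N(18, 12) cmH2O: the closing distribution must overlap the tidal
#' pressure range at every PEEP level (a feasibility requirement of the
#' fixed-unit-volume mechanics: what is exhaled each breath is the volume of
#' units that close) and must place closing mass inside every PEEP step so
#' each increment traps volume, the behaviour the stacked PV curves of a
#' recruitment manoeuvre show; see the methods vignette. Measurement noise
#' is 2% multiplicative.
#'
#' @param ... Named overrides of individual fields (e.g. `noise_sd_frac = 0`,
#'   `n_units = 2e4`).
#' @return A list of class `rm_scenario` with elements `population`
#'   (n_units, mu_top, sd_top, mu_tcp, sd_tcp, unit_volume), `settings`
#'   ([ventilator_settings()] fields), `noise_sd_frac`, `auto_peep`.
#' @export
healthy_scenario <- function(...) {
  sc <- list(
    name = "healthy",
    population = list(n_units = 100000L, mu_top = 42, sd_top = 19,
                      mu_tcp = 18, sd_tcp = 12, unit_volume = 0.010),
    settings = list(weight_kg = 24, vt_ml_per_kg = 12,
                    peep_schedule = c(5, 10, 15, 20), breaths_per_level = 12,
                    resp_rate = 15, sample_rate = 50, resistance = 0.02,
                    fio2 = 0.5),
    noise_sd_frac = 0.02,
    auto_peep = 0)
  modify_scenario(sc, ...)
}

#' @rdname healthy_scenario
#' @export
ards_scenario <- function(...) {
  sc <- healthy_scenario()
  sc$name <- "ards"
  sc$population$mu_top <- sc$population$mu_top + 15
  sc$population$sd_top <- sc$population$sd_top + 5
  modify_scenario(sc, ...)
}

modify_scenario <- function(sc, ...) {
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% names(sc$population)) sc$population[[nm]] <- ov[[nm]]
    else if (nm %in% names(sc$settings)) sc$settings[[nm]] <- ov[[nm]]
    else if (nm %in% c("noise_sd_frac", "auto_peep", "name")) sc[[nm]] <- ov[[nm]]
    else stop("unknown scenario field: ", nm)
  }
  class(sc) <- "rm_scenario"
  sc
}

#' Simulate a scenario
#'
#' Samples the unit population and runs [simulate_rm()]. The population and
#' the noise stream get distinct seeds derived from `seed` so that the two
#' sources of randomness are independent but jointly reproducible.
#'
#' @param scenario An `rm_scenario` (see [healthy_scenario()]).
#' @param seed Integer seed.
#' @return A `waveform_record` (see [simulate_rm()]).
#' @export
simulate_scenario <- function(scenario, seed = 1L) {
  p <- scenario$population
  pop <- sample_unit_population(p$n_units, p$mu_top, p$sd_top,
                                p$mu_tcp, p$sd_tcp, p$unit_volume,
                                seed = seed)
  st <- do.call(ventilator_settings, scenario$settings)
  simulate_rm(pop, st, noise_sd_frac = scenario$noise_sd_frac,
              auto_peep = scenario$auto_peep,
              seed = (seed + 104729L) %% .Machine$integer.max)
}

#' Read / write a scenario as YAML
#'
#' @param scenario An `rm_scenario`.
#' @param path File path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns an `rm_scenario`.
#' @export
write_scenario_yaml <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  sc <- yaml::read_yaml(path)
  needed <- c("population", "settings", "noise_sd_frac", "auto_peep")
  if (!all(needed %in% names(sc))) {
    stop("scenario YAML must have fields ", paste(needed, collapse = ", "))
  }
  class(sc) <- "rm_scenario"
  sc
}
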