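# Shared fixtures: a reduced-size unit population and manoeuvre that keep
# the unit tests fast, plus a cached run of the full shipped scenarios for
# the acceptance-level checks.

small_population <- function(seed = 1, mu_top = 42, sd_top = 19,
                             mu_tcp = 18, sd_tcp = 12,
                             n_units = 20000, unit_volume = 0.05) {
  sample_unit_population(n_units, mu_top, sd_top, mu_tcp, sd_tcp,
                         unit_volume, seed = seed)
}

small_settings <- function(breaths_per_level = 6, ...) {
  ventilator_settings(breaths_per_level = breaths_per_level, ...)
}

sim_small <- function(noise = 0, seed = 1, pop = small_population(),
                      settings = small_settings(), auto_peep = 0) {
  simulate_rm(pop, settings, noise_sd_frac = noise, auto_peep = auto_peep,
              seed = seed)
}

# exact model curve sampled on a pressure grid (for fitting tests)
model_curve <- function(params, pmin, pmax, n = 50, limb = "inflation",
                        noise_frac = 0, seed = NULL) {
  p <- seq(pmin, pmax, length.out = n)
  v <- model_volume(p, params)
  if (noise_frac > 0) {
    set.seed(seed)
    v <- v * (1 + rnorm(n, 0, noise_frac))
  }
  if (limb == "deflation") {
    p <- rev(p)
    v <- rev(v)
  }
  pv_curve(limb, peep = pmin, pressure = p, volume = pmax(v, 0))
}

fixture_scenario <- function(name) {
  read_scenario_yaml(system.file("extdata",
                                 paste0("scenario_", name, ".yaml"),
                                 package = "lungrecruit", mustWork = TRUE))
}

# full shipped-scenario pipeline, cached across tests within a run
.pipeline_cache <- new.env(parent = emptyenv())
run_fixture_pipeline <- function(name) {
  if (!is.null(.pipeline_cache[[name]])) return(.pipeline_cache[[name]])
  sc <- fixture_scenario(name)
  rec <- simulate_scenario(sc, seed = sc$seed)
  breaths <- segment_breaths(rec)
  curves <- build_pv_curves(rec, breaths, resistance = sc$settings$resistance)
  fits <- fit_manoeuvre(curves, tlc_max = "auto")
  out <- list(scenario = sc, record = rec, breaths = breaths,
              curves = curves, fits = fits)
  .pipeline_cache[[name]] <- out
  out
}
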