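#!/usr/bin/env Rscript
# Segment the simulated waveforms into breaths, estimate the trapped volume
# of each PEEP increment, and build the stacked per-PEEP pressure-volume
# curves (quasi-static pressure: the known ventilator resistance is removed).

suppressPackageStartupMessages(library(lungrecruit))

resistance <- 0.02  # cmH2O.s/ml, the simulated ventilator's resistance

for (nm in c("healthy", "ards")) {
  rec <- read_waveform_csv(file.path("results", paste0("waveform_", nm, ".csv")))
  breaths <- segment_breaths(rec)
  tv <- trapped_volumes(rec, breaths)
  curves <- build_pv_curves(rec, breaths, resistance = resistance)
  write_pv_csv(curves, file.path("results", paste0("pv_", nm, ".csv")))
  utils::write.csv(breaths, file.path("results", paste0("breaths_", nm, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(as.list(tv),
                       file.path("results", paste0("trapped_", nm, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("%s: %d breaths at %s cmH2O; trapped volumes (%s) = %s ml\n",
              nm, nrow(breaths),
              paste(unique(breaths$peep_cmH2O), collapse = "/"),
              paste(names(tv), collapse = ", "),
              paste(round(tv, 1), collapse = ", ")))
}
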