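#!/usr/bin/env Rscript
# Fit the error-function recruitment model to every limb of both simulated
# manoeuvres and report the per-PEEP parameter estimates and fitting errors.

suppressPackageStartupMessages(library(lungrecruit))

all_fits <- list()
for (nm in c("healthy", "ards")) {
  pv <- utils::read.csv(file.path("results", paste0("pv_", nm, ".csv")))
  curves <- lapply(split(pv, interaction(pv$peep_cmH2O, pv$limb)), function(d) {
    pv_curve(d$limb[1], d$peep_cmH2O[1], d$pressure_cmH2O, d$volume_ml,
             offset = min(d$volume_ml))
  })
  fits <- fit_manoeuvre(unname(curves), tlc_max = "auto")
  fits$state <- nm
  all_fits[[nm]] <- fits
  infl <- fits[fits$limb == "inflation", ]
  cat(sprintf("%s: fitted mean TOP across PEEP %s -> %s cmH2O (max MAPE %.2f%%)\n",
              nm, paste(infl$peep_cmH2O, collapse = "/"),
              paste(round(infl$mean_cmH2O, 1), collapse = ", "),
              max(fits$mape_pct)))
}
out <- do.call(rbind, all_fits)
rownames(out) <- NULL
utils::write.csv(out, "results/fits.csv", row.names = FALSE)
cat("wrote results/fits.csv\n")
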