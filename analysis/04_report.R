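#!/usr/bin/env Rscript
# Summarise fitted parameters into the reference-style tables, compare
# healthy and injured states with the rank-sum test, and place subjects on
# the disease-state-grouping (DSG) plane.

suppressPackageStartupMessages(library(lungrecruit))

## Reference per-subject tables -> median [IQR] / average summaries ----------
ref <- reference_mean_fits()
summ <- summarize_fits(ref, value_col = "mean_cmH2O",
                       by = c("state", "limb", "peep_cmH2O"))
summ$rendered <- render_summary(summ)
utils::write.csv(summ, "results/summary_mean_top_tcp.csv", row.names = FALSE)

sdsum <- summarize_fits(reference_sd_fits(), value_col = "sd_cmH2O",
                        by = c("state", "limb"))
utils::write.csv(sdsum, "results/summary_sd.csv", row.names = FALSE)

cat("healthy mean TOP at PEEP 5:",
    summ$rendered[summ$state == "healthy" & summ$limb == "inflation" &
                    summ$peep_cmH2O == 5], "cmH2O\n")
cat("injured-state average TOP at PEEP 5:",
    round(summ$mean[summ$state == "ards" & summ$limb == "inflation" &
                      summ$peep_cmH2O == 5], 1), "cmH2O\n")

## Rank-sum comparison: healthy (n=9) vs injured (n=3) TOP per PEEP ----------
wtab <- do.call(rbind, lapply(c(5, 10, 15, 20), function(peep) {
  x <- ref$mean_cmH2O[ref$state == "healthy" & ref$limb == "inflation" &
                        ref$peep_cmH2O == peep]
  y <- ref$mean_cmH2O[ref$state == "ards" & ref$limb == "inflation" &
                        ref$peep_cmH2O == peep]
  w <- wilcoxon_rank_sum(x, y)
  data.frame(peep_cmH2O = peep, rank_sum = w$statistic,
             p_value = w$p_value, method = w$method)
}))
utils::write.csv(wtab, "results/wilcoxon_top_healthy_vs_ards.csv",
                 row.names = FALSE)
cat("rank-sum two-sided p (TOP, healthy vs injured) per PEEP:",
    paste(signif(wtab$p_value, 3), collapse = ", "), "\n")

## DSG points and trajectories for the three injured subjects ----------------
# Panel boundaries are analysis configuration (no universal values exist);
# chosen between the reference healthy and injured clusters.
thr_top <- 45
thr_sd <- 24
sdref <- reference_sd_fits()
traj <- list()
pts <- list()
for (subj in c(5, 6, 9)) {
  seq_pts <- do.call(rbind, lapply(seq_along(c("healthy", "ards")), function(k) {
    st <- c("healthy", "ards")[k]
    assign_dsg_panel(
      ref$mean_cmH2O[ref$subject == subj & ref$state == st &
                       ref$limb == "inflation" & ref$peep_cmH2O == 5],
      sdref$sd_cmH2O[sdref$subject == subj & sdref$state == st &
                       sdref$limb == "inflation"],
      thr_top, thr_sd, state_tag = st, order = k)
  }))
  seq_pts$subject <- subj
  pts[[as.character(subj)]] <- seq_pts
  tr <- track_dsg(seq_pts)
  tr$subject <- subj
  traj[[as.character(subj)]] <- tr
  cat(sprintf("subject %d: %s (panel %s) -> %s (panel %s): %s\n", subj,
              seq_pts$state_tag[1], seq_pts$panel[1],
              seq_pts$state_tag[2], seq_pts$panel[2], tr$label))
}
utils::write.csv(do.call(rbind, pts), "results/dsg_points.csv",
                 row.names = FALSE)
utils::write.csv(do.call(rbind, traj), "results/dsg_trajectories.csv",
                 row.names = FALSE)

## Static compliance of the simulated manoeuvres -----------------------------
for (nm in c("healthy", "ards")) {
  rec <- read_waveform_csv(file.path("results", paste0("waveform_", nm, ".csv")))
  breaths <- segment_breaths(rec)
  cs <- vapply(unique(breaths$peep_cmH2O), function(peep) {
    b <- breaths[breaths$peep_cmH2O == peep, ]
    b <- b[nrow(b), ]
    plateau <- rec$paw_cmH2O[b$insp_end] -
      0.02 * rec$flow_ml_s[b$insp_end]   # remove the resistive component
    compute_static_compliance(b$inspired_ml, plateau, peep)
  }, numeric(1))
  cat(sprintf("%s static compliance across PEEP: %s ml/cmH2O\n", nm,
              paste(round(cs, 1), collapse = ", ")))
  utils::write.csv(data.frame(peep_cmH2O = unique(breaths$peep_cmH2O),
                              static_compliance_ml_cmH2O = cs),
                   file.path("results", paste0("compliance_", nm, ".csv")),
                   row.names = FALSE)
}
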