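# Bundled per-subject reference estimates from a step-wise PEEP recruitment
# study in piglets (nine healthy subjects; three of them re-studied after
# oleic-acid lung injury). These printed per-subject values feed the
# summary-statistics stage and serve as inputs for the disease-state
# trajectories.

ref_path <- function(file) {
  system.file("extdata", file, package = "lungrecruit", mustWork = TRUE)
}

#' Reference per-subject mean TOP/TCP estimates
#'
#' Per-subject model-based mean threshold opening and closing pressures at
#' PEEP 5/10/15/20 cmH2O, for nine healthy piglets and for the three that
#' later developed ARDS, in long format.
#'
#' @return A data frame with columns `subject`, `state`
#'   ("healthy"/"ards"), `peep_cmH2O`, `limb`
#'   ("inflation" for TOP, "deflation" for TCP), `parameter`
#'   ("TOP"/"TCP"), `mean_cmH2O`.
#' @export
reference_mean_fits <- function() {
  load_one <- function(file, state) {
    wide <- utils::read.csv(ref_path(file))
    long <- rbind(
      data.frame(subject = wide$subject, state = state,
                 peep_cmH2O = wide$peep_cmH2O, limb = "inflation",
                 parameter = "TOP", mean_cmH2O = wide$top_cmH2O),
      data.frame(subject = wide$subject, state = state,
                 peep_cmH2O = wide$peep_cmH2O, limb = "deflation",
                 parameter = "TCP", mean_cmH2O = wide$tcp_cmH2O))
    long
  }
  out <- rbind(load_one("reference_healthy_top_tcp.csv", "healthy"),
               load_one("reference_ards_top_tcp.csv", "ards"))
  out[order(out$state, out$limb, out$peep_cmH2O, out$subject), ]
}

#' Reference per-subject SD estimates
#'
#' SD of the fitted TOP (inflation) and TCP (deflation) distributions for
#' the three subjects studied in both the healthy and the ARDS state.
#'
#' @return A data frame with columns `subject`, `state`, `limb`,
#'   `sd_cmH2O`.
#' @export
reference_sd_fits <- function() {
  utils::read.csv(ref_path("reference_sd.csv"))
}
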