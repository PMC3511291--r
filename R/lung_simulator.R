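#' Ventilator settings for a step-wise PEEP recruitment manoeuvre
#'
#' Volume-controlled ventilation settings. Defaults describe the manoeuvre
#' analysed throughout this package: Vt = 12 ml/kg, PEEP stepped
#' 5 -> 10 -> 15 -> 20 cmH2O with 12 breaths per level.
#'
#' @param weight_kg Body mass, kg.
#' @param vt_ml_per_kg Tidal volume scale, ml/kg.
#' @param peep_schedule Ordered PEEP levels for the manoeuvre, cmH2O; must be
#'   strictly increasing.
#' @param breaths_per_level Breaths held at each PEEP level.
#' @param resp_rate Respiratory rate, breaths/min. Inspiration occupies one
#'   third of the breath period (I:E = 1:2).
#' @param sample_rate Sampling rate of the recorded waveforms, Hz (>= 25).
#' @param resistance Airway resistance, cmH2O.s/ml. Sets the resistive
#'   pressure drop and (with a compliance proxy) the expiratory time constant.
#' @param fio2 Inspired oxygen fraction (metadata only; no gas exchange is
#'   modelled).
#' @return An object of class `ventilator_settings`.
#' @export
ventilator_settings <- function(weight_kg = 24, vt_ml_per_kg = 12,
                                peep_schedule = c(5, 10, 15, 20),
                                breaths_per_level = 12, resp_rate = 15,
                                sample_rate = 50, resistance = 0.02,
                                fio2 = 0.5) {
  if (length(peep_schedule) < 1L) stop("peep_schedule must contain at least one PEEP level")
  if (length(peep_schedule) > 1L && any(diff(peep_schedule) <= 0)) {
    stop("peep_schedule must be strictly increasing")
  }
  if (weight_kg <= 0 || vt_ml_per_kg <= 0) stop("weight_kg and vt_ml_per_kg must be > 0")
  if (breaths_per_level < 1L) stop("breaths_per_level must be >= 1")
  if (resp_rate <= 0) stop("resp_rate must be > 0")
  if (sample_rate < 25) stop("sample_rate must be at least 25 Hz")
  if (resistance < 0) stop("resistance must be >= 0")
  structure(list(weight_kg = weight_kg, vt_ml_per_kg = vt_ml_per_kg,
                 peep_schedule = peep_schedule,
                 breaths_per_level = as.integer(breaths_per_level),
                 resp_rate = resp_rate, sample_rate = sample_rate,
                 resistance = resistance, fio2 = fio2),
            class = "ventilator_settings")
}

#' Sample a population of recruitable lung units
#'
#' Draws per-unit threshold opening pressures (TOP) and threshold closing
#' pressures (TCP) from independent normal distributions, re-drawing the TCP
#' of any unit that violates the hysteresis constraint TCP < TOP (done in
#' closed form by inverse-CDF sampling from the normal truncated above at the
#' unit's TOP, the limit of iterated re-drawing). Re-drawing only the TCP
#' keeps the TOP marginal exactly Normal(mu_top, sd_top), which the
#' Monte-Carlo oracle for the recruitment curve relies on. Every unit
#' contributes a fixed `unit_volume` when open; total capacity is
#' `n_units * unit_volume`. All units start closed.
#'
#' @param n_units Number of lung units (>= 1).
#' @param mu_top,sd_top Mean and SD of the TOP distribution, cmH2O (sd > 0).
#' @param mu_tcp,sd_tcp Mean and SD of the TCP distribution, cmH2O (sd > 0).
#' @param unit_volume Volume contributed by one open unit, ml (> 0).
#' @param seed Integer seed; identical seeds give bit-identical populations.
#' @return An object of class `lung_unit_population` with fields `n_units`,
#'   `top`, `tcp`, `unit_volume`, `is_open`, and the generating parameters.
#' @examples
#' pop <- sample_unit_population(1000, 42, 19, 18, 6, unit_volume = 1, seed = 1)
#' mean(pop$top)
#' @export
sample_unit_population <- function(n_units, mu_top, sd_top, mu_tcp, sd_tcp,
                                   unit_volume, seed) {
  if (n_units < 1L) stop("n_units must be >= 1")
  if (sd_top <= 0 || sd_tcp <= 0) stop("sd_top and sd_tcp must be > 0")
  if (unit_volume <= 0) stop("unit_volume must be > 0")
  if (missing(seed)) stop("seed must be supplied (reproducibility contract)")
  joint_sd <- sqrt(sd_top^2 + sd_tcp^2)
  if (mu_tcp - mu_top > 2 * joint_sd) {
    stop("configuration error: mu_tcp exceeds mu_top by more than 2 joint SDs; ",
         "the tcp < top rejection loop would not terminate quickly")
  }
  set.seed(as.integer(seed))
  top <- stats::rnorm(n_units, mu_top, sd_top)
  tcp <- stats::rnorm(n_units, mu_tcp, sd_tcp)
  bad <- which(tcp >= top)
  if (length(bad) > 0L) {
    # tcp | tcp < top: inverse-CDF draw from the truncated normal
    ub <- stats::pnorm(top[bad], mu_tcp, sd_tcp)
    u <- stats::runif(length(bad)) * pmax(ub, 1e-300)
    tcp[bad] <- stats::qnorm(pmax(u, 1e-300), mu_tcp, sd_tcp)
    tcp[bad] <- pmin(tcp[bad], top[bad] - 1e-9)
  }
  structure(list(n_units = as.integer(n_units), top = top, tcp = tcp,
                 unit_volume = unit_volume,
                 is_open = logical(n_units),
                 mu_top = mu_top, sd_top = sd_top,
                 mu_tcp = mu_tcp, sd_tcp = sd_tcp),
            class = "lung_unit_population")
}

#' @export
print.lung_unit_population <- function(x, ...) {
  cat(sprintf(paste0("Lung unit population: %d units x %.3g ml ",
                     "(capacity %.0f ml)\n  TOP ~ N(%.1f, %.1f), TCP ~ N(%.1f, %.1f) cmH2O\n"),
              x$n_units, x$unit_volume, x$n_units * x$unit_volume,
              x$mu_top, x$sd_top, x$mu_tcp, x$sd_tcp))
  invisible(x)
}

# cumulative trapezoidal integral on a uniform grid, anchored at 0
cumtrapz_uniform <- function(f, dt) {
  n <- length(f)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((f[-n] + f[-1]) / 2 * dt))
}

#' Simulate a step-wise PEEP recruitment manoeuvre
#'
#' Volume-controlled simulation of the hysteretic unit population. Each
#' inspiration delivers Vt at constant flow; the alveolar pressure at each
#' sample is the smallest pressure at which the population holds the current
#' delivered volume (closed units open when pressure reaches their TOP;
#' open units close when pressure falls to their TCP, retaining state between
#' samples). Airway pressure is alveolar pressure plus `resistance * flow`.
#' Expiration is passive single-exponential flow decay towards the volume
#' held by units whose TCP lies below the current PEEP, terminated when flow
#' falls under 1% of peak expiratory flow; units with TCP below PEEP stay
#' open, producing the trapped end-expiratory volume rise after each PEEP
#' step. Multiplicative Gaussian noise of relative SD `noise_sd_frac` is
#' applied to the pressure and flow channels; the volume channel is the
#' trapezoidal integral of the recorded flow.
#'
#' Ground truth for testing is attached as `attr(record, "truth")`: the
#' end-expiratory volume above the pre-manoeuvre relaxed state at the end of
#' each PEEP level (`eev_per_level`) and its increments (`trapped_per_step`).
#'
#' @param population A [sample_unit_population()] object.
#' @param settings A [ventilator_settings()] object.
#' @param noise_sd_frac Relative SD of the multiplicative measurement noise
#'   (default 0.02); 0 for noise-free records.
#' @param auto_peep Additive intrinsic end-expiratory pressure offset, cmH2O
#'   (default 0). Expiration terminates at PEEP + auto_peep.
#' @param seed Integer seed for the measurement noise.
#' @return A data frame of class `waveform_record` with columns `time_s`,
#'   `paw_cmH2O`, `flow_ml_s`, `volume_ml`, `peep_cmH2O`, plus `truth` and
#'   `settings` attributes.
#' @export
simulate_rm <- function(population, settings, noise_sd_frac = 0.02,
                        auto_peep = 0, seed = 1L) {
  if (!inherits(population, "lung_unit_population")) {
    stop("population must be a lung_unit_population")
  }
  if (!inherits(settings, "ventilator_settings")) {
    stop("settings must be a ventilator_settings object")
  }
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  uv <- population$unit_volume
  top <- population$top
  tcp <- population$tcp
  capacity <- population$n_units * uv
  vt <- settings$weight_kg * settings$vt_ml_per_kg
  if (vt >= capacity) {
    stop("infeasible ventilation: tidal volume (", vt,
         " ml) is not below total capacity (", capacity, " ml)")
  }

  dt <- 1 / settings$sample_rate
  n_per_breath <- max(6L, round(60 / settings$resp_rate / dt))
  n_insp <- max(2L, round(n_per_breath / 3))
  n_exp <- n_per_breath - n_insp
  flow_insp <- vt / (n_insp * dt)

  schedule <- settings$peep_schedule
  n_levels <- length(schedule)
  n_breaths <- settings$breaths_per_level
  n_total <- n_levels * n_breaths * n_per_breath

  # pre-manoeuvre relaxed state: fully collapsed (all units closed), so the
  # volume channel is the absolute recruited volume; units with TOP at or
  # below PEEP open during the first inspirations, through recorded flow
  open <- logical(population$n_units)
  baseline_volume <- 0

  palv <- numeric(n_total)
  flow <- numeric(n_total)
  peep_ann <- numeric(n_total)
  eev_levels <- numeric(n_levels)
  eev_breaths <- numeric(n_levels * n_breaths)

  k <- 0L
  last_flow <- 0
  v_chan <- 0   # trapezoidal volume channel value at the last written sample
  bi <- 0L
  for (li in seq_len(n_levels)) {
    eff_peep <- schedule[li] + auto_peep
    for (b in seq_len(n_breaths)) {
      ## ---- inspiration: constant flow -------------------------------
      v0_state <- sum(open) * uv
      closed_idx <- which(!open)
      ord <- closed_idx[order(top[closed_idx])]
      ct <- top[ord]
      f_seg <- rep(flow_insp, n_insp)
      # trapezoidal volume including the junction with the previous sample
      incr <- (c(last_flow, f_seg[-n_insp]) + f_seg) / 2 * dt
      v_seg <- v_chan + cumsum(incr)            # channel volume, ml above baseline
      v_abs <- baseline_volume + v_seg          # absolute open-unit volume target
      m <- pmax(0L, ceiling((v_abs - v0_state) / uv - 1e-9))
      if (m[n_insp] > length(ct)) {
        stop("infeasible ventilation: delivered volume exceeds the volume ",
             "the unit population can hold (all units open)")
      }
      pal <- ifelse(m == 0L, eff_peep, ct[pmax(m, 1L)])
      pal <- pmax(pal, eff_peep)
      idx <- k + seq_len(n_insp)
      palv[idx] <- pal
      flow[idx] <- f_seg
      peep_ann[idx] <- schedule[li]
      k <- k + n_insp
      m_final <- m[n_insp]
      if (m_final > 0L) open[ord[seq_len(m_final)]] <- TRUE
      plateau <- pal[n_insp]
      last_flow <- flow_insp
      v_chan <- v_seg[n_insp]
      v_ei_abs <- baseline_volume + v_chan

      ## ---- expiration: passive exponential decay --------------------
      closable <- which(open & tcp >= eff_peep)
      ctc <- sort(tcp[closable], decreasing = TRUE)
      n_open_ei <- sum(open)
      v_eq <- (n_open_ei - length(closable)) * uv
      # expiratory time constant = R x compliance proxy, floored at a
      # physiologic 0.3 s (expiratory valve + tubing slow real expiration)
      compliance_proxy <- vt / max(plateau - eff_peep, 0.5)
      tau <- max(settings$resistance * compliance_proxy, 0.3)
      te <- dt * seq_len(n_exp)
      amp <- max(v_ei_abs - v_eq, 0)
      f_exp <- -(amp / tau) * exp(-te / tau)
      if (amp > 0) {
        cut <- which(abs(f_exp) < 0.01 * abs(f_exp[1]))
        if (length(cut) > 0L) f_exp[cut[1]:n_exp] <- 0
      } else {
        f_exp[] <- 0
      }
      incr <- (c(last_flow, f_exp[-n_exp]) + f_exp) / 2 * dt
      v_seg <- v_chan + cumsum(incr)
      v_abs <- baseline_volume + v_seg
      c_cnt <- pmin(length(ctc),
                    pmax(0L, floor((n_open_ei * uv - v_abs) / uv + 1e-9)))
      if (length(ctc) > 0L) {
        nxt <- pmin(c_cnt + 1L, length(ctc))
        pal_e <- ifelse(c_cnt >= length(ctc), eff_peep,
                        pmax(eff_peep, ctc[nxt]))
      } else {
        pal_e <- rep(eff_peep, n_exp)
      }
      idx <- k + seq_len(n_exp)
      palv[idx] <- pal_e
      flow[idx] <- f_exp
      peep_ann[idx] <- schedule[li]
      k <- k + n_exp
      c_final <- c_cnt[n_exp]
      if (c_final > 0L) {
        close_idx <- closable[order(tcp[closable], decreasing = TRUE)[seq_len(c_final)]]
        open[close_idx] <- FALSE
      }
      last_flow <- f_exp[n_exp]
      v_chan <- v_seg[n_exp]
      bi <- bi + 1L
      eev_breaths[bi] <- sum(open) * uv - baseline_volume
    }
    eev_levels[li] <- sum(open) * uv - baseline_volume
  }

  time <- dt * (seq_len(n_total) - 1)
  paw <- palv + settings$resistance * flow
  if (noise_sd_frac > 0) {
    set.seed(as.integer(seed))
    paw <- paw * (1 + stats::rnorm(n_total, 0, noise_sd_frac))
    flow <- flow * (1 + stats::rnorm(n_total, 0, noise_sd_frac))
  }
  volume <- cumtrapz_uniform(flow, dt)

  record <- data.frame(time_s = time, paw_cmH2O = paw, flow_ml_s = flow,
                       volume_ml = volume, peep_cmH2O = peep_ann)
  class(record) <- c("waveform_record", "data.frame")
  attr(record, "truth") <- list(
    eev_per_level = eev_levels,
    trapped_per_step = if (n_levels > 1L) diff(eev_levels) else numeric(0),
    eev_per_breath = eev_breaths,
    vt = vt, capacity = capacity, baseline_volume = baseline_volume,
    mu_top = population$mu_top, sd_top = population$sd_top,
    mu_tcp = population$mu_tcp, sd_tcp = population$sd_tcp)
  attr(record, "settings") <- settings
  record
}

#' Quasi-static inflation curve of a unit population
#'
#' Monotone slow inflation from the fully collapsed state: at each pressure
#' the open volume is `unit_volume` times the number of units with TOP at or
#' below that pressure. For large populations this converges to the
#' error-function model of the generating TOP distribution.
#'
#' @param population A [sample_unit_population()] object.
#' @param pressures Monotone increasing pressures, cmH2O.
#' @return A data frame with columns `pressure` and `volume`.
#' @export
quasi_static_inflation <- function(population, pressures) {
  if (!inherits(population, "lung_unit_population")) {
    stop("population must be a lung_unit_population")
  }
  if (is.unsorted(pressures)) stop("pressures must be monotone increasing")
  st <- sort(population$top)
  counts <- findInterval(pressures, st)
  data.frame(pressure = pressures, volume = counts * population$unit_volume)
}

#' Write / read manoeuvre waveforms as CSV
#'
#' The CSV dialect has header
#' `time_s,paw_cmH2O,flow_ml_s,volume_ml,peep_cmH2O`, one row per sample,
#' '.' decimal, UTF-8.
#'
#' @param record A `waveform_record` data frame.
#' @param path File path.
#' @return `write_waveform_csv` returns `path` invisibly;
#'   `read_waveform_csv` returns a `waveform_record` data frame.
#' @export
write_waveform_csv <- function(record, path) {
  utils::write.csv(as.data.frame(record)[, c("time_s", "paw_cmH2O",
                                             "flow_ml_s", "volume_ml",
                                             "peep_cmH2O")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  record <- utils::read.csv(path)
  needed <- c("time_s", "paw_cmH2O", "flow_ml_s", "volume_ml", "peep_cmH2O")
  if (!all(needed %in% names(record))) {
    stop("waveform CSV must have columns ", paste(needed, collapse = ", "))
  }
  class(record) <- c("waveform_record", "data.frame")
  record
}
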