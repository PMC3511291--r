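# Breath segmentation, representative breaths, trapped-volume estimation and
# per-PEEP pressure-volume curve construction.

trapz_uniform <- function(f, dt) {
  n <- length(f)
  if (n < 2L) return(0)
  sum((f[-n] + f[-1]) / 2) * dt
}

record_dt <- function(record) {
  if (nrow(record) < 2L) stop("record must contain at least 2 samples")
  dts <- diff(record$time_s)
  if (any(abs(dts - dts[1]) > 1e-6 * dts[1])) {
    stop("record must be uniformly sampled")
  }
  dts[1]
}

#' Segment a manoeuvre record into breaths
#'
#' Breaths are delimited by inspiratory flow onsets: samples where flow rises
#' through `flow_threshold_frac * max(|flow|)` after having fallen below
#' `offset_frac * max(|flow|)` (hysteresis, so noise cannot re-trigger within
#' a breath). Each breath is labelled with the PEEP annotation at its onset;
#' inspired and expired volumes are trapezoidal integrals of the positive and
#' negative flow over the breath.
#'
#' @param record A `waveform_record` data frame (uniform sampling).
#' @param flow_threshold_frac Onset threshold as a fraction of peak absolute
#'   flow (default 0.05).
#' @param offset_frac Re-arming threshold as a fraction of peak absolute flow
#'   (default 0.01).
#' @return A data frame with one row per breath: `insp_start`, `insp_end`,
#'   `exp_end` (sample indices), `peep_cmH2O`, `inspired_ml`, `expired_ml`.
#' @export
segment_breaths <- function(record, flow_threshold_frac = 0.05,
                            offset_frac = 0.01) {
  if (is.null(record) || nrow(record) == 0L) stop("record is empty")
  dt <- record_dt(record)
  f <- record$flow_ml_s
  peak <- max(abs(f))
  if (peak <= 0) stop("no breaths detected: record contains no flow")
  thr_on <- flow_threshold_frac * peak
  thr_off <- offset_frac * peak

  crossings <- which(f >= thr_on & c(-Inf, f[-length(f)]) < thr_on)
  if (length(crossings) == 0L) stop("no breaths detected")
  onsets <- integer(0)
  armed_from <- 1L
  for (cx in crossings) {
    seg <- if (length(onsets) == 0L) f[seq_len(cx - 1L)] else
      f[seq(onsets[length(onsets)], cx - 1L)]
    if (length(onsets) == 0L || any(seg <= thr_off)) {
      onsets <- c(onsets, cx)
    }
  }
  if (length(onsets) == 0L) stop("no breaths detected")

  n <- length(f)
  breaths <- lapply(seq_along(onsets), function(i) {
    s <- onsets[i]
    e_next <- if (i < length(onsets)) onsets[i + 1L] - 1L else n
    seg <- f[s:e_next]
    below <- which(seg <= 0)
    insp_end <- if (length(below) > 0L) s + below[1L] - 2L else e_next
    insp_end <- max(insp_end, s + 1L)
    # integration window starts one sample before the onset so the onset
    # ramp is counted and consecutive windows tile the record exactly
    wseg <- f[max(s - 1L, 1L):e_next]
    data.frame(insp_start = s, insp_end = insp_end, exp_end = e_next,
               peep_cmH2O = record$peep_cmH2O[s],
               inspired_ml = trapz_uniform(pmax(wseg, 0), dt),
               expired_ml = -trapz_uniform(pmin(wseg, 0), dt))
  })
  out <- do.call(rbind, breaths)
  rownames(out) <- NULL
  out
}

resample_phase <- function(x, n_phase) {
  if (length(x) == 1L) return(rep(x, n_phase))
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n_phase))$y
}

breath_traces <- function(record, breath, n_phase) {
  si <- breath$insp_start:breath$insp_end
  se <- breath$insp_end:breath$exp_end
  v0 <- record$volume_ml[breath$insp_start]
  list(paw_insp = resample_phase(record$paw_cmH2O[si], n_phase),
       flow_insp = resample_phase(record$flow_ml_s[si], n_phase),
       vol_insp = resample_phase(record$volume_ml[si] - v0, n_phase),
       paw_exp = resample_phase(record$paw_cmH2O[se], n_phase),
       flow_exp = resample_phase(record$flow_ml_s[se], n_phase),
       vol_exp = resample_phase(record$volume_ml[se] - v0, n_phase))
}

#' Representative breath at one PEEP level
#'
#' The representative breath is built from the last two breaths at the level:
#' either their pointwise mean after resampling both to a common phase grid
#' (`method = "mean"`, robust to noise) or simply the last breath
#' (`method = "last"`). If only one breath exists it is returned with a
#' warning flag. Volumes are relative to the breath's own onset
#' (end-expiratory state).
#'
#' @param breaths Breath table from [segment_breaths()], already restricted
#'   to one PEEP level (or not: the level is selected with `peep`).
#' @param record The `waveform_record` the breaths index into.
#' @param peep PEEP level to select; default: the single level present.
#' @param method `"mean"` (default) or `"last"`.
#' @param n_phase Number of resampled phase points per limb (default 200).
#' @return A list of class `rep_breath` with resampled `paw`/`flow`/`vol`
#'   traces for each limb, the level, inspired/expired volumes and a
#'   `single_breath` warning flag.
#' @export
select_representative_breath <- function(breaths, record, peep = NULL,
                                         method = c("mean", "last"),
                                         n_phase = 200L) {
  method <- match.arg(method)
  if (is.null(peep)) {
    lv <- unique(breaths$peep_cmH2O)
    if (length(lv) != 1L) stop("breaths span several PEEP levels; give `peep`")
    peep <- lv
  }
  bl <- breaths[breaths$peep_cmH2O == peep, , drop = FALSE]
  if (nrow(bl) == 0L) stop("missing level: no breaths at PEEP ", peep)
  single <- nrow(bl) == 1L
  if (single) {
    warning("only one breath at PEEP ", peep, "; representative = that breath")
    use <- bl
  } else if (method == "last") {
    use <- bl[nrow(bl), , drop = FALSE]
  } else {
    use <- bl[(nrow(bl) - 1L):nrow(bl), , drop = FALSE]
  }
  traces <- lapply(seq_len(nrow(use)), function(i) {
    breath_traces(record, use[i, ], n_phase)
  })
  avg <- function(field) {
    Reduce(`+`, lapply(traces, `[[`, field)) / length(traces)
  }
  structure(list(peep_cmH2O = peep,
                 paw_insp = avg("paw_insp"), flow_insp = avg("flow_insp"),
                 vol_insp = avg("vol_insp"),
                 paw_exp = avg("paw_exp"), flow_exp = avg("flow_exp"),
                 vol_exp = avg("vol_exp"),
                 inspired_ml = mean(use$inspired_ml),
                 expired_ml = mean(use$expired_ml),
                 single_breath = single),
            class = "rep_breath")
}

#' Estimate the trapped volume over a PEEP increment
#'
#' The trapped (recruitment) volume for a PEEP increment is the estimated
#' end-expiratory lung-volume gain: the sum over the transition breaths of
#' inspired minus expired volume. Small negative estimates (measurement
#' noise) are clamped to 0 with a warning, since end-expiratory volume cannot
#' fall at a PEEP increase under this protocol.
#'
#' @param record The `waveform_record` (unused beyond validation; the breath
#'   table already carries the integrated volumes).
#' @param transition_breaths Breath-table rows spanning one PEEP increment
#'   (by default all breaths at the incoming level, over which per-breath
#'   net gains telescope to the full end-expiratory change).
#' @return Trapped volume in ml (>= 0).
#' @export
estimate_trapped_volume <- function(record, transition_breaths) {
  if (is.null(transition_breaths) || nrow(transition_breaths) == 0L) {
    stop("transition breath set is empty")
  }
  est <- sum(transition_breaths$inspired_ml - transition_breaths$expired_ml)
  if (est < 0) {
    warning(sprintf("negative trapped-volume estimate (%.2f ml) clamped to 0", est))
    est <- 0
  }
  est
}

#' Per-increment trapped volumes for a whole manoeuvre
#'
#' Applies [estimate_trapped_volume()] to each PEEP increment, using all
#' breaths at the incoming level as the transition window. With
#' `include_washin = TRUE` (default) the net volume retained during the
#' first level is reported as the initial `0->PEEP1` increment: when the
#' record starts from the relaxed (collapsed) state this is the wash-in
#' recruitment at baseline PEEP, and when the record starts at a ventilatory
#' steady state it is close to zero, recovering the convention that the
#' first level carries no offset.
#'
#' @param record A `waveform_record`.
#' @param breaths Breath table from [segment_breaths()].
#' @param include_washin Report the first level's net gain as a `0->PEEP1`
#'   increment (default TRUE).
#' @return Named numeric vector, one entry per increment
#'   (names like `"5->10"`).
#' @export
trapped_volumes <- function(record, breaths, include_washin = TRUE) {
  levels <- unique(breaths$peep_cmH2O)
  idx <- if (include_washin) seq_along(levels) else seq_along(levels)[-1L]
  if (length(idx) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  out <- vapply(idx, function(j) {
    tb <- breaths[breaths$peep_cmH2O == levels[j], , drop = FALSE]
    estimate_trapped_volume(record, tb)
  }, numeric(1))
  from <- ifelse(idx == 1L, 0, levels[pmax(idx - 1L, 1L)])
  names(out) <- paste0(from, "->", levels[idx])
  out
}

#' Pressure-volume curve for one limb at one PEEP level
#'
#' @param limb `"inflation"` or `"deflation"`.
#' @param peep PEEP level, cmH2O.
#' @param pressure,volume Ordered samples; pressure must be strictly monotone
#'   (increasing for inflation, decreasing for deflation), volume
#'   non-negative; at least 3 points.
#' @param offset Cumulative trapped-volume offset already included in
#'   `volume`, ml.
#' @return An object of class `pv_curve`.
#' @export
pv_curve <- function(limb = c("inflation", "deflation"), peep, pressure,
                     volume, offset = 0) {
  limb <- match.arg(limb)
  if (length(pressure) != length(volume)) stop("pressure/volume length mismatch")
  if (length(pressure) < 3L) stop("a PV curve needs at least 3 points")
  d <- diff(pressure)
  if (limb == "inflation" && any(d <= 0)) {
    stop("inflation limb pressure must be strictly increasing")
  }
  if (limb == "deflation" && any(d >= 0)) {
    stop("deflation limb pressure must be strictly decreasing")
  }
  if (any(volume < -1e-9)) stop("volume must be non-negative")
  structure(list(limb = limb, peep = peep, pressure = pressure,
                 volume = pmax(volume, 0), offset = offset),
            class = "pv_curve")
}

#' @export
print.pv_curve <- function(x, ...) {
  cat(sprintf("PV curve (%s limb, PEEP %g cmH2O): %d points, offset %.1f ml\n",
              x$limb, x$peep, length(x$pressure), x$offset))
  invisible(x)
}

# collapse duplicate pressures (averaging volume) and enforce monotonicity
monotone_pv <- function(pressure, volume, decreasing = FALSE) {
  o <- order(pressure, decreasing = decreasing)
  p <- pressure[o]; v <- volume[o]
  key <- cumsum(c(TRUE, abs(diff(p)) > 1e-9))
  p <- tapply(p, key, mean)
  v <- tapply(v, key, mean)
  list(pressure = as.numeric(p), volume = as.numeric(v))
}

#' Build per-PEEP pressure-volume curves
#'
#' For each PEEP level, the representative breath is split into an inflation
#' limb (inspiration samples) and a deflation limb (expiration samples). The
#' volume axis of each curve is offset by the running sum of the trapped
#' volumes of all preceding PEEP increments (optionally including the
#' first-level wash-in as the `0->PEEP1` increment, see
#' [trapped_volumes()]), so curves stack with PEEP. When
#' a `resistance` estimate is given, the resistive component
#' `resistance * flow` is removed from the recorded airway pressure before
#' curve construction (quasi-static correction); by default raw airway
#' pressure is used, matching fits to recorded pressure.
#'
#' @param record A `waveform_record`.
#' @param breaths Breath table from [segment_breaths()].
#' @param resistance Optional airway resistance (cmH2O.s/ml) for the
#'   resistive-pressure correction; `NULL` (default) fits raw pressure.
#' @param representative `"mean"` (default) or `"last"`; see
#'   [select_representative_breath()].
#' @param include_washin Passed to [trapped_volumes()] (default TRUE).
#' @param n_phase Phase points per limb.
#' @return A list of `pv_curve` objects ordered by PEEP then limb
#'   (inflation, deflation), with the per-increment trapped volumes attached
#'   as `attr(, "trapped")`.
#' @export
build_pv_curves <- function(record, breaths, resistance = NULL,
                            representative = c("mean", "last"),
                            include_washin = TRUE, n_phase = 200L) {
  representative <- match.arg(representative)
  levels <- unique(breaths$peep_cmH2O)
  trapped <- trapped_volumes(record, breaths, include_washin = include_washin)
  offsets <- if (include_washin) cumsum(trapped) else c(0, cumsum(trapped))
  curves <- list()
  for (j in seq_along(levels)) {
    rb <- select_representative_breath(breaths, record, peep = levels[j],
                                       method = representative,
                                       n_phase = n_phase)
    p_insp <- rb$paw_insp
    p_exp <- rb$paw_exp
    if (!is.null(resistance)) {
      p_insp <- p_insp - resistance * rb$flow_insp
      p_exp <- p_exp - resistance * rb$flow_exp
    }
    # end-expiratory samples can dip a few ml below the breath-onset
    # reference (integration smear, noise); clamp at the curve floor
    infl <- monotone_pv(p_insp, pmax(rb$vol_insp, 0) + offsets[j],
                        decreasing = FALSE)
    defl <- monotone_pv(p_exp, pmax(rb$vol_exp, 0) + offsets[j],
                        decreasing = TRUE)
    curves[[length(curves) + 1L]] <-
      pv_curve("inflation", levels[j], infl$pressure, infl$volume, offsets[j])
    curves[[length(curves) + 1L]] <-
      pv_curve("deflation", levels[j], defl$pressure, defl$volume, offsets[j])
  }
  attr(curves, "trapped") <- trapped
  curves
}

#' Write PV curves as CSV
#'
#' Columns `limb,peep_cmH2O,pressure_cmH2O,volume_ml`, all curves stacked.
#'
#' @param curves List of `pv_curve` objects.
#' @param path Output file.
#' @export
write_pv_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(limb = cv$limb, peep_cmH2O = cv$peep,
               pressure_cmH2O = cv$pressure, volume_ml = cv$volume)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
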