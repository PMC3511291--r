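# Nonlinear least-squares estimation of (mean, sd, tlc) per limb per PEEP
# level, with the mean-absolute-percentage fitting error used to report
# model performance.

fit_residuals <- function(par, pressure, volume, weights) {
  (par[3] * stats::pnorm(pressure, par[1], par[2]) - volume) * weights
}

fit_cost <- function(par, pressure, volume, weights) {
  sum(fit_residuals(par, pressure, volume, weights)^2)
}

fit_weights <- function(volume, weighting) {
  if (weighting == "none") return(rep(1, length(volume)))
  # multiplicative measurement noise: residuals are relative, floored at
  # the same 1%-of-max level the MAPE guard uses
  1 / pmax(volume, 0.01 * max(volume))
}

default_init <- function(pressure, volume) {
  o <- order(pressure)
  p <- pressure[o]; v <- volume[o]
  slope <- diff(v) / diff(p)
  mean0 <- p[which.max(slope)]
  span <- max(p) - min(p)
  recruit_params(mean = mean0, sd = max(span / 4, 1e-3),
                 tlc = 1.05 * max(v))
}

run_lm <- function(par0, lower, upper, pressure, volume, weights) {
  par0 <- pmin(pmax(par0, lower), upper)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = fit_residuals, pressure = pressure, volume = volume,
    weights = weights,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8,
                                         maxiter = 500))
  list(par = fit$par, cost = sum(fit$fvec^2), info = fit$info)
}

#' Fit the recruitment model to one PV limb
#'
#' Estimates (mean, sd, tlc) by bounded Levenberg-Marquardt least squares,
#' subject to sd > 0 and tlc >= max(v). The default objective minimises
#' relative residuals, \eqn{\sum_i ((V_{model}(p_i) - v_i)/v_i)^2} with the
#' denominator floored at 1% of the maximum volume: ventilator pressure and
#' flow noise is multiplicative, so residual spread scales with volume and
#' relative weighting is the matching least-squares criterion (and keeps the
#' low-volume tail, which carries most of the information about the
#' distribution location, from being ignored). `weighting = "none"` gives
#' plain unweighted least squares; both coincide on noise-free data.
#' Unless supplied, initialisation follows the convention:
#' mean = pressure of the maximum finite-difference slope dV/dP,
#' sd = pressure span / 4, tlc = 1.05 x max(v). A deterministic grid of
#' additional starting points (means up to two spans above the window, a
#' range of SDs, with tlc chosen so the model passes through the top of the
#' curve) guards against local minima on poorly spanned (tail-only) curves;
#' the lowest-cost solution is returned, so results are bit-reproducible.
#'
#' @param curve A [pv_curve()] (>= 3 points, monotone pressure).
#' @param init Optional [recruit_params()] initial guess.
#' @param bounds Optional list with elements `lower` and `upper`, each a
#'   length-3 numeric vector (mean, sd, tlc).
#' @param multi_start Use the deterministic multi-start grid (default TRUE).
#' @param weighting `"relative"` (default) or `"none"`; see Details.
#' @return A list of class `recruitment_fit`: `params` ([recruit_params()]),
#'   `limb`, `peep`, `mape` (%), `n_points`, `converged`,
#'   `poorly_identified` (pressure span < 1 fitted SD), `cost`, `init`.
#' @export
fit_limb <- function(curve, init = NULL, bounds = NULL, multi_start = TRUE,
                     weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  if (!inherits(curve, "pv_curve")) stop("curve must be a pv_curve")
  pressure <- curve$pressure
  volume <- curve$volume
  if (length(pressure) < 3L) stop("a PV curve needs at least 3 points")
  if (diff(range(volume)) < 1e-9 * max(abs(volume), 1)) {
    stop("unidentifiable curve: all volumes equal (sd unbounded)")
  }
  if (is.null(init)) init <- default_init(pressure, volume)
  stop_if_not_params(init)
  span <- max(pressure) - min(pressure)
  vmax <- max(volume)
  if (is.null(bounds)) {
    lower <- c(min(pressure) - 2 * span, 1e-3, vmax * (1 + 1e-9))
    upper <- c(max(pressure) + 3 * span, 10 * span, 100 * vmax)
  } else {
    lower <- bounds$lower
    upper <- bounds$upper
  }

  starts <- list(c(init$mean, init$sd, init$tlc))
  if (multi_start) {
    pmax_ <- max(pressure)
    for (m0 in pmax_ + span * c(0, 0.5, 1, 2)) {
      for (s0 in span * c(1 / 8, 1 / 4, 1 / 2, 1)) {
        frac <- stats::pnorm(pmax_, m0, s0)
        tlc0 <- if (frac > 1e-6) vmax / frac else upper[3]
        starts[[length(starts) + 1L]] <- c(m0, s0, tlc0)
      }
    }
  }
  weights <- fit_weights(volume, weighting)
  best <- NULL
  for (st in starts) {
    res <- tryCatch(run_lm(st, lower, upper, pressure, volume, weights),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$cost < best$cost)) best <- res
  }
  if (is.null(best)) {
    fit <- structure(list(params = init, limb = curve$limb, peep = curve$peep,
                          mape = NA_real_, n_points = length(pressure),
                          converged = FALSE, poorly_identified = TRUE,
                          cost = fit_cost(c(init$mean, init$sd, init$tlc),
                                          pressure, volume, weights),
                          init = init),
                     class = "recruitment_fit")
    return(fit)
  }
  params <- recruit_params(best$par[1], best$par[2], best$par[3])
  fit <- structure(list(params = params, limb = curve$limb, peep = curve$peep,
                        mape = NA_real_, n_points = length(pressure),
                        converged = best$info %in% 1:3,
                        poorly_identified = span < params$sd,
                        cost = best$cost, init = init),
                   class = "recruitment_fit")
  fit$mape <- compute_mape(fit, curve)
  fit
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cat(sprintf(paste0("Recruitment fit (%s limb, PEEP %g): mean = %.2f, ",
                     "sd = %.2f, tlc = %.1f; MAPE = %.2f%%%s\n"),
              x$limb, x$peep, x$params$mean, x$params$sd, x$params$tlc,
              x$mape, if (x$poorly_identified) " [poorly identified]" else ""))
  invisible(x)
}

#' Mean absolute percentage fitting error
#'
#' `(100/n) * sum(|V_model(p_i) - v_i| / v_i)` over the curve points,
#' excluding points whose measured volume is below 1% of the maximum volume
#' (a guard against division blow-up near zero volume).
#'
#' @param fit A `recruitment_fit` (or [recruit_params()]) giving the model.
#' @param curve The [pv_curve()] the error is evaluated on.
#' @return MAPE in percent.
#' @export
compute_mape <- function(fit, curve) {
  params <- if (inherits(fit, "recruitment_fit")) fit$params else fit
  stop_if_not_params(params)
  v <- curve$volume
  keep <- v > 0.01 * max(v)
  if (!any(keep)) stop("MAPE undefined: all points excluded by the 1%-of-max guard")
  pred <- model_volume(curve$pressure[keep], params)
  100 * mean(abs(pred - v[keep]) / v[keep])
}

#' Fit every limb of a manoeuvre
#'
#' One fit per (PEEP, limb). Inflation fits estimate the TOP distribution,
#' deflation fits the TCP distribution. Per-curve failures are caught and
#' reported as rows with `NA` parameters and the error message; other curves
#' are still fitted.
#'
#' @param curves List of [pv_curve()] objects (e.g. from
#'   [build_pv_curves()]).
#' @param tlc_max Optional upper bound on the fitted recruitable capacity
#'   shared across the manoeuvre: a number, or `"auto"` for 1.2 times the
#'   largest volume observed on any curve. This is an identifiability
#'   guard: on curves whose pressure window does not reach the upper
#'   shoulder of the recruitment curve, the (mean, sd, tlc) likelihood has a
#'   ridge along which all three parameters drift upward, and a recruitable
#'   capacity far beyond any volume the manoeuvre demonstrates is
#'   unsupported by the data. `NULL` (default) leaves the per-curve default
#'   bounds of [fit_limb()].
#' @param ... Passed on to [fit_limb()].
#' @return A data frame ordered by PEEP then limb with columns
#'   `peep_cmH2O`, `limb`, `parameter` ("TOP"/"TCP"), `mean_cmH2O`,
#'   `sd_cmH2O`, `tlc_ml`, `mape_pct`, `n_points`, `converged`,
#'   `poorly_identified`, `error`; the fit objects are attached as
#'   `attr(, "fits")`.
#' @export
fit_manoeuvre <- function(curves, tlc_max = NULL, ...) {
  if (length(curves) == 0L) stop("no curves supplied")
  limb_rank <- function(l) match(l, c("inflation", "deflation"))
  o <- order(vapply(curves, `[[`, numeric(1), "peep"),
             vapply(curves, function(cv) limb_rank(cv$limb), numeric(1)))
  curves <- curves[o]
  if (identical(tlc_max, "auto")) {
    tlc_max <- 1.2 * max(vapply(curves, function(cv) max(cv$volume),
                                numeric(1)))
  }
  curve_bounds <- function(cv) {
    if (is.null(tlc_max)) return(NULL)
    span <- diff(range(cv$pressure))
    vmax <- max(cv$volume)
    list(lower = c(min(cv$pressure) - 2 * span, 1e-3, vmax * (1 + 1e-9)),
         upper = c(max(cv$pressure) + 3 * span, 10 * span,
                   max(tlc_max, vmax * (1 + 1e-6))))
  }
  rows <- list()
  fits <- list()
  for (cv in curves) {
    fit <- tryCatch(fit_limb(cv, bounds = curve_bounds(cv), ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        peep_cmH2O = cv$peep, limb = cv$limb,
        parameter = if (cv$limb == "inflation") "TOP" else "TCP",
        mean_cmH2O = NA_real_, sd_cmH2O = NA_real_, tlc_ml = NA_real_,
        mape_pct = NA_real_, n_points = length(cv$pressure),
        converged = FALSE, poorly_identified = NA,
        error = conditionMessage(fit))
      fits[[length(fits) + 1L]] <- NULL
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        peep_cmH2O = fit$peep, limb = fit$limb,
        parameter = if (fit$limb == "inflation") "TOP" else "TCP",
        mean_cmH2O = fit$params$mean, sd_cmH2O = fit$params$sd,
        tlc_ml = fit$params$tlc, mape_pct = fit$mape,
        n_points = fit$n_points, converged = fit$converged,
        poorly_identified = fit$poorly_identified, error = NA_character_)
      fits[[length(fits) + 1L]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
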