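#' Recruitment model parameters
#'
#' Container for the three parameters of the error-function recruitment model:
#' the mean and standard deviation of the threshold-pressure distribution
#' (threshold opening pressures, TOP, for an inflation limb; threshold closing
#' pressures, TCP, for a deflation limb) and the recruitable capacity `tlc`,
#' the asymptotic volume when every lung unit is open.
#'
#' The model states that the recruited volume at airway pressure \eqn{P} is
#' \deqn{V(P) = \frac{1}{2}\left(1 + \mathrm{erf}\frac{P - \mu}{\sqrt{2}\,\sigma}\right) \cdot TLC,}
#' i.e. the normal CDF of the threshold-pressure distribution scaled by the
#' recruitable capacity.
#'
#' @param mean Mean threshold pressure (cmH2O). Pressure of the maximum rate
#'   of recruitment (inflation) or derecruitment (deflation).
#' @param sd Standard deviation of the threshold-pressure distribution
#'   (cmH2O); an index of lung heterogeneity. Must be positive.
#' @param tlc Recruitable capacity (ml). Must be positive.
#' @return An object of class `recruit_params`.
#' @examples
#' p <- recruit_params(mean = 35, sd = 10, tlc = 500)
#' model_volume(35, p) # half the capacity
#' @export
recruit_params <- function(mean, sd, tlc) {
  if (!is.numeric(mean) || !is.numeric(sd) || !is.numeric(tlc) ||
      length(mean) != 1L || length(sd) != 1L || length(tlc) != 1L ||
      !is.finite(mean) || !is.finite(sd) || !is.finite(tlc)) {
    stop("mean, sd and tlc must be finite numeric scalars")
  }
  if (sd <= 0) stop("sd must be > 0")
  if (tlc <= 0) stop("tlc must be > 0")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 tlc = as.numeric(tlc)),
            class = "recruit_params")
}

#' @export
print.recruit_params <- function(x, ...) {
  cat(sprintf("Recruitment model parameters: mean = %.2f cmH2O, sd = %.2f cmH2O, tlc = %.1f ml\n",
              x$mean, x$sd, x$tlc))
  invisible(x)
}

stop_if_not_params <- function(params) {
  if (!inherits(params, "recruit_params")) {
    stop("params must be a recruit_params object")
  }
  invisible(params)
}

#' Fraction of recruitable units open at a given pressure
#'
#' Evaluates \eqn{\frac{1}{2}(1 + \mathrm{erf}((P-\mu)/(\sqrt{2}\sigma)))},
#' the cumulative fraction of the threshold-pressure distribution below `pressure`.
#' Computed through the identity with the normal CDF,
#' \eqn{\frac{1}{2}(1+\mathrm{erf}(z/\sqrt 2)) = \Phi(z)}.
#'
#' @param pressure Airway pressure(s), cmH2O. Vectorised.
#' @param params A [recruit_params] object.
#' @return Fraction(s) in \[0, 1\], strictly increasing in pressure.
#' @export
fraction_recruited <- function(pressure, params) {
  stop_if_not_params(params)
  if (!is.numeric(pressure)) stop("pressure must be numeric")
  stats::pnorm(pressure, mean = params$mean, sd = params$sd)
}

#' Model volume at a given pressure
#'
#' Recruited volume `tlc * fraction_recruited(pressure)`, bounded in
#' \[0, tlc\].
#'
#' @inheritParams fraction_recruited
#' @return Volume(s) in ml.
#' @export
model_volume <- function(pressure, params) {
  params$tlc * fraction_recruited(pressure, params)
}

#' Invert the recruitment model
#'
#' Returns the pressure at which the model holds a given volume; the exact
#' inverse of [model_volume()] through the normal quantile function (inverse
#' error function).
#'
#' @param volume Volume(s) in ml, strictly between 0 and `tlc`.
#' @param params A [recruit_params] object.
#' @return Pressure(s) in cmH2O.
#' @export
invert_model <- function(volume, params) {
  stop_if_not_params(params)
  if (!is.numeric(volume)) stop("volume must be numeric")
  if (any(volume <= 0 | volume >= params$tlc)) {
    stop("volume must lie strictly between 0 and tlc")
  }
  stats::qnorm(volume / params$tlc, mean = params$mean, sd = params$sd)
}

#' Threshold-pressure density
#'
#' Density of the (normal) threshold opening/closing pressure distribution.
#' Its maximum at `mean` is the pressure of the maximum rate of
#' recruitment/derecruitment; it is the derivative of [model_volume()]
#' divided by `tlc`.
#'
#' @inheritParams fraction_recruited
#' @return Density values, per cmH2O.
#' @export
threshold_density <- function(pressure, params) {
  stop_if_not_params(params)
  if (!is.numeric(pressure)) stop("pressure must be numeric")
  stats::dnorm(pressure, mean = params$mean, sd = params$sd)
}
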