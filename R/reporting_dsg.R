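# Summary tables (median/IQR/mean), Wilcoxon rank-sum comparison, static
# compliance, and the disease-state-grouping (DSG) plane.

#' Nearest-rank quantile
#'
#' The p-th quantile as the ceiling(p*n)-th order statistic. For n = 9 the
#' 1st and 3rd quartiles are the 3rd and 7th order statistics, the convention
#' that reproduces the reference summary tables from per-subject values.
#'
#' @param x Numeric sample.
#' @param p Probability in (0, 1\].
#' @return A single order statistic of `x`.
#' @export
nearest_rank_quantile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

#' Summarise fitted parameters into median/IQR/mean tables
#'
#' Groups a long table of fitted values and reports n, median, nearest-rank
#' 1st/3rd quartiles, and the arithmetic mean. Full precision is retained;
#' [render_summary()] rounds to one decimal for report rendering.
#'
#' @param fits Data frame of fitted values (one row per subject x group).
#' @param value_col Name of the value column to summarise.
#' @param by Character vector of grouping columns.
#' @return Data frame with the grouping columns plus `n`, `median`,
#'   `iqr_low`, `iqr_high`, `mean`. Empty groups are omitted.
#' @examples
#' df <- data.frame(g = "a", v = c(1, 2, 3, 4, 5))
#' summarize_fits(df, "v", "g")
#' @export
summarize_fits <- function(fits, value_col = "mean_cmH2O",
                           by = c("state", "limb", "peep_cmH2O")) {
  if (!value_col %in% names(fits)) stop("missing value column ", value_col)
  by <- by[by %in% names(fits)]
  if (length(by) == 0L) stop("no grouping columns found")
  key <- interaction(fits[by], drop = TRUE, lex.order = TRUE)
  groups <- split(fits, key)
  rows <- lapply(groups, function(g) {
    v <- g[[value_col]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      warning("empty group omitted")
      return(NULL)
    }
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = length(v),
                     median = nearest_rank_quantile(v, 0.5),
                     iqr_low = nearest_rank_quantile(v, 0.25),
                     iqr_high = nearest_rank_quantile(v, 0.75),
                     mean = mean(v)))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Render summary cells to one decimal
#'
#' `"median [iqr_low-iqr_high]"` strings with every number rounded to one
#' decimal, the rendering used in the report tables.
#'
#' @param summary A row set from [summarize_fits()].
#' @return Character vector of rendered cells.
#' @export
render_summary <- function(summary) {
  fmt <- function(x) formatC(round(x, 1), format = "f", digits = 1)
  sprintf("%s [%s-%s]", fmt(summary$median), fmt(summary$iqr_low),
          fmt(summary$iqr_high))
}

#' Wilcoxon rank-sum test (mid-ranks, exact by enumeration for small n)
#'
#' Two-sided rank-sum test of two independent samples. Ties receive
#' mid-ranks. For `n_x + n_y <= exact_max_n` the p-value is exact: all
#' choose(N, n_x) assignments of the pooled mid-ranks are enumerated and the
#' two-sided p is the fraction of assignments whose rank sum deviates from
#' its null mean at least as much as the observed one. For larger samples a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max_n Largest pooled size for exact enumeration (default 12).
#' @return List with `statistic` (rank sum of `x`), `p_value`, and `method`
#'   ("exact" or "normal").
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value # exactly 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  r <- rank(c(x, y))   # mid-ranks for ties
  w <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  if (N <= exact_max_n) {
    sums <- utils::combn(N, nx, FUN = function(i) sum(r[i]))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- nx * ny / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Static respiratory compliance
#'
#' `vt / (plateau_pressure - peep)`, ml/cmH2O.
#'
#' @param vt Tidal volume, ml.
#' @param plateau_pressure End-inspiratory plateau pressure, cmH2O; must
#'   exceed `peep`.
#' @param peep PEEP, cmH2O.
#' @return Compliance in ml/cmH2O.
#' @export
compute_static_compliance <- function(vt, plateau_pressure, peep) {
  if (any(plateau_pressure <= peep)) {
    stop("plateau pressure must exceed PEEP")
  }
  vt / (plateau_pressure - peep)
}

#' Assign a disease-state-grouping panel
#'
#' Places a (mean TOP, SD) point on the four-panel DSG plane:
#' B = low SD & low TOP (healthiest), A = high SD & low TOP,
#' D = low SD & high TOP, C = high SD & high TOP. The thresholds are
#' mandatory configuration: no defaults are claimed, since panel boundaries
#' are patient- or group-specific. Equality with a threshold is assigned to
#' the lower category with a note.
#'
#' @param mean_top Mean TOP, cmH2O (typically the baseline-PEEP inflation
#'   fit).
#' @param sd_top SD of the TOP distribution, cmH2O.
#' @param top_threshold,sd_threshold Panel boundaries, cmH2O.
#' @param state_tag Free label (e.g. "healthy", "ARDS").
#' @param order Sequence index for trajectory tracking.
#' @return A one-row data frame of class `dsg_point` with columns
#'   `mean_top`, `sd_top`, `panel`, `state_tag`, `order`, `boundary_note`.
#' @export
assign_dsg_panel <- function(mean_top, sd_top, top_threshold, sd_threshold,
                             state_tag = "", order = 1L) {
  if (missing(top_threshold) || missing(sd_threshold) ||
      is.null(top_threshold) || is.null(sd_threshold)) {
    stop("configuration error: DSG panel thresholds must be supplied")
  }
  low_top <- mean_top <= top_threshold
  low_sd <- sd_top <= sd_threshold
  panel <- if (low_top && low_sd) "B" else if (low_top) "A" else
    if (low_sd) "D" else "C"
  note <- mean_top == top_threshold || sd_top == sd_threshold
  if (note) message("DSG value equals a threshold; assigned to the lower category")
  out <- data.frame(mean_top = mean_top, sd_top = sd_top, panel = panel,
                    state_tag = state_tag, order = order,
                    boundary_note = note)
  class(out) <- c("dsg_point", "data.frame")
  out
}

#' Track a subject's trajectory on the DSG plane
#'
#' For each consecutive pair of DSG points, reports the change in mean TOP
#' and SD and a qualitative label: `improving` when both changes are
#' non-positive with at least one negative (the lung is recruiting at lower
#' pressure and/or becoming more homogeneous), `worsening` when both are
#' non-negative with at least one positive, `unchanged` when both are zero,
#' `mixed` otherwise.
#'
#' @param points Data frame of DSG points (rows of [assign_dsg_panel()] or
#'   any frame with `mean_top`, `sd_top`, ordered by `order`); at least 2
#'   rows.
#' @return Data frame with one row per consecutive pair: `from`, `to`,
#'   `delta_mean_top`, `delta_sd_top`, `label`.
#' @export
track_dsg <- function(points) {
  if (nrow(points) < 2L) stop("trajectory tracking needs at least 2 points")
  if ("order" %in% names(points)) points <- points[order(points$order), ]
  n <- nrow(points)
  d_top <- diff(points$mean_top)
  d_sd <- diff(points$sd_top)
  label <- vapply(seq_len(n - 1L), function(i) {
    dt <- d_top[i]; ds <- d_sd[i]
    if (dt == 0 && ds == 0) "unchanged"
    else if (dt <= 0 && ds <= 0) "improving"
    else if (dt >= 0 && ds >= 0) "worsening"
    else "mixed"
  }, character(1))
  data.frame(from = seq_len(n - 1L), to = seq_len(n - 1L) + 1L,
             delta_mean_top = d_top, delta_sd_top = d_sd, label = label)
}
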