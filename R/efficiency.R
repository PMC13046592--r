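#' Cost-efficiency table from inefficiency draws
#'
#' Scores each hospital-year cell by the posterior mean of exp(-u_it),
#' expressed in percent, and aggregates by year and overall. Two overall
#' conventions are computed: the mean over all hospital-year cells and the
#' mean of the yearly means (they coincide for balanced panels).
#'
#' @param u_draws Matrix of retained inefficiency draws
#'   (iterations x cells), all nonnegative.
#' @param cells Data frame with one row per cell: `hospital_id`, `year`.
#' @return An object of class `efficiency_table`: list with `cells`
#'   (hospital_id, year, ce_pct, u_mean), `yearly` (year, ce_pct, n),
#'   `overall_cell_mean`, `overall_year_mean` (all in percent).
#' @export
efficiency_from_draws <- function(u_draws, cells) {
  u_draws <- as.matrix(u_draws)
  if (nrow(u_draws) == 0L || ncol(u_draws) == 0L) stop("empty draws")
  if (any(u_draws < 0)) stop("inefficiency draws must be nonnegative")
  if (nrow(cells) != ncol(u_draws))
    stop("cells and draw columns do not align")
  ce <- colMeans(exp(-u_draws)) * 100
  cell_df <- data.frame(hospital_id = cells$hospital_id, year = cells$year,
                        ce_pct = ce, u_mean = colMeans(u_draws),
                        stringsAsFactors = FALSE)
  yearly <- stats::aggregate(ce_pct ~ year, data = cell_df, FUN = mean)
  yearly$n <- as.vector(table(cell_df$year)[as.character(yearly$year)])
  structure(list(cells = cell_df, yearly = yearly,
                 overall_cell_mean = mean(ce),
                 overall_year_mean = mean(yearly$ce_pct)),
            class = "efficiency_table")
}

#' @export
print.efficiency_table <- function(x, ...) {
  cat("cost efficiency (%)\n")
  print(x$yearly, row.names = FALSE)
  cat(sprintf("  overall (cell mean):        %.2f\n", x$overall_cell_mean))
  cat(sprintf("  overall (mean of yearly):   %.2f\n", x$overall_year_mean))
  invisible(x)
}

#' Yearly and overall efficiency means
#'
#' Aggregates an [efficiency_from_draws()] table, or a bare vector of
#' yearly means, under one of two conventions: `"cell-mean"` (average over
#' every hospital-year cell) or `"year-mean-of-means"` (average of the
#' yearly averages).
#'
#' @param x An `efficiency_table`, or a numeric vector of yearly mean
#'   efficiencies (in which case only `"year-mean-of-means"` applies, with
#'   optional `weights` for the cell-mean convention).
#' @param mode `"cell-mean"` or `"year-mean-of-means"`.
#' @param weights Optional yearly cell counts when `x` is a bare vector.
#' @return List with `yearly` (named numeric) and `overall`.
#' @export
yearly_overall_means <- function(x, mode = c("cell-mean",
                                             "year-mean-of-means"),
                                 weights = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "efficiency_table")) {
    yearly <- stats::setNames(x$yearly$ce_pct, x$yearly$year)
    overall <- if (mode == "cell-mean") x$overall_cell_mean
               else x$overall_year_mean
  } else {
    yearly <- as.numeric(x)
    overall <- if (mode == "year-mean-of-means") mean(yearly)
    else {
      if (is.null(weights)) stop("cell-mean mode needs yearly cell counts")
      sum(yearly * weights) / sum(weights)
    }
    names(yearly) <- names(x)
  }
  list(yearly = yearly, overall = overall)
}

#' Efficiency gap between the heterogeneous and homogeneous models
#'
#' The percentage-point difference random-model minus fixed-model mean
#' efficiency: the overestimation of inefficiency incurred by ignoring
#' hospital heterogeneity.
#'
#' @param fixed_mean Fixed-coefficient mean efficiency, percent in (0, 100].
#' @param random_mean Random-coefficient mean efficiency, percent in (0, 100].
#' @return Gap in percentage points.
#' @export
heterogeneity_gap <- function(fixed_mean, random_mean) {
  for (m in c(fixed_mean, random_mean))
    if (!is.finite(m) || m <= 0 || m > 100)
      stop("mean efficiencies must lie in (0, 100]")
  random_mean - fixed_mean
}

#' Inefficiency margin implied by a mean efficiency
#'
#' @param mean_eff Mean efficiency in percent, in (0, 100].
#' @return `100 - mean_eff`, the percent cost reduction available.
#' @export
inefficiency_share <- function(mean_eff) {
  if (any(!is.finite(mean_eff)) || any(mean_eff <= 0) || any(mean_eff > 100))
    stop("mean efficiency must lie in (0, 100]")
  100 - mean_eff
}

#' Potential cost saving from removing inefficiency
#'
#' @param mean_cost Mean cost per hospital (any monetary unit).
#' @param ineff_share Inefficiency margin in percent.
#' @return `mean_cost * ineff_share / 100`, same unit as `mean_cost`.
#' @export
potential_saving <- function(mean_cost, ineff_share) {
  if (mean_cost <= 0 || ineff_share < 0) stop("inputs must be positive")
  mean_cost * ineff_share / 100
}

#' Kernel density of cell-level inefficiency
#'
#' Density of the per-cell posterior-mean inefficiency (or efficiency)
#' values, Silverman's rule bandwidth by default, renormalized so the
#' trapezoid integral over the returned grid is exactly 1.
#'
#' @param values Numeric vector (e.g. `table$cells$u_mean`).
#' @param bw Bandwidth rule or value, passed to [stats::density()].
#' @param n Grid size.
#' @return Data frame with columns `grid`, `density`.
#' @export
inefficiency_density <- function(values, bw = "nrd0", n = 512L) {
  if (!length(values)) stop("empty input")
  d <- stats::density(values, bw = bw, n = n)
  area <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
  data.frame(grid = d$x, density = d$y / area)
}

#' Fixed-versus-random bias report
#'
#' Summarizes the heterogeneity bias: both models' mean efficiencies, the
#' percentage-point gap, the inefficiency margins, and the potential
#' saving at the panel's mean cost.
#'
#' @param fixed_mean_eff Fixed-model mean efficiency (percent).
#' @param random_mean_eff Random-model mean efficiency (percent).
#' @param mean_cost Mean cost per hospital (thousands of currency units).
#' @return List of class `bias_report` with fields `fixed_mean_eff`,
#'   `random_mean_eff`, `gap_pp`, `ineff_share_fixed`,
#'   `ineff_share_random`, `potential_saving` (thousands) and
#'   `potential_saving_millions`.
#' @export
bias_report <- function(fixed_mean_eff, random_mean_eff, mean_cost) {
  share_r <- inefficiency_share(random_mean_eff)
  share_f <- inefficiency_share(fixed_mean_eff)
  saving <- potential_saving(mean_cost, share_r)
  structure(list(
    fixed_mean_eff = fixed_mean_eff,
    random_mean_eff = random_mean_eff,
    gap_pp = heterogeneity_gap(fixed_mean_eff, random_mean_eff),
    ineff_share_fixed = share_f,
    ineff_share_random = share_r,
    potential_saving = saving,
    potential_saving_millions = saving / 1000
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("heterogeneity bias report\n")
  cat(sprintf("  mean efficiency, fixed coefficients:  %.2f%%\n", x$fixed_mean_eff))
  cat(sprintf("  mean efficiency, random coefficients: %.2f%%\n", x$random_mean_eff))
  cat(sprintf("  overestimation of inefficiency:       %.2f pp\n", x$gap_pp))
  cat(sprintf("  inefficiency margin (random):         %.2f%%\n", x$ineff_share_random))
  cat(sprintf("  potential saving per hospital:        %.2f million\n",
              x$potential_saving_millions))
  invisible(x)
}
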