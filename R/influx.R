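#' An empirical or simulated carbon-influx dataset
#'
#' @param name dataset identifier.
#' @param kind `"NPP"` or `"GPP"`.
#' @param years consecutive integer years covered.
#' @param values years x cells matrix (gC m^-2 yr^-1); `NA` marks masked
#'   cells.
#' @return An `influx_dataset`.
#' @export
influx_dataset <- function(name, kind = c("NPP", "GPP"), years, values) {
  kind <- match.arg(kind)
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be consecutive")
  values <- as.matrix(values)
  if (nrow(values) != length(years)) stop("values must have one row per year")
  if (any(values < 0, na.rm = TRUE)) stop("influx values must be non-negative")
  rownames(values) <- years
  structure(list(name = name, kind = kind, years = years, values = values),
            class = "influx_dataset")
}

#' @export
print.influx_dataset <- function(x, ...) {
  cat("<influx_dataset> ", x$name, " (", x$kind, "), years ",
      min(x$years), "-", max(x$years), ", ", ncol(x$values), " cells\n",
      sep = "")
  invisible(x)
}

#' Convert an empirical GPP dataset to NPP
#'
#' Removes autotrophic (plant) respiration using the simulated NPP-to-GPP
#' ratio, per year and cell:
#' `npp_emp = gpp_emp * npp_sim / gpp_sim`. Cells where the simulated GPP is
#' zero yield zero NPP and are counted in the `n_zero_sim` attribute.
#'
#' @param gpp_emp an `influx_dataset` of kind `"GPP"`.
#' @param gpp_sim,npp_sim simulated series as years x cells matrices with
#'   year rownames covering `gpp_emp$years`, or `influx_dataset`s.
#' @return An `influx_dataset` of kind `"NPP"` over `gpp_emp$years`.
#' @export
gpp_to_npp <- function(gpp_emp, gpp_sim, npp_sim) {
  stopifnot(inherits(gpp_emp, "influx_dataset"))
  if (gpp_emp$kind != "GPP") stop("gpp_emp must be of kind GPP")
  as_mat <- function(x) if (inherits(x, "influx_dataset")) x$values else as.matrix(x)
  gpp_sim <- as_mat(gpp_sim); npp_sim <- as_mat(npp_sim)
  if (any(gpp_sim < 0, na.rm = TRUE) || any(npp_sim < 0, na.rm = TRUE))
    stop("simulated series must be non-negative")
  yrs <- as.character(gpp_emp$years)
  if (!all(yrs %in% rownames(gpp_sim)) || !all(yrs %in% rownames(npp_sim)))
    stop("simulated series must cover the empirical years")
  ratio <- npp_sim[yrs, , drop = FALSE] / gpp_sim[yrs, , drop = FALSE]
  zero <- gpp_sim[yrs, , drop = FALSE] == 0
  ratio[zero] <- 0
  out <- influx_dataset(paste0(gpp_emp$name, "_as_npp"), "NPP", gpp_emp$years,
                        gpp_emp$values * ratio)
  attr(out, "n_zero_sim") <- sum(zero, na.rm = TRUE)
  out
}

# Per-cell OLS slope and mean over rows of a years x cells matrix.
# Columns containing NA return NA. Same least-squares algebra as lm(v ~ t).
ols_slopes <- function(values, years) {
  t_c <- years - mean(years)
  denom <- sum(t_c^2)
  vbar <- colMeans(values)
  slope <- drop(crossprod(t_c, sweep(values, 2, vbar))) / denom
  list(slope = slope, mean = vbar, t_mid = mean(years))
}

#' Refine an empirical NPP series with the simulated trend
#'
#' Produces the influx series used in fusion: the simulated series up to the
#' merge year, then the empirical series with its linear trend replaced by
#' the simulated linear trend over the common period,
#' `refined(t) = emp(t) + (s_sim - s_emp) * (t - t_mid)`,
#' where `s_sim`, `s_emp` are per-cell OLS slopes over the common period and
#' `t_mid` its mid-year. This keeps the empirical interannual variability
#' and magnitude while aligning the trend with the simulation, so the
#' emulator can be initialised from the pre-merge simulated epoch. Years
#' after the empirical coverage revert to the simulated series. Negative
#' refined values are floored at zero and counted.
#'
#' @param npp_sim_full simulated NPP over the full span: years x cells
#'   matrix with year rownames, or an `influx_dataset`.
#' @param npp_emp empirical `influx_dataset` of kind `"NPP"`.
#' @param merge_year first year at which the refined series departs from the
#'   simulation; must be the first year of `common_period`.
#' @param common_period integer years over which trends are fitted (at least
#'   3); defaults to the overlap of the two series.
#' @return A `refined_npp`: list with `years`, `values`, `merge_year`,
#'   `source_name` and a `diagnostics` list (`n_floored`,
#'   `n_cells_unrefined` for cells left simulated because of masking,
#'   `merge_step` mean absolute step at the merge year).
#' @export
refine_npp <- function(npp_sim_full, npp_emp, merge_year = NULL,
                       common_period = NULL) {
  stopifnot(inherits(npp_emp, "influx_dataset"))
  if (npp_emp$kind != "NPP") stop("npp_emp must be of kind NPP (see gpp_to_npp)")
  if (inherits(npp_sim_full, "influx_dataset")) {
    sim_years <- npp_sim_full$years
    sim <- npp_sim_full$values
  } else {
    sim <- as.matrix(npp_sim_full)
    sim_years <- as.integer(rownames(sim))
  }
  if (ncol(sim) != ncol(npp_emp$values))
    stop("simulated and empirical series must share cells")
  overlap <- intersect(sim_years, npp_emp$years)
  if (is.null(common_period)) common_period <- overlap
  common_period <- as.integer(common_period)
  if (length(common_period) < 3) stop("common period must span at least 3 years")
  if (!all(common_period %in% overlap))
    stop("common period must lie within both series")
  if (is.null(merge_year)) merge_year <- min(common_period)
  if (merge_year != min(common_period))
    stop("merge_year must be the first year of the common period")

  cp <- as.character(common_period)
  emp_cp <- npp_emp$values[cp, , drop = FALSE]
  ok <- colSums(is.na(emp_cp)) == 0
  fit_emp <- ols_slopes(emp_cp[, ok, drop = FALSE], common_period)
  fit_sim <- ols_slopes(sim[cp, ok, drop = FALSE], common_period)

  refined <- sim
  emp_span <- intersect(sim_years[sim_years >= merge_year], npp_emp$years)
  es <- as.character(emp_span)
  adj <- outer(emp_span - fit_emp$t_mid, fit_sim$slope - fit_emp$slope)
  vals <- npp_emp$values[es, ok, drop = FALSE] + adj
  n_floored <- sum(vals < 0)
  vals[vals < 0] <- 0
  refined[es, ok] <- vals

  pre <- merge_year - 1L
  merge_step <- if (pre %in% sim_years) {
    mean(abs(refined[as.character(merge_year), ok] -
               refined[as.character(pre), ok]))
  } else NA_real_
  structure(list(years = sim_years, values = refined,
                 merge_year = merge_year,
                 common_period = common_period,
                 source_name = npp_emp$name,
                 diagnostics = list(n_floored = n_floored,
                                    n_cells_unrefined = sum(!ok),
                                    merge_step = merge_step)),
            class = "refined_npp")
}

#' @export
print.refined_npp <- function(x, ...) {
  cat("<refined_npp> from ", x$source_name, ", merge year ", x$merge_year,
      ", common period ", min(x$common_period), "-", max(x$common_period),
      "; floored values: ", x$diagnostics$n_floored,
      ", unrefined cells: ", x$diagnostics$n_cells_unrefined, "\n", sep = "")
  invisible(x)
}
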