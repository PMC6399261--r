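#' An observational stock dataset (AGB or soil carbon)
#'
#' @param name dataset identifier.
#' @param kind `"AGB"` (gC m^-2) or `"soilC"` (total kgC m^-2).
#' @param values per-cell stock; `NA` marks masked cells.
#' @param layered for soil carbon, a cells x layers matrix of carbon per
#'   depth interval (kgC m^-2 per layer).
#' @param layer_bounds depth bounds (m) of the layers, strictly increasing
#'   from 0, length `ncol(layered) + 1`.
#' @return A `stock_dataset`.
#' @export
stock_dataset <- function(name, kind = c("AGB", "soilC"), values,
                          layered = NULL, layer_bounds = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) stop("stock values must be non-negative")
  if (!is.null(layered)) {
    layered <- as.matrix(layered)
    if (is.null(layer_bounds)) stop("layer_bounds required with layered values")
    layer_bounds <- as.numeric(layer_bounds)
    if (layer_bounds[1] != 0 || any(diff(layer_bounds) <= 0))
      stop("layer bounds must strictly increase from 0")
    if (length(layer_bounds) != ncol(layered) + 1)
      stop("need one more bound than layers")
    if (nrow(layered) != length(values))
      stop("layered values must share cells with totals")
    if (any(layered < 0, na.rm = TRUE)) stop("layered stocks must be non-negative")
  }
  structure(list(name = name, kind = kind, values = values,
                 layered = layered, layer_bounds = layer_bounds,
                 adjusted = FALSE),
            class = "stock_dataset")
}

#' @export
print.stock_dataset <- function(x, ...) {
  cat("<stock_dataset> ", x$name, " (", x$kind, "), ", length(x$values),
      " cells", if (!is.null(x$layered))
        paste0(", ", ncol(x$layered), " depth layers to ",
               max(x$layer_bounds), " m"),
      if (x$adjusted) ", depth-adjusted", "\n", sep = "")
  invisible(x)
}

# Cumulative carbon above depth d from layered stocks, linear within layers.
cum_carbon_above <- function(layered, bounds, depth) {
  lo <- bounds[-length(bounds)]
  hi <- bounds[-1]
  # fraction of each layer lying above `depth` (vector over cells or scalar)
  n <- nrow(layered)
  depth <- rep_len(depth, n)
  frac <- outer(depth, lo, `-`) / matrix(hi - lo, n, length(lo), byrow = TRUE)
  frac[frac < 0] <- 0
  frac[frac > 1] <- 1
  rowSums(layered * frac)
}

#' Depth-adjust a layered soil-carbon dataset for peatland and permafrost
#'
#' The emulated vegetation is assumed to interact only with the upper 40 cm
#' of peat soils and, in permafrost terrain, only with carbon inside the
#' seasonally thawed active layer. Per cell, the peatland area fraction
#' keeps carbon above 0.40 m; the remaining fraction keeps carbon above the
#' active-layer depth where permafrost is present, or the full profile
#' otherwise. Within-layer truncation is linear. The adjustment never
#' increases a cell's stock, and an already-adjusted dataset is returned
#' unchanged (idempotent).
#'
#' @param stock a layered `stock_dataset` of kind `"soilC"` whose layers
#'   reach the domain's soil reference depth.
#' @param domain a [grid_domain].
#' @return A `stock_dataset` with adjusted per-cell totals (kgC m^-2).
#' @export
adjust_soil_c <- function(stock, domain) {
  stopifnot(inherits(stock, "stock_dataset"), inherits(domain, "grid_domain"))
  if (stock$kind != "soilC") stop("adjust_soil_c applies to soil carbon")
  if (isTRUE(stock$adjusted)) return(stock)
  if (is.null(stock$layered)) stop("layered stocks required for adjustment")
  n <- nrow(stock$layered)
  if (n != nrow(domain$cells)) stop("stock and domain must share cells")
  max_depth <- max(stock$layer_bounds)
  if (max_depth < domain$soil_reference_depth - 1e-9)
    stop("soil layers do not cover the reference depth of ",
         domain$soil_reference_depth, " m")
  full <- rowSums(stock$layered)
  peat_cut <- cum_carbon_above(stock$layered, stock$layer_bounds, 0.40)
  alt <- pmin(domain$cells$active_layer_depth, max_depth)
  pf <- !is.na(alt)
  other <- full
  if (any(pf))
    other[pf] <- cum_carbon_above(stock$layered[pf, , drop = FALSE],
                                  stock$layer_bounds, alt[pf])
  w <- domain$cells$peat_fraction
  adjusted <- w * peat_cut + (1 - w) * other
  out <- stock_dataset(stock$name, "soilC", adjusted)
  out$adjusted <- TRUE
  out
}

#' Apparent turnover rate from influx and stock
#'
#' The apparent turnover rate is the carbon influx divided by the stock
#' (yr^-1); its inverse is the apparent residence time. It equals the true
#' rate only at steady state, but computing simulated and observed rates
#' with the identical quotient offsets much of the transient bias. Cells
#' with zero or missing stock or influx are masked with a reason code
#' rather than yielding infinities.
#'
#' @param influx_mean per-cell influx averaged over the stated window
#'   (gC m^-2 yr^-1).
#' @param stock per-cell stock in gC m^-2 (convert soil kgC with
#'   `* 1000` before calling).
#' @param kind `"vegetation"` or `"soil"`.
#' @return An `apparent_turnover`: list with `kind`, `rate` (NA where
#'   masked) and `mask_reason`.
#' @export
apparent_turnover_rate <- function(influx_mean, stock,
                                   kind = c("vegetation", "soil")) {
  kind <- match.arg(kind)
  influx_mean <- as.numeric(influx_mean)
  stock <- as.numeric(stock)
  stopifnot(length(influx_mean) == length(stock))
  if (any(influx_mean < 0, na.rm = TRUE) || any(stock < 0, na.rm = TRUE))
    stop("influx and stock must be non-negative")
  reason <- rep("", length(stock))
  reason[is.na(stock) | is.na(influx_mean)] <- "missing"
  reason[!is.na(stock) & stock == 0] <- "zero_stock"
  reason[reason == "" & influx_mean == 0] <- "zero_influx"
  rate <- ifelse(reason == "", influx_mean / stock, NA_real_)
  structure(list(kind = kind, rate = rate, mask_reason = reason),
            class = "apparent_turnover")
}

#' Apparent turnover rates of an emulator trajectory
#'
#' Computes the simulated counterpart of [apparent_turnover_rate] from a
#' trajectory with the identical formula and window: window-mean influx
#' divided by window-mean AGB (vegetation) or litter+soil carbon (soil).
#'
#' @param trajectory a `state_trajectory`.
#' @param system the [pool_system] that produced it.
#' @param window integer years to average over.
#' @param kind `"vegetation"` or `"soil"`.
#' @return An `apparent_turnover`.
#' @export
apparent_rates <- function(trajectory, system, window,
                           kind = c("vegetation", "soil")) {
  kind <- match.arg(kind)
  idx <- match(window, trajectory$years)
  if (anyNA(idx)) stop("window years absent from trajectory")
  stocks <- stock_summaries(trajectory, system, window)
  u <- colMeans(trajectory$influx_used[idx, , drop = FALSE])
  stock <- if (kind == "vegetation") stocks$agb else stocks$soil_c
  apparent_turnover_rate(u, stock, kind)
}

#' Rescale a compartment's exit rates towards observed apparent turnover
#'
#' Multiplies the environmental scalar of every pool in the chosen
#' compartment by `r = apparent_obs / apparent_sim` per cell, so that the
#' emulator's aggregate apparent rate matches the observation-derived one
#' while all relative flows within the compartment are preserved.
#' `"soil"` covers the litter and soil pools jointly, because observed
#' soil-carbon stocks do not separate litter from mineral soil. Cells
#' masked in either rate are left unmodified and counted, as are cells
#' where the rescaled effective annual exit fraction `K * xi` of any pool
#' in the compartment would exceed `max_exit`: the annual explicit step
#' cannot represent faster turnover, so those cells keep the simulated
#' rates (mirroring the fallback to simulated rates where observations
#' cannot be used).
#'
#' @param system a [pool_system].
#' @param xi cells x pools environmental-scalar matrix (a scalar or vector
#'   is expanded).
#' @param apparent_obs,apparent_sim `apparent_turnover` objects of the same
#'   kind, computed with the identical formula and window.
#' @param compartment `"vegetation"` or `"soil"`.
#' @param max_exit largest representable effective annual exit fraction
#'   (default 1).
#' @return The modified cells x pools `xi` matrix, with attributes
#'   `n_unmodified` (cells left untouched), `n_exceeding` (the subset
#'   reverted for exceeding `max_exit`) and `ratio` (per-cell factor, NA
#'   where masked or reverted).
#' @export
rescale_exit_rates <- function(system, xi, apparent_obs, apparent_sim,
                               compartment = c("vegetation", "soil"),
                               max_exit = 1) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(apparent_obs, "apparent_turnover"),
            inherits(apparent_sim, "apparent_turnover"))
  n <- length(apparent_obs$rate)
  stopifnot(length(apparent_sim$rate) == n)
  p <- n_pools(system)
  xi <- expand_xi(xi, n, p)
  r <- apparent_obs$rate / apparent_sim$rate
  if (any(r <= 0, na.rm = TRUE))
    stop("non-positive turnover rescaling ratio")
  pools <- if (compartment == "vegetation") {
    system$compartment == "vegetation"
  } else {
    system$compartment %in% c("litter", "soil")
  }
  ok <- !is.na(r)
  kmax <- apply(sweep(xi[, pools, drop = FALSE], 2, system$K[pools], `*`),
                1, max)
  exceeding <- ok & kmax * r > max_exit + 1e-12
  ok <- ok & !exceeding
  r[!ok] <- NA_real_
  xi[ok, pools] <- xi[ok, pools, drop = FALSE] * r[ok]
  attr(xi, "n_unmodified") <- sum(!ok)
  attr(xi, "n_exceeding") <- sum(exceeding)
  attr(xi, "ratio") <- r
  xi
}
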