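#' Annual forcing for the emulator
#'
#' Bundles the influx series and environmental rate scalars driving the
#' linear system. The scalar `xi` multiplies each pool's baseline exit rate;
#' it is where the dynamic model's climate sensitivity of turnover enters,
#' and where turnover fusion rescales rates.
#'
#' @param years consecutive integer years.
#' @param U years x cells influx matrix (NPP, gC m^-2 yr^-1), non-negative.
#' @param xi environmental scalars: `NULL` (all 1), a scalar, a per-pool
#'   vector, a cells x pools matrix (constant in time), or a years x cells x
#'   pools array; strictly positive.
#' @return A `forcing_set`.
#' @export
forcing_set <- function(years, U, xi = NULL) {
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be consecutive")
  U <- as.matrix(U)
  if (nrow(U) != length(years)) stop("U must have one row per year")
  if (any(U < 0)) stop("influx U must be non-negative")
  if (!is.null(xi)) {
    if (is.array(xi) && length(dim(xi)) == 3 && dim(xi)[1] != length(years))
      stop("time-varying xi must have one slice per year")
    if (any(xi <= 0)) stop("xi must be strictly positive")
  }
  rownames(U) <- years
  structure(list(years = years, U = U, xi = xi), class = "forcing_set")
}

#' @export
print.forcing_set <- function(x, ...) {
  cat("<forcing_set> years ", min(x$years), "-", max(x$years), ", ",
      ncol(x$U), " cells, xi: ",
      if (is.null(x$xi)) "1 (uniform)" else paste(dim(as.array(x$xi)),
                                                  collapse = " x "),
      "\n", sep = "")
  invisible(x)
}

# xi slice for year index t, as accepted by expand_xi()
forcing_xi_at <- function(forcing, t, p) {
  xi <- forcing$xi
  if (is.null(xi)) return(1)
  if (is.array(xi) && length(dim(xi)) == 3) return(xi[t, , ])
  xi
}

#' Replace the environmental scalars of a forcing set
#' @param forcing a [forcing_set].
#' @param xi new scalars (see [forcing_set]).
#' @return a new `forcing_set`.
#' @export
set_xi <- function(forcing, xi) {
  forcing_set(forcing$years, forcing$U, xi)
}

#' Spatial domain of grid cells
#'
#' Describes the cells shared by all gridded fields: area, land-cover class
#' (six classes by default, in the spirit of global land-cover aggregation
#' schemes), peatland fraction and permafrost active-layer depth. The
#' active-layer depth is `NA` outside permafrost.
#'
#' @param area per-cell area (m^2), positive.
#' @param land_cover_class per-cell integer class code.
#' @param peat_fraction per-cell peatland area fraction in \[0, 1\].
#' @param active_layer_depth per-cell active-layer thickness (m); `NA` where
#'   there is no permafrost.
#' @param soil_reference_depth reference depth of soil-carbon accounting (m).
#' @param class_names optional names for the class codes.
#' @return A `grid_domain`.
#' @export
grid_domain <- function(area, land_cover_class, peat_fraction = 0,
                        active_layer_depth = NA_real_,
                        soil_reference_depth = 2.0, class_names = NULL) {
  n <- length(area)
  if (any(area <= 0)) stop("cell areas must be positive")
  peat_fraction <- rep_len(peat_fraction, n)
  if (any(peat_fraction < 0 | peat_fraction > 1))
    stop("peat_fraction must lie in [0, 1]")
  active_layer_depth <- rep_len(as.numeric(active_layer_depth), n)
  if (any(!is.na(active_layer_depth) & active_layer_depth <= 0))
    stop("active_layer_depth must be positive where defined")
  land_cover_class <- rep_len(as.integer(land_cover_class), n)
  structure(list(
    cells = data.frame(cell = seq_len(n), area = as.numeric(area),
                       land_cover_class = land_cover_class,
                       peat_fraction = peat_fraction,
                       active_layer_depth = active_layer_depth),
    soil_reference_depth = soil_reference_depth,
    class_names = class_names), class = "grid_domain")
}

#' @export
print.grid_domain <- function(x, ...) {
  cat("<grid_domain> ", nrow(x$cells), " cells, ",
      length(unique(x$cells$land_cover_class)), " land-cover classes, ",
      sum(x$cells$peat_fraction > 0), " peat cells, ",
      sum(!is.na(x$cells$active_layer_depth)), " permafrost cells\n", sep = "")
  invisible(x)
}
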