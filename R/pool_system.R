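#' Construct a linear carbon pool system
#'
#' A pool system is the traceability-framework representation of a carbon
#' cycle: influx `u` is allocated to pools by fractions `b`, each pool `j`
#' loses carbon at an effective rate `K[j] * xi[j]` (yr^-1), and a fraction
#' `A[i, j]` of the outflux leaving pool `j` enters pool `i`. Whatever part of
#' an outflux is not transferred (`1 - colSums(A)`) is respired out of the
#' system. The network must be acyclic in the direction vegetation -> litter ->
#' soil: vegetation pools never receive transfers from litter or soil pools.
#'
#' @param pool_names character vector of unique pool identifiers.
#' @param compartment per-pool label, one of `"vegetation"`, `"litter"`,
#'   `"soil"`.
#' @param aboveground per-pool logical; `TRUE` for pools counted in
#'   aboveground biomass (vegetation pools only).
#' @param b allocation fraction of influx entering each pool; must sum to 1
#'   and be zero outside the vegetation compartment.
#' @param A transfer fraction matrix, `A[i, j]` = fraction of the outflux of
#'   pool `j` entering pool `i`. Non-negative, zero diagonal, column sums
#'   at most 1.
#' @param K baseline exit rate per pool (yr^-1), strictly positive.
#'
#' @return An object of class `pool_system`.
#' @examples
#' sys <- pool_system("biomass", "vegetation", TRUE, b = 1,
#'                    A = matrix(0, 1, 1), K = 0.5)
#' steady_state(sys, u0 = 2)  # 4 gC m^-2
#' @export
pool_system <- function(pool_names, compartment, aboveground, b, A, K) {
  p <- length(pool_names)
  stopifnot(p >= 1, !anyDuplicated(pool_names))
  compartment <- match.arg(compartment, c("vegetation", "litter", "soil"),
                           several.ok = TRUE)
  if (length(compartment) != p) stop("compartment must have one label per pool")
  aboveground <- as.logical(aboveground)
  A <- as.matrix(A)
  stopifnot(length(aboveground) == p, length(b) == p, length(K) == p,
            all(dim(A) == c(p, p)))
  if (abs(sum(b) - 1) > 1e-10) stop("allocation fractions b must sum to 1")
  if (any(b < 0)) stop("allocation fractions b must be non-negative")
  if (any(b > 0 & compartment != "vegetation"))
    stop("influx may only be allocated to vegetation pools")
  if (any(A < 0)) stop("transfer fractions must be non-negative")
  if (any(diag(A) != 0)) stop("self-transfers A[j, j] must be zero")
  if (any(colSums(A) > 1 + 1e-10))
    stop("column sums of A must not exceed 1")
  if (any(K <= 0)) stop("baseline exit rates K must be strictly positive")
  if (any(aboveground & compartment != "vegetation"))
    stop("only vegetation pools can be flagged aboveground")
  # directed acyclic flow towards the soil: no transfers back into vegetation
  veg <- compartment == "vegetation"
  if (any(A[veg, !veg, drop = FALSE] > 0))
    stop("vegetation pools must not receive transfers from litter/soil pools")
  dimnames(A) <- list(pool_names, pool_names)
  structure(
    list(pool_names = pool_names,
         compartment = compartment,
         aboveground = aboveground,
         b = stats::setNames(as.numeric(b), pool_names),
         A = A,
         K = stats::setNames(as.numeric(K), pool_names),
         respired_fraction = stats::setNames(1 - colSums(A), pool_names)),
    class = "pool_system")
}

#' @export
print.pool_system <- function(x, ...) {
  cat("<pool_system> ", length(x$pool_names), " pools\n", sep = "")
  df <- data.frame(pool = x$pool_names, compartment = x$compartment,
                   aboveground = x$aboveground, b = x$b, K = x$K,
                   respired_fraction = round(x$respired_fraction, 4),
                   row.names = NULL)
  print(df, ...)
  invisible(x)
}

n_pools <- function(system) length(system$pool_names)

#' Default eight-pool carbon network
#'
#' Leaf, wood and root vegetation pools (leaf and wood aboveground), an
#' above- and a belowground litter pool, and fast, slow and passive soil
#' pools. Allocation, transfer fractions and baseline rates are set to give
#' realistic mid-latitude stocks (AGB of a few kgC m^-2, ~12 kgC m^-2 soil to
#' 2 m) at an influx of ~500 gC m^-2 yr^-1. Vegetation exits carry no
#' respiration (influx is net of autotrophic respiration); litter and soil
#' exits are partly respired heterotrophically.
#'
#' @return A [pool_system].
#' @export
default_pool_system <- function() {
  nm <- c("leaf", "wood", "root", "litter_ag", "litter_bg",
          "soil_fast", "soil_slow", "soil_passive")
  comp <- c("vegetation", "vegetation", "vegetation", "litter", "litter",
            "soil", "soil", "soil")
  ag <- c(TRUE, TRUE, FALSE, rep(FALSE, 5))
  b <- c(0.35, 0.30, 0.35, rep(0, 5))
  K <- c(0.4, 0.025, 0.25, 0.20, 0.25, 0.08, 0.01, 0.002)
  A <- matrix(0, 8, 8, dimnames = list(nm, nm))
  A["litter_ag", "leaf"] <- 1
  A["litter_ag", "wood"] <- 1
  A["litter_bg", "root"] <- 1
  A["soil_fast", "litter_ag"] <- 0.45
  A["soil_fast", "litter_bg"] <- 0.45
  A["soil_slow", "soil_fast"] <- 0.30
  A["soil_passive", "soil_slow"] <- 0.05
  pool_system(nm, comp, ag, b, A, K)
}

# Expand an environmental-scalar argument to an n_cells x n_pools matrix.
expand_xi <- function(xi, n_cells, p) {
  if (is.null(xi)) xi <- 1
  if (is.matrix(xi)) {
    stopifnot(nrow(xi) == n_cells, ncol(xi) == p)
    return(xi)
  }
  if (length(xi) == 1) return(matrix(xi, n_cells, p))
  if (length(xi) == p) return(matrix(xi, n_cells, p, byrow = TRUE))
  if (length(xi) == n_cells) return(matrix(xi, n_cells, p))
  stop("xi has incompatible dimensions")
}

#' Steady-state pool stocks under constant forcing
#'
#' Solves the per-cell linear balance: for every pool `p`,
#' `b_p u0 + sum_j A[p, j] K_j xi_j X_j = K_p xi_p X_p`, i.e. inputs equal
#' outputs. This exact solve is the emulator's spin-up: it replaces the
#' dynamic model's long stochastic initialisation with a reproducible
#' equilibrium.
#'
#' @param system a [pool_system].
#' @param u0 per-cell constant influx (gC m^-2 yr^-1), non-negative.
#' @param xi0 environmental rate scalar: scalar, per-pool vector, per-cell
#'   vector, or cells x pools matrix; strictly positive.
#' @return cells x pools matrix of equilibrium stocks (gC m^-2).
#' @export
steady_state <- function(system, u0, xi0 = 1) {
  u0 <- as.numeric(u0)
  if (any(u0 < 0)) stop("influx u0 must be non-negative")
  p <- n_pools(system)
  xi0 <- expand_xi(xi0, length(u0), p)
  if (any(xi0 <= 0)) stop("environmental scalars xi0 must be strictly positive")
  keff <- sweep(xi0, 2, system$K, `*`)
  bad <- which(colSums(keff <= 0 | !is.finite(keff)) > 0)
  if (length(bad))
    stop("pool(s) with zero or non-finite effective exit rate: ",
         paste(system$pool_names[bad], collapse = ", "))
  IA <- diag(p) - system$A
  # (I - A) diag(K xi) X = b u0  =>  X = u0 * [(I - A)^{-1} b] / (K xi)
  cvec <- tryCatch(solve(IA, system$b),
                   error = function(e) stop("singular flow matrix: ",
                                            conditionMessage(e)))
  X <- outer(u0, cvec) / keff
  colnames(X) <- system$pool_names
  X
}

#' Advance pool stocks by one annual step
#'
#' Explicit annual update: `F_j = K_j xi_j X_j` leaves each pool; a fraction
#' `A[i, j]` of it enters pool `i`, the remainder is respired; allocation
#' `b_p u` enters the vegetation pools. Effective annual exit fractions
#' `K * xi` above 1 would make the explicit step lose mass and are an error.
#'
#' @param system a [pool_system].
#' @param X_t cells x pools matrix of stocks (gC m^-2), non-negative.
#' @param u_t per-cell influx for the year (gC m^-2 yr^-1).
#' @param xi_t environmental scalar (see [steady_state]).
#' @return list with `X` (updated stocks), `outflux` (per-pool gross exits,
#'   cells x pools), `respired` (per-cell efflux leaving the system) and
#'   `influx` (per-cell influx used).
#' @export
step_annual <- function(system, X_t, u_t, xi_t = 1) {
  X_t <- as.matrix(X_t)
  p <- n_pools(system)
  if (ncol(X_t) != p) stop("X_t must have one column per pool")
  if (any(X_t < 0)) stop("stocks X_t must be non-negative")
  u_t <- as.numeric(u_t)
  stopifnot(length(u_t) == nrow(X_t))
  xi_t <- expand_xi(xi_t, nrow(X_t), p)
  keff <- sweep(xi_t, 2, system$K, `*`)
  if (any(keff > 1 + 1e-12))
    stop("effective annual exit fraction K*xi exceeds 1 for pool(s) ",
         paste(unique(system$pool_names[which(keff > 1 + 1e-12,
                                              arr.ind = TRUE)[, 2]]),
               collapse = ", "),
         "; sub-annual stepping would be required")
  Fout <- keff * X_t
  gains <- Fout %*% t(system$A)
  X_next <- X_t + outer(u_t, system$b) + gains - Fout
  X_next[X_next < 0 & X_next > -1e-12] <- 0 # numerical underflow only
  respired <- drop(Fout %*% system$respired_fraction)
  list(X = X_next, outflux = Fout, respired = respired, influx = u_t)
}

#' Run the emulator over an annual forcing series
#'
#' Integrates [step_annual] over all years of a forcing set. Stocks are
#' recorded at the end of each year; the initial state is carried in the
#' result for mass-balance checks.
#'
#' @param system a [pool_system].
#' @param X0 cells x pools initial stocks, typically from [steady_state] of
#'   the spin-up climatology (see [spinup_state]).
#' @param forcing a [forcing_set].
#' @return A `state_trajectory`: list with `years`, `X` (years x cells x
#'   pools array of end-of-year stocks), `X0`, `influx_used` (years x cells),
#'   `efflux_respired` (years x cells), `efflux_by_pool` (years x cells x
#'   pools).
#' @export
run_transient <- function(system, X0, forcing) {
  stopifnot(inherits(forcing, "forcing_set"))
  X0 <- as.matrix(X0)
  p <- n_pools(system)
  nT <- length(forcing$years)
  nC <- ncol(forcing$U)
  if (nrow(X0) != nC || ncol(X0) != p)
    stop("X0 dimensions do not match forcing (cells x pools expected)")
  X <- array(NA_real_, c(nT, nC, p),
             dimnames = list(forcing$years, NULL, system$pool_names))
  effp <- array(NA_real_, c(nT, nC, p))
  infl <- matrix(NA_real_, nT, nC)
  resp <- matrix(NA_real_, nT, nC)
  Xc <- X0
  for (t in seq_len(nT)) {
    st <- step_annual(system, Xc, forcing$U[t, ], forcing_xi_at(forcing, t, p))
    Xc <- st$X
    X[t, , ] <- Xc
    effp[t, , ] <- st$outflux
    infl[t, ] <- st$influx
    resp[t, ] <- st$respired
  }
  structure(list(years = forcing$years, X = X, X0 = X0, influx_used = infl,
                 efflux_respired = resp, efflux_by_pool = effp),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory> years ", min(x$years), "-", max(x$years),
      ", ", dim(x$X)[2], " cells, ", dim(x$X)[3], " pools\n", sep = "")
  invisible(x)
}

#' Per-year mass-balance error of a trajectory
#'
#' For every cell and year the change in total stored carbon must equal
#' influx minus respired efflux. Returns the years x cells matrix of
#' absolute errors scaled by `max(1, total stock)`.
#' @param trajectory a `state_trajectory`.
#' @return matrix of relative mass-balance errors.
#' @export
mass_balance_error <- function(trajectory) {
  tot <- apply(trajectory$X, c(1, 2), sum) # years x cells
  prev <- rbind(rowSums(trajectory$X0), tot[-nrow(tot), , drop = FALSE])
  err <- abs((tot - prev) - (trajectory$influx_used - trajectory$efflux_respired))
  err / pmax(1, tot)
}

#' Spin-up state from the leading climatological window of a forcing set
#'
#' Averages influx and environmental scalars over the first `window` years
#' (default 30, echoing an early-20th-century climatology) and solves for the
#' corresponding steady state.
#'
#' @param system a [pool_system].
#' @param forcing a [forcing_set].
#' @param window number of leading years to average (default 30, capped at
#'   the series length).
#' @return cells x pools matrix of initial stocks.
#' @export
spinup_state <- function(system, forcing, window = 30L) {
  window <- min(as.integer(window), length(forcing$years))
  if (window < 1) stop("spin-up window must contain at least one year")
  u0 <- colMeans(forcing$U[seq_len(window), , drop = FALSE])
  p <- n_pools(system)
  xis <- lapply(seq_len(window), function(t) forcing_xi_at(forcing, t, p))
  xi0 <- Reduce(`+`, lapply(xis, function(x)
    expand_xi(x, ncol(forcing$U), p))) / window
  steady_state(system, u0, xi0)
}

#' Global annual net biome production of a trajectory
#'
#' NBP is the net land-atmosphere exchange: area-weighted global sum of
#' influx minus respired efflux, converted from gC to PgC (1 Pg = 1e15 g).
#' By mass balance it equals the year-over-year change in total stored
#' carbon.
#'
#' @param trajectory a `state_trajectory`.
#' @param domain a [grid_domain] sharing the trajectory's cells.
#' @return numeric vector of annual NBP (PgC yr^-1), named by year.
#' @export
nbp_series <- function(trajectory, domain) {
  stopifnot(inherits(domain, "grid_domain"))
  if (nrow(domain$cells) != dim(trajectory$X)[2])
    stop("trajectory and domain must share cells")
  net <- trajectory$influx_used - trajectory$efflux_respired  # years x cells
  nbp <- drop(net %*% domain$cells$area) * 1e-15
  stats::setNames(nbp, trajectory$years)
}

#' Time-averaged aboveground biomass and soil carbon stocks
#'
#' AGB sums vegetation pools flagged aboveground; soil carbon sums litter
#' and soil pools (observational soil-carbon products do not separate litter
#' from mineral soil). Both are averaged over the requested year window.
#'
#' @param trajectory a `state_trajectory`.
#' @param system the [pool_system] that produced it.
#' @param window integer vector of years to average over (must be present in
#'   the trajectory).
#' @return list with per-cell numeric vectors `agb` and `soil_c` (gC m^-2).
#' @export
stock_summaries <- function(trajectory, system, window) {
  idx <- match(window, trajectory$years)
  if (length(idx) == 0 || anyNA(idx))
    stop("window years absent from trajectory")
  ag <- system$aboveground
  so <- system$compartment %in% c("litter", "soil")
  Xw <- trajectory$X[idx, , , drop = FALSE]
  agb <- colMeans(apply(Xw[, , ag, drop = FALSE], c(1, 2), sum))
  soil <- colMeans(apply(Xw[, , so, drop = FALSE], c(1, 2), sum))
  list(agb = agb, soil_c = soil)
}
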