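# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 31 + k) %% 2^31)

#' Configuration of the synthetic study world
#'
#' Collects every knob of the generator: grid and class layout, simulation
#' span, the truth influx field (smooth spatial gradient, linear trend,
#' multiplicative AR(1) interannual variability), the model world's
#' per-class bias factors on influx and turnover, the observation-noise
#' levels of the pseudo-observation datasets, and peat/permafrost extent.
#' Every stochastic draw is derived from `seed`.
#'
#' @param seed integer seed (mandatory; all generator randomness derives
#'   from it).
#' @param nx,ny grid dimensions (default 20 x 20).
#' @param n_classes number of contiguous land-cover classes (default 6).
#' @param years simulation span (default 1901:2014).
#' @param common_period trend-fitting period of the flux-tower-like
#'   products (default 1982:2011).
#' @param stock_window years over which stocks and apparent rates are
#'   averaged (default 2000:2009, the contemporary-data epoch).
#' @param npp_range low/high end of the spatial productivity gradient
#'   (gC m^-2 yr^-1).
#' @param trend_slope linear influx trend (gC m^-2 yr^-2).
#' @param iav_sd,iav_ar1 standard deviation and lag-1 autocorrelation of the
#'   multiplicative lognormal interannual variability.
#' @param bias_influx,bias_veg_turnover,bias_soil_turnover per-class
#'   multiplicative model biases (length `n_classes`, all > 0).
#' @param cue per-class carbon-use efficiency (NPP/GPP) used to define GPP.
#' @param influx_roster data.frame describing the influx pseudo-datasets:
#'   columns `name`, `kind` (NPP/GPP), `start`, `end`, `sd`. The default
#'   mimics one satellite NPP product (2000-2014) and four flux-tower GPP
#'   upscalings (1982-2011).
#' @param agb_sd,soil_sd per-dataset multiplicative noise sd of the two AGB
#'   and two soil-carbon pseudo-datasets.
#' @param noise_model `"lognormal"` (default; stocks and fluxes are positive
#'   and skewed) or `"gaussian"` (additive, sd relative to the truth value).
#' @param mask_fraction fraction of cells masked (NA) per pseudo-dataset,
#'   drawn independently so shared-area logic is exercised.
#' @param peat_cell_fraction,permafrost_cell_fraction fractions of cells
#'   designated peatland / permafrost.
#' @param cell_area cell area in m^2 (default 3e11; 400 cells then total
#'   1.2e14 m^2, about the global land area).
#' @param soil_layer_bounds depth bounds (m) of the layered truth soil
#'   carbon.
#' @param soil_efold e-folding depth (m) of the soil-carbon profile.
#' @param netflux_noise_sd additive noise sd of the net-flux reference
#'   (PgC yr^-1).
#' @param netflux_halfwidth stated uncertainty half-width of the net-flux
#'   reference (PgC yr^-1, default 0.8).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed,
                         nx = 20L, ny = 20L, n_classes = 6L,
                         years = 1901:2014,
                         common_period = 1982:2011,
                         stock_window = 2000:2009,
                         npp_range = c(200, 1100),
                         trend_slope = 0.5,
                         iav_sd = 0.05, iav_ar1 = 0.3,
                         bias_influx = c(1.25, 0.90, 1.10, 0.85, 1.15, 0.95),
                         bias_veg_turnover = c(1.20, 0.95, 1.05, 0.90, 1.10, 1.00),
                         bias_soil_turnover = c(1.15, 0.90, 1.10, 0.95, 0.85, 1.05),
                         cue = c(0.45, 0.50, 0.45, 0.50, 0.55, 0.50),
                         influx_roster = NULL,
                         agb_sd = c(0.15, 0.20),
                         soil_sd = c(0.25, 0.30),
                         noise_model = c("lognormal", "gaussian"),
                         mask_fraction = 0.02,
                         peat_cell_fraction = 0.10,
                         permafrost_cell_fraction = 0.15,
                         cell_area = 3e11,
                         soil_layer_bounds = c(0, 0.2, 0.4, 0.6, 0.8, 1, 1.5, 2),
                         soil_efold = 0.5,
                         netflux_noise_sd = 0.2,
                         netflux_halfwidth = 0.8) {
  if (missing(seed)) stop("a seed is mandatory")
  noise_model <- match.arg(noise_model)
  if (is.null(influx_roster))
    influx_roster <- data.frame(
      name = c("npp_sat", "gpp_ml_a", "gpp_ml_b", "gpp_ml_c", "gpp_ml_d"),
      kind = c("NPP", "GPP", "GPP", "GPP", "GPP"),
      start = c(2000L, 1982L, 1982L, 1982L, 1982L),
      end = c(2014L, 2011L, 2011L, 2011L, 2011L),
      sd = rep(0.10, 5), stringsAsFactors = FALSE)
  cfg <- list(seed = as.integer(seed), nx = as.integer(nx), ny = as.integer(ny),
              n_classes = as.integer(n_classes), years = as.integer(years),
              common_period = as.integer(common_period),
              stock_window = as.integer(stock_window),
              npp_range = npp_range, trend_slope = trend_slope,
              iav_sd = iav_sd, iav_ar1 = iav_ar1,
              bias_influx = rep_len(bias_influx, n_classes),
              bias_veg_turnover = rep_len(bias_veg_turnover, n_classes),
              bias_soil_turnover = rep_len(bias_soil_turnover, n_classes),
              cue = rep_len(cue, n_classes),
              influx_roster = influx_roster,
              agb_sd = agb_sd, soil_sd = soil_sd, noise_model = noise_model,
              mask_fraction = mask_fraction,
              peat_cell_fraction = peat_cell_fraction,
              permafrost_cell_fraction = permafrost_cell_fraction,
              cell_area = cell_area,
              soil_layer_bounds = soil_layer_bounds, soil_efold = soil_efold,
              netflux_noise_sd = netflux_noise_sd,
              netflux_halfwidth = netflux_halfwidth)
  sds <- c(cfg$iav_sd, cfg$influx_roster$sd, cfg$agb_sd, cfg$soil_sd,
           cfg$netflux_noise_sd, cfg$mask_fraction)
  if (any(sds < 0)) stop("noise levels and fractions must be non-negative")
  if (any(c(cfg$bias_influx, cfg$bias_veg_turnover,
            cfg$bias_soil_turnover) <= 0))
    stop("bias factors must be strictly positive")
  structure(cfg, class = "synth_config")
}

#' Generate the spatial domain
#'
#' Cells are laid out row-major on an `nx x ny` grid with equal areas and
#' contiguous land-cover class blocks. Peatland and permafrost cells are
#' placed (deterministically under the seed) in the first two classes, the
#' "high-latitude" end of the grid, with peat fractions in 0.3-0.9 and
#' active-layer depths in 0.4-1.5 m.
#'
#' @param config a [synth_config].
#' @return A [grid_domain].
#' @export
make_domain <- function(config) {
  n <- config$nx * config$ny
  if (config$n_classes > n) stop("more classes than cells")
  cls <- as.integer(cut(seq_len(n), config$n_classes, labels = FALSE))
  with_seed(sub_seed(config$seed, 1L), {
    highlat <- which(cls <= 2L)
    n_peat <- round(config$peat_cell_fraction * n)
    n_perm <- round(config$permafrost_cell_fraction * n)
    peat <- rep(0, n)
    alt <- rep(NA_real_, n)
    if (n_peat > 0) {
      pc <- sample(highlat, min(n_peat, length(highlat)))
      peat[pc] <- stats::runif(length(pc), 0.3, 0.9)
    }
    if (n_perm > 0) {
      fc <- sample(highlat, min(n_perm, length(highlat)))
      alt[fc] <- stats::runif(length(fc), 0.4, 1.5)
    }
    grid_domain(area = rep(config$cell_area, n), land_cover_class = cls,
                peat_fraction = peat, active_layer_depth = alt,
                soil_reference_depth = max(config$soil_layer_bounds),
                class_names = paste0("class_", seq_len(config$n_classes)))
  })
}

#' Generate the synthetic truth
#'
#' Truth NPP is a smooth spatial productivity gradient times a linear trend
#' plus multiplicative lognormal AR(1) interannual variability. Truth
#' stocks follow from the pool system: exact steady state of the leading
#' 30-year climatology, then a transient run over the full span. The truth
#' soil carbon is also distributed over depth layers with an exponential
#' profile, so the peat/permafrost depth adjustment has structure to cut.
#'
#' @param config a [synth_config].
#' @param domain a [grid_domain] from [make_domain].
#' @param system a [pool_system] (default [default_pool_system]).
#' @return list with `forcing` ([forcing_set], xi = 1), `trajectory`
#'   (`state_trajectory`), `npp` (years x cells), `agb`, `soil_c` (per-cell
#'   window means, gC m^-2), `soil_layered` (cells x layers, kgC m^-2),
#'   `layer_bounds`, `system`, `window`.
#' @export
make_truth <- function(config, domain, system = default_pool_system()) {
  n <- nrow(domain$cells)
  nT <- length(config$years)
  xf <- ((seq_len(n) - 1) %% config$nx) / max(1, config$nx - 1)
  yf <- ((seq_len(n) - 1) %/% config$nx) / max(1, config$ny - 1)
  grad <- config$npp_range[1] +
    diff(config$npp_range) * (0.6 * yf + 0.4 * (0.5 - 0.5 * cos(pi * xf)))
  trend <- config$trend_slope * (config$years - config$years[1])
  base <- outer(rep(1, nT), grad) + outer(trend, rep(1, n))
  iav <- with_seed(sub_seed(config$seed, 2L), {
    if (config$iav_sd == 0) matrix(1, nT, n) else {
      e <- matrix(0, nT, n)
      innov_sd <- config$iav_sd * sqrt(1 - config$iav_ar1^2)
      e[1, ] <- stats::rnorm(n, 0, config$iav_sd)
      for (t in 2:nT)
        e[t, ] <- config$iav_ar1 * e[t - 1, ] + stats::rnorm(n, 0, innov_sd)
      exp(e - config$iav_sd^2 / 2)
    }
  })
  npp <- pmax(base, 0) * iav
  rownames(npp) <- config$years
  forcing <- forcing_set(config$years, npp, xi = NULL)
  X0 <- spinup_state(system, forcing)
  traj <- run_transient(system, X0, forcing)
  stocks <- stock_summaries(traj, system, config$stock_window)
  zb <- config$soil_layer_bounds
  Fz <- (1 - exp(-zb / config$soil_efold)) /
    (1 - exp(-max(zb) / config$soil_efold))
  frac <- diff(Fz)
  soil_layered <- outer(stocks$soil_c / 1000, frac) # gC -> kgC m^-2
  list(forcing = forcing, trajectory = traj, npp = npp,
       agb = stocks$agb, soil_c = stocks$soil_c,
       soil_layered = soil_layered, layer_bounds = zb,
       system = system, window = config$stock_window)
}

#' Generate the biased model world
#'
#' Stands in for the fully dynamic simulation the emulator traces:
#' simulated NPP is the truth times a per-class influx bias; the
#' environmental scalars of vegetation and litter+soil pools carry
#' per-class turnover biases; simulated GPP is NPP divided by the per-class
#' carbon-use efficiency. The model-world trajectory runs through the same
#' emulator from its own spin-up.
#'
#' @param truth output of [make_truth].
#' @param config a [synth_config].
#' @param domain a [grid_domain].
#' @return list with `npp_sim`, `gpp_sim` (years x cells), `xi` (cells x
#'   pools), `forcing`, `trajectory`, `agb`, `soil_c`, `system`.
#' @export
make_model_world <- function(truth, config, domain) {
  system <- truth$system
  cls <- domain$cells$land_cover_class
  b_in <- config$bias_influx[cls]
  npp_sim <- sweep(truth$npp, 2, b_in, `*`)
  gpp_sim <- sweep(npp_sim, 2, config$cue[cls], `/`)
  p <- n_pools(system)
  xi <- matrix(1, nrow(domain$cells), p)
  veg <- system$compartment == "vegetation"
  xi[, veg] <- config$bias_veg_turnover[cls]
  xi[, !veg] <- config$bias_soil_turnover[cls]
  forcing <- forcing_set(config$years, npp_sim, xi)
  X0 <- spinup_state(system, forcing)
  traj <- run_transient(system, X0, forcing)
  stocks <- stock_summaries(traj, system, config$stock_window)
  list(npp_sim = npp_sim, gpp_sim = gpp_sim, xi = xi, forcing = forcing,
       trajectory = traj, agb = stocks$agb, soil_c = stocks$soil_c,
       system = system)
}

apply_noise <- function(values, sd, model, seed) {
  if (sd == 0) return(values)
  with_seed(seed, {
    if (model == "lognormal") {
      values * exp(matrix(stats::rnorm(length(values), 0, sd),
                          nrow(as.matrix(values))) - sd^2 / 2)
    } else {
      values + matrix(stats::rnorm(length(values), 0, sd),
                      nrow(as.matrix(values))) * values
    }
  })
}

mask_cells <- function(n, fraction, seed) {
  if (fraction <= 0) return(integer(0))
  with_seed(seed, sample.int(n, round(fraction * n)))
}

#' Generate pseudo-observation datasets
#'
#' Emulates the independent observational products of the real analysis:
#' influx datasets per the configured roster (one satellite-NPP-like, four
#' flux-tower-GPP-like by default), two AGB datasets and two layered
#' soil-carbon datasets. Each is the truth times independent multiplicative
#' lognormal noise (mean one) with its own mask of missing cells, so pairs
#' of datasets disagree by construction and shared-area logic is exercised.
#'
#' @param truth output of [make_truth].
#' @param config a [synth_config].
#' @param domain a [grid_domain].
#' @return list (a dataset registry) with elements `influx` (list of
#'   [influx_dataset]), `agb`, `soil` (lists of [stock_dataset], soil
#'   layered).
#' @export
make_pseudo_obs <- function(truth, config, domain) {
  n <- nrow(domain$cells)
  cls <- domain$cells$land_cover_class
  roster <- config$influx_roster
  influx <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    yrs <- roster$start[i]:roster$end[i]
    idx <- match(yrs, config$years)
    if (anyNA(idx)) stop("influx roster years outside the simulation span")
    base <- truth$npp[idx, , drop = FALSE]
    if (roster$kind[i] == "GPP") base <- sweep(base, 2, config$cue[cls], `/`)
    vals <- apply_noise(base, roster$sd[i], config$noise_model,
                        sub_seed(config$seed, 10L + i))
    vals[, mask_cells(n, config$mask_fraction, sub_seed(config$seed, 30L + i))] <- NA
    influx[[i]] <- influx_dataset(roster$name[i], roster$kind[i], yrs, vals)
  }
  names(influx) <- roster$name
  agb_names <- c("agb_vod", "agb_inv")
  agb <- lapply(seq_along(config$agb_sd), function(i) {
    vals <- drop(apply_noise(matrix(truth$agb, 1), config$agb_sd[i],
                             config$noise_model, sub_seed(config$seed, 20L + i)))
    vals[mask_cells(n, config$mask_fraction, sub_seed(config$seed, 40L + i))] <- NA
    stock_dataset(agb_names[i], "AGB", vals)
  })
  names(agb) <- agb_names[seq_along(agb)]
  soil_names <- c("soil_survey", "soil_maps")
  soil <- lapply(seq_along(config$soil_sd), function(i) {
    lay <- apply_noise(truth$soil_layered, config$soil_sd[i],
                       config$noise_model, sub_seed(config$seed, 25L + i))
    lay[mask_cells(n, config$mask_fraction, sub_seed(config$seed, 45L + i)), ] <- NA
    stock_dataset(soil_names[i], "soilC", rowSums(lay), layered = lay,
                  layer_bounds = truth$layer_bounds)
  })
  names(soil) <- soil_names[seq_along(soil)]
  list(influx = influx, agb = agb, soil = soil)
}

#' Generate the net land-flux reference series
#'
#' The truth NBP plus small additive Gaussian noise, carrying a constant
#' stated uncertainty half-width (attribute `halfwidth`, default 0.8 PgC).
#'
#' @param truth output of [make_truth].
#' @param config a [synth_config].
#' @param domain a [grid_domain].
#' @return named numeric vector (PgC yr^-1) with attribute `halfwidth`.
#' @export
make_net_flux_reference <- function(truth, config, domain) {
  nbp <- nbp_series(truth$trajectory, domain)
  noisy <- with_seed(sub_seed(config$seed, 50L),
                     nbp + stats::rnorm(length(nbp), 0, config$netflux_noise_sd))
  attr(noisy, "halfwidth") <- config$netflux_halfwidth
  noisy
}
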