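# Fixtures and independent oracles shared across the suite.

# A single-pool system: everything respired on exit.
one_pool <- function(K = 0.5) {
  pool_system("biomass", "vegetation", TRUE, b = 1,
              A = matrix(0, 1, 1), K = K)
}

# Two-pool chain: influx into pool 1, half of its outflux feeds pool 2.
two_pool_chain <- function() {
  A <- matrix(0, 2, 2)
  A[2, 1] <- 0.5
  pool_system(c("veg", "soil"), c("vegetation", "soil"), c(TRUE, FALSE),
              b = c(1, 0), A = A, K = c(1, 0.25))
}

# Random valid system with <= 5 pools: compartments ordered vegetation ->
# litter -> soil, transfers strictly "downhill" so the flow is acyclic.
random_system <- function(p, seed) {
  set.seed(seed)
  n_veg <- sample(seq_len(max(1, p - 1)), 1)
  comp <- c(rep("vegetation", n_veg),
            sample(c("litter", "soil"), p - n_veg, replace = TRUE))
  comp[comp != "vegetation"] <- sort(comp[comp != "vegetation"],
                                     decreasing = TRUE) # litter before soil
  b <- numeric(p)
  b[seq_len(n_veg)] <- stats::runif(n_veg)
  b <- b / sum(b)
  A <- matrix(0, p, p)
  for (j in seq_len(p - 1)) {
    targets <- which(seq_len(p) > j & comp != "vegetation")
    if (!length(targets)) next
    w <- stats::runif(length(targets))
    A[targets, j] <- w / sum(w) * stats::runif(1, 0.2, 0.9)
  }
  K <- stats::runif(p, 0.02, 0.8)
  pool_system(paste0("p", seq_len(p)), comp, comp == "vegetation" &
                stats::runif(p) < 0.5, b, A, K)
}

# Brute-force bookkeeping oracle: moves carbon flux by flux, pool by pool,
# cell by cell -- independent of the vectorised implementation.
oracle_step <- function(system, X, u, xi) {
  p <- length(system$K)
  nc <- nrow(X)
  Xn <- X
  respired <- numeric(nc)
  for (cc in seq_len(nc)) {
    for (j in seq_len(p)) {
      Fj <- system$K[j] * xi[cc, j] * X[cc, j]
      Xn[cc, j] <- Xn[cc, j] - Fj
      for (i in seq_len(p)) Xn[cc, i] <- Xn[cc, i] + system$A[i, j] * Fj
      respired[cc] <- respired[cc] + system$respired_fraction[j] * Fj
    }
    for (j in seq_len(p)) Xn[cc, j] <- Xn[cc, j] + system$b[j] * u[cc]
  }
  list(X = Xn, respired = respired)
}

# Small, fast synthetic world shared by pipeline-level tests.
small_config <- function(seed = 11, ...) {
  args <- list(seed = seed, nx = 8, ny = 5, n_classes = 3,
               bias_influx = c(1.25, 0.9, 1.1),
               bias_veg_turnover = c(1.2, 0.95, 1.05),
               bias_soil_turnover = c(1.15, 0.9, 1.1),
               cue = c(0.45, 0.5, 0.55),
               influx_roster = data.frame(
                 name = c("npp_sat", "gpp_ml_a"), kind = c("NPP", "GPP"),
                 start = c(2000L, 1982L), end = c(2014L, 2011L),
                 sd = c(0.1, 0.1), stringsAsFactors = FALSE),
               agb_sd = c(0.15, 0.20), soil_sd = c(0.25, 0.30),
               # 40 cells instead of 400: a tenth of the land area, so a
               # tenth of the net-flux noise keeps signal-to-noise realistic
               netflux_noise_sd = 0.02)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

# Equilibrium recovery conditions: constant truth forcing, exact
# observations, correct model influx, biased model turnover. The
# influx/stock quotient is an exact rate only at steady state, so this is
# where fusing data-derived rates must reproduce the truth.
recovery_config <- function(seed = 5) {
  synth_config(seed = seed, trend_slope = 0, iav_sd = 0,
               bias_influx = rep(1, 6),
               influx_roster = data.frame(
                 name = c("npp_sat", "gpp_ml_a"), kind = c("NPP", "GPP"),
                 start = c(2000L, 1982L), end = c(2014L, 2011L),
                 sd = c(0, 0), stringsAsFactors = FALSE),
               agb_sd = 0, soil_sd = 0, mask_fraction = 0,
               peat_cell_fraction = 0, permafrost_cell_fraction = 0,
               netflux_noise_sd = 0)
}
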