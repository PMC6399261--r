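# Pipeline stages over an on-disk bundle directory. Each stage is callable
# from R or from the thin command-line wrapper in inst/cli/carbonfuse.R;
# every output is reproducible from the config and seed alone.

#' Generate a synthetic dataset bundle on disk
#'
#' Writes domain, truth, model world, pseudo-observations and the net-flux
#' reference to `out_dir` in the package's self-describing TSV container,
#' plus a `manifest.json` listing every file with its checksum and the
#' seed.
#'
#' @param config a [synth_config] (or a path to a YAML file holding its
#'   arguments, `seed` included).
#' @param out_dir output directory (created if needed).
#' @param system a [pool_system] (default [default_pool_system]).
#' @return invisibly, the in-memory bundle (list with `config`, `system`,
#'   `domain`, `truth`, `world`, `obs`, `net_flux_ref`, `dir`).
#' @export
pipeline_synth <- function(config, out_dir, system = default_pool_system()) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    if (!is.null(args$influx_roster))
      args$influx_roster <- as.data.frame(args$influx_roster,
                                          stringsAsFactors = FALSE)
    config <- do.call(synth_config, args)
  }
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable")
  domain <- make_domain(config)
  truth <- make_truth(config, domain, system)
  world <- make_model_world(truth, config, domain)
  obs <- make_pseudo_obs(truth, config, domain)
  net_flux_ref <- make_net_flux_reference(truth, config, domain)

  cfg_out <- unclass(config)
  cfg_out$influx_roster <- as.list(config$influx_roster)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  write_pool_system(system, file.path(out_dir, "system.yaml"))
  write_domain(domain, file.path(out_dir, "domain.tsv"))
  for (d in c("truth", "model", "obs")) dir.create(file.path(out_dir, d),
                                                   showWarnings = FALSE)
  wf <- function(values, sub, name, units, kind = "", extra = list())
    write_grid_field(values, file.path(out_dir, sub, paste0(name, ".tsv")),
                     name, units, kind, extra)
  wf(truth$npp, "truth", "npp", "gC m-2 yr-1", "NPP")
  wf(truth$agb, "truth", "agb", "gC m-2", "AGB")
  wf(truth$soil_c, "truth", "soil_c", "gC m-2", "soilC")
  wf(truth$soil_layered, "truth", "soil_layered", "kgC m-2 per layer",
     "soilC", extra = list(layer_bounds = truth$layer_bounds,
                           note = "rows are cells, columns depth layers"))
  wf(nbp_series(truth$trajectory, domain), "truth", "nbp", "PgC yr-1")
  wf(world$npp_sim, "model", "npp_sim", "gC m-2 yr-1", "NPP")
  wf(world$gpp_sim, "model", "gpp_sim", "gC m-2 yr-1", "GPP")
  wf(world$xi, "model", "xi", "dimensionless", "",
     extra = list(note = "rows are cells, columns pools"))
  for (d in obs$influx)
    wf(d$values, "obs", paste0("influx_", d$name), "gC m-2 yr-1", d$kind)
  for (d in obs$agb)
    wf(d$values, "obs", paste0("agb_", d$name), "gC m-2", "AGB")
  for (d in obs$soil)
    wf(d$layered, "obs", paste0("soil_", d$name), "kgC m-2 per layer",
       "soilC", extra = list(layer_bounds = d$layer_bounds))
  wf(net_flux_ref, "truth", "net_flux_ref", "PgC yr-1", "",
     extra = list(halfwidth = attr(net_flux_ref, "halfwidth")))
  write_manifest(out_dir, config$seed)
  invisible(list(config = config, system = system, domain = domain,
                 truth = truth, world = world, obs = obs,
                 net_flux_ref = net_flux_ref, dir = out_dir))
}

#' Read a synthetic bundle back from disk
#' @param dir bundle directory written by [pipeline_synth].
#' @return list with `config`, `system`, `domain`, `world` (forcing fields
#'   only), `obs`, `net_flux_ref`, `truth_npp`, `dir`.
#' @export
read_bundle <- function(dir) {
  args <- yaml::read_yaml(file.path(dir, "config.yaml"))
  args$influx_roster <- as.data.frame(args$influx_roster,
                                      stringsAsFactors = FALSE)
  config <- do.call(synth_config, args)
  system <- read_pool_system(file.path(dir, "system.yaml"))
  domain <- read_domain(file.path(dir, "domain.tsv"))
  rf <- function(...) read_grid_field(file.path(dir, ...))
  world <- list(npp_sim = rf("model", "npp_sim.tsv"),
                gpp_sim = rf("model", "gpp_sim.tsv"),
                xi = unname(rf("model", "xi.tsv")), system = system)
  rownames(world$xi) <- NULL
  roster <- config$influx_roster
  influx <- lapply(seq_len(nrow(roster)), function(i) {
    v <- rf("obs", paste0("influx_", roster$name[i], ".tsv"))
    influx_dataset(roster$name[i], roster$kind[i],
                   as.integer(rownames(v)), v)
  })
  names(influx) <- roster$name
  agb_files <- list.files(file.path(dir, "obs"), "^agb_")
  agb <- lapply(agb_files, function(f) {
    v <- rf("obs", f)
    stock_dataset(attr(v, "meta")$name, "AGB", v)
  })
  names(agb) <- sub("^agb_(.*)\\.tsv$", "\\1", agb_files)
  for (i in seq_along(agb)) agb[[i]]$name <- names(agb)[i]
  soil_files <- list.files(file.path(dir, "obs"), "^soil_")
  soil <- lapply(soil_files, function(f) {
    v <- rf("obs", f)
    bounds <- as.numeric(strsplit(attr(v, "meta")$layer_bounds, " ")[[1]])
    lay <- as.matrix(v)
    stock_dataset(sub("^soil_(.*)\\.tsv$", "\\1", f), "soilC",
                  rowSums(lay), layered = lay, layer_bounds = bounds)
  })
  names(soil) <- sub("^soil_(.*)\\.tsv$", "\\1", soil_files)
  nfr <- rf("truth", "net_flux_ref.tsv")
  attr(nfr, "halfwidth") <- as.numeric(attr(nfr, "meta")$halfwidth)
  list(config = config, system = system, domain = domain, world = world,
       obs = list(influx = influx, agb = agb, soil = soil),
       net_flux_ref = nfr, truth_npp = rf("truth", "npp.tsv"), dir = dir)
}

#' Run fusion realizations over a bundle
#'
#' Enumerates the ensemble from the registered datasets (or a supplied
#' subset), executes each realization, and writes per-realization AGB,
#' soil carbon and NBP under `runs/<id>/`. The unfused model world is run
#' and written as `runs/unfused/`. Completed realizations (all three
#' output files present) are skipped, so an interrupted run resumes.
#'
#' @param dir bundle directory from [pipeline_synth].
#' @param realizations optional data.frame as from [build_ensemble]; by
#'   default the full ensemble over all registered datasets.
#' @return invisibly, list with the ensemble table and the named outputs.
#' @export
pipeline_run <- function(dir, realizations = NULL) {
  b <- read_bundle(dir)
  config <- b$config
  if (is.null(realizations))
    realizations <- build_ensemble(names(b$obs$influx), names(b$obs$agb),
                                   names(b$obs$soil))
  run_dir <- file.path(dir, "runs")
  dir.create(run_dir, showWarnings = FALSE)
  utils::write.table(realizations, file.path(run_dir, "ensemble.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  world <- b$world
  years <- config$years
  outputs <- list()
  write_run <- function(id, agb, soil_c, nbp) {
    d <- file.path(run_dir, id)
    dir.create(d, showWarnings = FALSE)
    write_grid_field(agb, file.path(d, "agb.tsv"), "agb", "gC m-2", "AGB")
    write_grid_field(soil_c, file.path(d, "soil_c.tsv"), "soil_c", "gC m-2",
                     "soilC")
    write_grid_field(nbp, file.path(d, "nbp.tsv"), "nbp", "PgC yr-1")
  }
  done <- function(id) all(file.exists(file.path(run_dir, id,
                                                 c("agb.tsv", "soil_c.tsv",
                                                   "nbp.tsv"))))
  # unfused model world
  forcing <- forcing_set(years, world$npp_sim, world$xi)
  traj <- run_transient(world$system, spinup_state(world$system, forcing),
                        forcing)
  st <- stock_summaries(traj, world$system, config$stock_window)
  outputs$unfused <- list(agb = st$agb, soil_c = st$soil_c,
                          nbp = nbp_series(traj, b$domain))
  if (!done("unfused"))
    write_run("unfused", st$agb, st$soil_c, outputs$unfused$nbp)
  for (k in seq_len(nrow(realizations))) {
    id <- realizations$id[k]
    if (done(id)) {
      outputs[[id]] <- read_run(run_dir, id)
      next
    }
    res <- run_realization(realizations[k, ], world, b$obs, b$domain,
                           years = years,
                           stock_window = config$stock_window)
    outputs[[id]] <- list(agb = res$agb, soil_c = res$soil_c, nbp = res$nbp)
    write_run(id, res$agb, res$soil_c, res$nbp)
  }
  invisible(list(ensemble = realizations, outputs = outputs))
}

read_run <- function(run_dir, id) {
  list(agb = as.numeric(read_grid_field(file.path(run_dir, id, "agb.tsv"))),
       soil_c = as.numeric(read_grid_field(file.path(run_dir, id,
                                                     "soil_c.tsv"))),
       nbp = read_grid_field(file.path(run_dir, id, "nbp.tsv")))
}

#' Evaluate completed realizations of a bundle
#'
#' Reads the per-realization outputs, computes agreement metrics against
#' the pseudo-observations (per class and globally), the data-vs-data
#' baseline, the NBP-vs-reference metrics and the IoA ranking, and writes
#' them as tidy TSV tables under `reports/`.
#'
#' @param dir bundle directory with completed `runs/`.
#' @param eval_years years of the NBP comparison (default the config's
#'   common period).
#' @return the list from [evaluate_realizations].
#' @export
pipeline_evaluate <- function(dir, eval_years = NULL) {
  b <- read_bundle(dir)
  run_dir <- file.path(dir, "runs")
  if (!dir.exists(run_dir)) stop("no runs/ under ", dir, "; run the ensemble first")
  ens <- utils::read.table(file.path(run_dir, "ensemble.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  ids <- c("unfused", ens$id)
  missing <- ids[!vapply(ids, function(id)
    all(file.exists(file.path(run_dir, id,
                              c("agb.tsv", "soil_c.tsv", "nbp.tsv")))),
    logical(1))]
  if (length(missing))
    stop("missing realization outputs: ", paste(missing, collapse = ", "))
  outputs <- lapply(stats::setNames(ids, ids), read_run, run_dir = run_dir)
  if (is.null(eval_years)) eval_years <- b$config$common_period
  ev <- evaluate_realizations(outputs, b$obs, b$domain, b$net_flux_ref,
                              eval_years = eval_years)
  rep_dir <- file.path(dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  for (nm in names(ev))
    utils::write.table(ev[[nm]], file.path(rep_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  ev
}

#' Summarise an evaluated bundle
#'
#' Best realization by NBP IoA, its gain over the unfused model, and the
#' ensemble NBP spread (maximum across-realization range over the
#' evaluation years).
#'
#' @param dir bundle directory with completed `reports/`.
#' @param eval_years years of the NBP spread computation (default the
#'   config's common period).
#' @return list with `best_id`, `best_ioa`, `unfused_ioa`, `improvement`,
#'   `nbp_spread` (PgC yr^-1).
#' @export
pipeline_report <- function(dir, eval_years = NULL) {
  b <- read_bundle(dir)
  if (is.null(eval_years)) eval_years <- b$config$common_period
  run_dir <- file.path(dir, "runs")
  nbp_tab <- utils::read.table(file.path(dir, "reports", "nbp.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  fused <- nbp_tab[nbp_tab$realization != "unfused", ]
  best <- fused[which.max(fused$ioa), ]
  unfused_ioa <- nbp_tab$ioa[nbp_tab$realization == "unfused"]
  ids <- nbp_tab$realization[nbp_tab$realization != "unfused"]
  yrs <- as.character(eval_years)
  nbps <- vapply(ids, function(id)
    read_grid_field(file.path(run_dir, id, "nbp.tsv"))[yrs],
    numeric(length(yrs)))
  spread <- max(apply(nbps, 1, max) - apply(nbps, 1, min))
  out <- list(best_id = best$realization, best_ioa = best$ioa,
              unfused_ioa = unfused_ioa,
              improvement = best$ioa - unfused_ioa, nbp_spread = spread)
  cat(sprintf(paste0("best realization: %s (NBP IoA %.3f; unfused %.3f; ",
                     "improvement %+.3f)\nensemble NBP spread: %.2f PgC yr-1\n"),
              out$best_id, out$best_ioa, out$unfused_ioa, out$improvement,
              out$nbp_spread))
  invisible(out)
}
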