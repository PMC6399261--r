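#' Enumerate the model-data fusion ensemble
#'
#' A realization is one fusion configuration: a choice of which emulator
#' components are replaced (influx, vegetation turnover, soil turnover) and
#' by which datasets. Six categories are enumerated, each realization
#' carrying exactly one NPP dataset (the same dataset corrects the influx
#' and feeds the apparent turnover rates):
#'
#' * `influx` — influx only, one per NPP dataset;
#' * `veg_turnover` — vegetation turnover only, NPP x AGB;
#' * `soil_turnover` — soil turnover only, NPP x soil;
#' * `influx+veg` — influx and vegetation turnover, NPP x AGB;
#' * `influx+soil` — influx and soil turnover, NPP x soil;
#' * `influx+both` — influx and both turnovers, NPP x AGB x soil.
#'
#' With 5 NPP, 2 AGB and 2 soil datasets this yields 5 + 10 + 10 + 10 + 10 +
#' 20 = 65 realizations. Ordering is deterministic: categories in the order
#' above, datasets in registration order.
#'
#' @param npp_datasets,agb_datasets,soil_datasets character vectors of
#'   registered dataset names (non-empty).
#' @return A data.frame with columns `id`, `category`, `components`
#'   (`+`-separated), `npp_dataset`, `agb_dataset`, `soil_dataset` (NA when
#'   unused).
#' @export
build_ensemble <- function(npp_datasets, agb_datasets, soil_datasets) {
  if (!length(npp_datasets) || !length(agb_datasets) || !length(soil_datasets))
    stop("dataset rosters must be non-empty")
  row <- function(category, components, npp, agb = NA_character_,
                  soil = NA_character_) {
    data.frame(category = category, components = components,
               npp_dataset = npp, agb_dataset = agb, soil_dataset = soil,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (n in npp_datasets)
    out[[length(out) + 1L]] <- row("influx", "influx", n)
  for (n in npp_datasets) for (a in agb_datasets)
    out[[length(out) + 1L]] <- row("veg_turnover", "veg_turnover", n, agb = a)
  for (n in npp_datasets) for (s in soil_datasets)
    out[[length(out) + 1L]] <- row("soil_turnover", "soil_turnover", n, soil = s)
  for (n in npp_datasets) for (a in agb_datasets)
    out[[length(out) + 1L]] <- row("influx+veg", "influx+veg_turnover", n,
                                   agb = a)
  for (n in npp_datasets) for (s in soil_datasets)
    out[[length(out) + 1L]] <- row("influx+soil", "influx+soil_turnover", n,
                                   soil = s)
  for (n in npp_datasets) for (a in agb_datasets) for (s in soil_datasets)
    out[[length(out) + 1L]] <- row("influx+both",
                                   "influx+veg_turnover+soil_turnover", n,
                                   agb = a, soil = s)
  ens <- do.call(rbind, out)
  ens <- cbind(id = sprintf("r%03d", seq_len(nrow(ens))), ens,
               stringsAsFactors = FALSE)
  ens
}

# components of a realization row as a character vector
realization_components <- function(real) {
  strsplit(real$components, "+", fixed = TRUE)[[1]]
}
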