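# Gridded fields travel as self-describing TSV: commented "key: value"
# metadata lines (name, kind, units, named dimensions) followed by the
# table. Plain text keeps bundles portable and diffable.

#' Write a gridded field, per-cell vector or annual series to TSV
#'
#' @param values a years x cells matrix (year rownames), a per-cell vector,
#'   or a year-named series.
#' @param path output file.
#' @param name field name recorded in the metadata header.
#' @param units units attribute (e.g. `"gC m-2 yr-1"`).
#' @param kind optional kind attribute (e.g. `"NPP"`).
#' @param extra named list of further metadata entries.
#' @return `path`, invisibly.
#' @export
write_grid_field <- function(values, path, name, units = "", kind = "",
                             extra = list()) {
  if (is.matrix(values) && is.null(rownames(values))) {
    # cell-indexed matrix (e.g. depth layers or pools in columns)
    type <- "cellmatrix"
    df <- data.frame(cell = seq_len(nrow(values)), values, check.names = FALSE)
    names(df) <- c("cell", paste0("col_", seq_len(ncol(values))))
  } else if (is.matrix(values)) {
    type <- "matrix"
    df <- data.frame(year = rownames(values), values, check.names = FALSE)
    names(df) <- c("year", paste0("cell_", seq_len(ncol(values))))
  } else if (!is.null(names(values)) &&
             !anyNA(suppressWarnings(as.integer(names(values))))) {
    type <- "series"
    df <- data.frame(year = names(values), value = as.numeric(values))
  } else {
    type <- "vector"
    df <- data.frame(cell = seq_along(values), value = as.numeric(values))
  }
  meta <- c(list(name = name, kind = kind, units = units, type = type), extra)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a field written by [write_grid_field]
#'
#' @param path file to read.
#' @return The matrix, vector or named series, with the metadata attached
#'   as a `meta` attribute.
#' @export
read_grid_field <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ([^:]+): ?(.*)$", "\\1\x01\\2", lines[h])
    kv <- strsplit(kv, "\x01")[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else ""
  }
  df <- utils::read.table(text = lines[-hdr], sep = "\t", header = TRUE,
                          check.names = FALSE)
  out <- switch(meta$type,
    matrix = {
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$year
      dimnames(m)[2] <- list(NULL)
      m
    },
    cellmatrix = unname(as.matrix(df[, -1, drop = FALSE])),
    series = stats::setNames(df$value, df$year),
    vector = df$value,
    stop("unknown field type in ", path))
  attr(out, "meta") <- meta
  out
}

#' Serialize a pool system to a YAML config file
#' @param system a [pool_system].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pool_system <- function(system, path) {
  yaml::write_yaml(list(
    pool_names = system$pool_names,
    compartment = system$compartment,
    aboveground = system$aboveground,
    b = as.numeric(system$b),
    K = as.numeric(system$K),
    A = apply(system$A, 1, as.numeric, simplify = FALSE)), path)
  invisible(path)
}

#' Read a pool system from a YAML config file
#' @param path file written by [write_pool_system] (or hand-edited).
#' @return A [pool_system].
#' @export
read_pool_system <- function(path) {
  y <- yaml::read_yaml(path)
  A <- do.call(rbind, y$A)
  pool_system(y$pool_names, y$compartment, y$aboveground, y$b, A, y$K)
}

write_domain <- function(domain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# soil_reference_depth: %s", domain$soil_reference_depth),
             con)
  writeLines(sprintf("# class_names: %s",
                     paste(domain$class_names, collapse = ",")), con)
  utils::write.table(domain$cells, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_domain <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  depth <- as.numeric(sub("^# soil_reference_depth: ", "",
                          lines[grep("soil_reference_depth", lines)]))
  cn <- strsplit(sub("^# class_names: ", "",
                     lines[grep("class_names", lines)]), ",")[[1]]
  df <- utils::read.table(text = lines[-hdr], sep = "\t", header = TRUE)
  grid_domain(df$area, df$land_cover_class, df$peat_fraction,
              df$active_layer_depth, soil_reference_depth = depth,
              class_names = if (length(cn)) cn else NULL)
}

write_manifest <- function(dir, seed) {
  files <- list.files(dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  sums <- as.character(tools::md5sum(file.path(dir, files)))
  manifest <- list(seed = seed,
                   files = data.frame(file = files, md5 = sums,
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
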