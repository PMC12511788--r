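# Run-level orchestration behind the command-line interface: flat key=value
# configs, reproducibility metadata, and the five pipeline commands
# (simulate, thin, eoo, calibrate, compare/richness).

default_config <- function() {
  list(template = NA_character_, occurrences = NA_character_,
       expert_maps = NA_character_, out_dir = "eoomapr_out",
       id_field = "unit_id", bioregion_field = "bioregion_id",
       ecoregion_field = "ecoregion_id",
       min_year = 1990, min_area_km2 = 1, n_min = 20,
       method = "plugin", p = 0.99, grid_n = 512, seed = 1)
}

#' Read a flat key = value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' an error; missing keys take package defaults (plug-in bandwidth, 99%
#' region, 1990 cutoff, 1 km2 island filter, 20-record minimum).
#'
#' @param path Config file, or NULL for pure defaults.
#' @param overrides Named list applied on top (CLI flags).
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    for (ln in readLines(path, warn = FALSE)) {
      ln <- sub("#.*$", "", ln)
      if (!grepl("=", ln)) next
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
    }
  }
  for (k in names(overrides)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$config_hash <- sprintf("%08x", string_hash31(paste(
    names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","), ""),
    collapse = ";")))
  cfg
}

load_template_from_config <- function(cfg) {
  t <- load_template(cfg$template, id_field = cfg$id_field,
                     parent_fields = c(cfg$bioregion_field, cfg$ecoregion_field))
  filter_min_area(t, cfg$min_area_km2)
}

#' Thin occurrences per a run configuration
#'
#' Loads template and occurrences, applies the pre-filters, unit assignment
#' and biogeographic thinning, and writes per-species thinned CSVs plus a
#' provenance report.
#' @param cfg A config list from [read_config()].
#' @return Invisibly, the report data frame.
#' @export
run_thin <- function(cfg) {
  t <- load_template_from_config(cfg)
  sc <- classify_size(t)
  t <- set_size_classes(t, sc)
  extent <- template_extent(t)
  occ_sets <- load_occurrences(cfg$occurrences)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sp in names(occ_sets)) {
    o <- preprocess_occurrences(occ_sets[[sp]], extent, cfg$min_year)
    o <- assign_units(o, t)
    o <- biogeographic_thin(o, sc, seed = substream_seed(cfg$seed, sp))
    write_occurrences(o, file.path(cfg$out_dir, paste0("thinned_",
                                                       gsub("[^A-Za-z0-9_-]", "_", sp), ".csv")))
    prov <- o$provenance
    rows[[sp]] <- data.frame(species = sp,
                             raw = nrow(o$records) + sum(prov$removed[prov$filter == "malformed"]),
                             kept = n_records(o),
                             passes_min_sample = meets_min_sample(o, cfg$n_min),
                             t(stats::setNames(prov$removed, prov$filter)),
                             config_hash = cfg$config_hash,
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  report <- do.call(rbind, rows)
  utils::write.csv(report, file.path(cfg$out_dir, "thinning_report.csv"),
                   row.names = FALSE)
  invisible(report)
}

run_pipeline_sets <- function(cfg) {
  t <- load_template_from_config(cfg)
  sc <- classify_size(t)
  t <- set_size_classes(t, sc)
  extent <- template_extent(t)
  occ_sets <- load_occurrences(cfg$occurrences)
  thinned <- list()
  for (sp in names(occ_sets)) {
    o <- preprocess_occurrences(occ_sets[[sp]], extent, cfg$min_year)
    o <- assign_units(o, t)
    thinned[[sp]] <- biogeographic_thin(o, sc, seed = substream_seed(cfg$seed, sp))
  }
  list(template = t, sc = sc, occ = thinned)
}

#' Derive EOO maps per a run configuration
#'
#' Species failing the minimum-sample rule are skipped (named in the
#' messages); each map is written as a GeoJSON feature collection with the
#' full parameter record.
#' @param cfg A config list.
#' @return Invisibly, the named list of `eoo_map`s.
#' @export
run_eoo <- function(cfg) {
  ctx <- run_pipeline_sets(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list()
  for (sp in names(ctx$occ)) {
    o <- ctx$occ[[sp]]
    if (!meets_min_sample(o, cfg$n_min)) {
      message("skipping ", sp, ": ", n_records(o), " < ", cfg$n_min,
              " records after thinning")
      next
    }
    m <- build_eoo(o, ctx$template, method = cfg$method, p = cfg$p,
                   n_min = cfg$n_min, grid_n = cfg$grid_n, seed = cfg$seed)
    maps[[sp]] <- m
    props <- data.frame(species = sp, method = cfg$method, p = cfg$p,
                        n_used = m$params$n_used,
                        h11 = m$params$H[1, 1], h12 = m$params$H[1, 2],
                        h22 = m$params$H[2, 2], grid_n = cfg$grid_n,
                        seed = cfg$seed, config_hash = cfg$config_hash,
                        area_km2 = m$region$area_km2,
                        n_components = m$unclipped$n_components)
    write_geojson(list(m$region$polygons), props,
                  file.path(cfg$out_dir, paste0("eoo_",
                                                gsub("[^A-Za-z0-9_-]", "_", sp), ".geojson")),
                  crs_tag = ctx$template$crs_tag)
  }
  invisible(maps)
}

#' Calibration table per a run configuration
#' @param cfg A config list.
#' @return Invisibly, the calibration table.
#' @export
run_calibrate <- function(cfg) {
  ctx <- run_pipeline_sets(cfg)
  eligible <- Filter(function(o) meets_min_sample(o, cfg$n_min), ctx$occ)
  cal <- calibrate_kde(eligible, ctx$template, grid_n = cfg$grid_n)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cal$table
  tab$config_hash <- cfg$config_hash
  utils::write.csv(tab, file.path(cfg$out_dir, "calibration.csv"),
                   row.names = FALSE)
  invisible(cal$table)
}

#' Map comparison (V-measure and richness errors) per a run configuration
#'
#' Expert maps are read from `cfg$expert_maps` (GeoJSON with a `species_key`
#' property; features flagged via an `exclude` property are dropped).
#' @param cfg A config list.
#' @param exclude_species Optional species keys excluded from the summary.
#' @return Invisibly, list(vmeasure, richness).
#' @export
run_compare <- function(cfg, exclude_species = character(0)) {
  ctx <- run_pipeline_sets(cfg)
  extent <- template_extent(ctx$template)
  maps <- list()
  for (sp in names(ctx$occ)) {
    o <- ctx$occ[[sp]]
    if (!meets_min_sample(o, cfg$n_min)) next
    m <- build_eoo(o, ctx$template, method = cfg$method, p = cfg$p,
                   n_min = cfg$n_min, grid_n = cfg$grid_n, seed = cfg$seed)
    maps[[sp]] <- to_presence_absence(m, extent, source = "eoo")
  }
  expert_raw <- read_geojson(cfg$expert_maps)
  keep <- if ("exclude" %in% names(expert_raw$properties))
    !(expert_raw$properties$exclude %in% c(TRUE, "TRUE", "true", "1")) else
      rep(TRUE, length(expert_raw$geoms))
  expert <- list()
  for (i in which(keep)) {
    key <- expert_raw$properties$species_key[i]
    expert[[key]] <- to_presence_absence(expert_raw$geoms[[i]], extent,
                                         species = key, source = "expert")
  }
  vb <- vmeasure_batch(maps, expert, exclude = exclude_species)
  rich <- richness_scale_errors(maps, expert, ctx$template)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  vt <- vb$table; vt$config_hash <- cfg$config_hash
  utils::write.csv(vt, file.path(cfg$out_dir, "vmeasure.csv"), row.names = FALSE)
  rt <- rich; rt$config_hash <- cfg$config_hash
  utils::write.csv(rt, file.path(cfg$out_dir, "richness_errors.csv"),
                   row.names = FALSE)
  invisible(list(vmeasure = vb, richness = rich))
}

#' Emit a synthetic benchmark bundle per a run configuration
#'
#' Writes the synthetic template (GeoJSON), per-species occurrence CSVs with
#' ground-truth columns, and a sidecar CSV of mixture parameters.
#' @param cfg A config list (uses `seed` and `out_dir`).
#' @return Invisibly, the benchmark list from [make_benchmark()].
#' @export
run_simulate <- function(cfg) {
  bm <- make_benchmark(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_template(bm$template, file.path(cfg$out_dir, "template.geojson"))
  truth_rows <- list()
  for (sp in names(bm$occ)) {
    write_occurrences(bm$occ[[sp]], file.path(cfg$out_dir,
                                              paste0("occurrences_", sp, ".csv")))
    tr <- bm$ranges[[sp]]
    for (k in seq_along(tr$weights)) {
      truth_rows[[paste(sp, k)]] <- data.frame(
        species = sp, archetype = tr$archetype, component = k,
        weight = tr$weights[k], mean_x = tr$means[k, 1], mean_y = tr$means[k, 2],
        cov_11 = tr$covs[[k]][1, 1], cov_12 = tr$covs[[k]][1, 2],
        cov_22 = tr$covs[[k]][2, 2], stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, truth_rows),
                   file.path(cfg$out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(bm)
}
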