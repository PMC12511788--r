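# Presence-only occurrence handling: loading, the 1990/extent/coordinate
# pre-filters, point-in-unit assignment, and biogeographic thinning (per-unit
# caps at the size-class mean, sampled without replacement).
#
# An occurrence_set is a list:
#   species    species name (one set per species)
#   records    data frame: record_id, x, y, year, unit_id, status
#              status: raw -> retained -> kept / thinned_out (filtered_out
#              records keep the name of the filter that removed them)
#   provenance data frame: filter, removed  (ordered log of removals)

new_occurrence_set <- function(species, records, provenance = NULL) {
  if (is.null(provenance))
    provenance <- data.frame(filter = character(0), removed = integer(0),
                             stringsAsFactors = FALSE)
  structure(list(species = species, records = records, provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("<occurrence_set> ", x$species, ": ", nrow(x$records), " records (",
      sum(x$records$status == "kept"), " kept)\n", sep = "")
  invisible(x)
}

log_filter <- function(occ, filter, removed) {
  occ$provenance <- rbind(occ$provenance,
                          data.frame(filter = filter, removed = as.integer(removed),
                                     stringsAsFactors = FALSE))
  occ
}

#' Count records by status
#' @param occ An `occurrence_set`.
#' @param status Status values to count (default `"kept"`).
#' @export
n_records <- function(occ, status = "kept") sum(occ$records$status %in% status)

#' Load occurrence records from CSV
#'
#' One `occurrence_set` per species. Rows with unparseable coordinates are
#' counted as malformed and excluded from the raw records, never silently
#' dropped.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the roles `species`, `x`,
#'   `y`, `year` to column names in the file.
#' @return Named list of `occurrence_set`, keyed by species; attribute
#'   `malformed` holds the per-species malformed-row counts.
#' @export
load_occurrences <- function(path,
                             column_map = c(species = "species", x = "x",
                                            y = "y", year = "year")) {
  stopifnot(file.exists(path))
  need <- c("species", "x", "y", "year")
  if (!all(need %in% names(column_map)))
    stop("column_map must name columns for: ", paste(need, collapse = ", "))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols))
    stop("occurrence file lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- data.frame(species = raw[[column_map["species"]]],
                   x = suppressWarnings(as.numeric(raw[[column_map["x"]]])),
                   y = suppressWarnings(as.numeric(raw[[column_map["y"]]])),
                   year = suppressWarnings(as.integer(raw[[column_map["year"]]])),
                   stringsAsFactors = FALSE)
  had_coords <- raw[[column_map["x"]]] != "" & raw[[column_map["y"]]] != ""
  malformed <- (is.na(df$x) | is.na(df$y)) & had_coords
  out <- list(); mal <- integer(0)
  for (sp in unique(df$species)) {
    sel <- df$species == sp & !malformed
    rec <- df[sel, c("x", "y", "year"), drop = FALSE]
    rec <- data.frame(record_id = paste0(sp, "#", seq_len(nrow(rec))),
                      rec, unit_id = NA_character_, status = "raw",
                      stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    out[[sp]] <- new_occurrence_set(sp, rec)
    mal[sp] <- sum(df$species == sp & malformed)
    if (mal[sp] > 0) out[[sp]] <- log_filter(out[[sp]], "malformed", mal[sp])
  }
  attr(out, "malformed") <- mal
  out
}

#' Build an occurrence set from coordinates
#'
#' Programmatic constructor used by the synthetic-data generator and tests.
#' @param species Species name.
#' @param xy n x 2 matrix of projected coordinates (m).
#' @param year Integer vector (recycled).
#' @param extra Optional data frame of additional columns (e.g. ground-truth
#'   flags) bound onto the records.
#' @export
occurrence_set <- function(species, xy, year = 2000L, extra = NULL) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(xy)
  rec <- data.frame(record_id = sprintf("%s#%d", species, seq_len(n)),
                    x = xy[, 1], y = xy[, 2],
                    year = as.integer(rep_len(year, n)),
                    unit_id = rep(NA_character_, n),
                    status = rep("raw", n),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) rec <- cbind(rec, extra)
  new_occurrence_set(species, rec)
}

#' Pre-filter occurrence records
#'
#' Removes records with missing coordinates, a year before `min_year`
#' (records from `min_year` itself are kept; records with no year are
#' removed), or a location outside the study extent.
#'
#' @param occ An `occurrence_set`.
#' @param extent An `mpoly` study extent (e.g. [template_extent()]).
#' @param min_year Cutoff year, default 1990.
#' @export
preprocess_occurrences <- function(occ, extent, min_year = 1990) {
  rec <- occ$records
  active <- rec$status == "raw"
  no_coord <- active & (is.na(rec$x) | is.na(rec$y))
  rec$status[no_coord] <- "filtered_out_coords"
  occ$records <- rec
  occ <- log_filter(occ, "missing_coordinates", sum(no_coord))
  active <- rec$status == "raw"
  old <- active & (is.na(rec$year) | rec$year < min_year)
  rec$status[old] <- "filtered_out_year"
  occ$records <- rec
  occ <- log_filter(occ, paste0("year_before_", min_year), sum(old))
  active <- rec$status == "raw"
  if (any(active)) {
    inside <- mp_contains(extent, cbind(rec$x[active], rec$y[active]))
    out_idx <- which(active)[!inside]
    rec$status[out_idx] <- "filtered_out_extent"
    occ$records <- rec
    occ <- log_filter(occ, "outside_extent", length(out_idx))
  } else {
    occ <- log_filter(occ, "outside_extent", 0L)
  }
  occ$records$status[occ$records$status == "raw"] <- "retained"
  occ
}

#' Assign records to template units
#'
#' Point-in-polygon assignment against the template's units, visited in
#' lexicographic unit-id order so that boundary points deterministically get
#' the smallest containing id. Retained records falling in no unit are
#' removed (logged).
#'
#' @param occ A preprocessed `occurrence_set`.
#' @param template An `eoo_template`.
#' @export
assign_units <- function(occ, template) {
  rec <- occ$records
  active <- which(rec$status == "retained")
  if (length(active)) {
    pts <- cbind(rec$x[active], rec$y[active])
    assigned <- rep(NA_character_, length(active))
    todo <- seq_along(active)
    for (i in order(template$units$unit_id)) {
      if (!length(todo)) break
      g <- template$geoms[[i]]
      sub <- pts[todo, , drop = FALSE]
      hit <- mp_contains(g, sub) | mp_on_boundary(g, sub)
      assigned[todo[hit]] <- template$units$unit_id[i]
      todo <- todo[!hit]
    }
    rec$unit_id[active] <- assigned
    lost <- active[is.na(assigned)]
    rec$status[lost] <- "filtered_out_no_unit"
    occ$records <- rec
    occ <- log_filter(occ, "no_unit", length(lost))
  } else {
    occ <- log_filter(occ, "no_unit", 0L)
  }
  occ
}

#' Biogeographic thinning
#'
#' For each size class, the per-unit record count is capped at the ceiling of
#' the mean count over the *occupied* units of that class (for this species),
#' and over-cap units are subsampled uniformly without replacement. Each
#' unit's subsample is drawn from a deterministic substream derived from
#' `seed` and the unit id, so results are reproducible and independent across
#' units and species.
#'
#' @param occ An `occurrence_set` with unit ids assigned.
#' @param sc A `size_classification` from [classify_size()].
#' @param seed Integer seed governing all subsampling.
#' @param caps Optional named integer vector (size class -> cap) freezing
#'   the caps instead of recomputing them; with frozen caps re-thinning an
#'   already-thinned set is the identity.
#' @return The thinned set; surviving records get status `"kept"`, removed
#'   ones `"thinned_out"`. Attribute `caps` stores the per-class caps.
#' @export
biogeographic_thin <- function(occ, sc, seed, caps = NULL) {
  rec <- occ$records
  active <- which(rec$status %in% c("retained", "kept"))
  if (!length(active)) {
    warning("no occupied units; nothing to thin for ", occ$species)
    occ <- log_filter(occ, "thinned", 0L)
    attr(occ, "caps") <- stats::setNames(integer(0), character(0))
    return(occ)
  }
  unit <- rec$unit_id[active]
  cls <- unname(sc$class_of[unit])
  if (any(is.na(cls)))
    stop("records assigned to units absent from the size classification")
  counts <- table(unit)
  unit_class <- sc$class_of[names(counts)]
  if (is.null(caps)) {
    caps <- integer(0)
    for (cl in unique(unit_class)) {
      caps[cl] <- as.integer(ceiling(mean(counts[unit_class == cl])))
    }
  } else if (!all(unique(unit_class) %in% names(caps))) {
    stop("frozen caps must cover every occupied size class")
  }
  drop_idx <- integer(0)
  for (u in names(counts)) {
    cap <- caps[[unit_class[[u]]]]
    idx <- active[unit == u]
    if (length(idx) > cap) {
      keep <- with_seed(substream_seed(seed, u),
                        sample(length(idx), cap, replace = FALSE))
      drop_idx <- c(drop_idx, idx[-keep])
    }
  }
  rec$status[active] <- "kept"
  rec$status[drop_idx] <- "thinned_out"
  occ$records <- rec
  occ <- log_filter(occ, "thinned", length(drop_idx))
  attr(occ, "caps") <- caps
  occ
}

#' Minimum-sample rule
#'
#' A species qualifies for EOO estimation only when at least `n_min` records
#' survive biogeographic thinning.
#' @param occ A thinned `occurrence_set`.
#' @param n_min Minimum kept records (default 20).
#' @export
meets_min_sample <- function(occ, n_min = 20) n_records(occ, "kept") >= n_min

#' Kept coordinates as a matrix
#' @param occ An `occurrence_set`.
#' @param status Statuses to extract (default `"kept"`).
#' @export
occ_coords <- function(occ, status = "kept") {
  sel <- occ$records$status %in% status
  cbind(x = occ$records$x[sel], y = occ$records$y[sel])
}

#' Write an occurrence set (with status column) to CSV
#' @param occ An `occurrence_set`.
#' @param path Output file.
#' @export
write_occurrences <- function(occ, path) {
  df <- cbind(species = occ$species, occ$records)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
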