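# Nested biogeographic template: ingestion, island filtering, Jenks size
# classification of unit areas, and aggregation to coarser levels.
#
# A template is a list:
#   units    data frame: unit_id, bioregion_id, ecoregion_id, name, area_km2,
#            size_class
#   geoms    named list of `mpoly`, one per unit (projected metres)
#   level    "subregion", "bioregion" or "ecoregion"
#   crs_tag  CRS identifier carried through outputs (no reprojection is done)

new_template <- function(units, geoms, level, crs_tag) {
  stopifnot(nrow(units) == length(geoms))
  structure(list(units = units, geoms = geoms, level = level, crs_tag = crs_tag),
            class = "eoo_template")
}

#' @export
print.eoo_template <- function(x, ...) {
  cat("<eoo_template> ", nrow(x$units), " units at level '", x$level,
      "', total area ", round(sum(x$units$area_km2)), " km2\n", sep = "")
  invisible(x)
}

# heuristic guard against geographic (degree) coordinates
check_projected <- function(geoms) {
  bb <- do.call(rbind, lapply(geoms, function(g) mp_bbox(g)))
  if (max(abs(bb[, c(1, 3)])) <= 360 && max(abs(bb[, c(2, 4)])) <= 90)
    stop("coordinates look geographic (degrees); a projected equal-area CRS ",
         "in metres is required (e.g. an Albers equal-area projection)")
  invisible(TRUE)
}

validate_unit_geoms <- function(geoms, ids) {
  bad <- character(0)
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    ok <- length(g) > 0 && all(vapply(g, function(p)
      all(vapply(p, function(r) nrow(r) >= 3 && all(is.finite(r)) &&
                   abs(ring_signed_area(r)) > 0, TRUE)), TRUE))
    if (!ok || mp_area(g) <= 0) bad <- c(bad, ids[i])
  }
  if (length(bad))
    stop("irreparable unit geometries (empty, non-finite or zero-area): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Load a nested biogeographic template
#'
#' Reads a polygon layer (GeoJSON or ESRI Shapefile) of operational units at
#' the finest level (subregions) with parent identifiers for the two coarser
#' levels. Areas are computed from the geometry (km^2), never taken from
#' attribute fields.
#'
#' @param path Path to a `.geojson`/`.json` or `.shp` file with projected
#'   (metre) coordinates.
#' @param id_field Property holding the unique unit identifier.
#' @param parent_fields Character vector of two property names: the bioregion
#'   (mid-level) and ecoregion (top-level) parent identifiers.
#' @param name_field Optional property with a human-readable unit name.
#' @param crs_tag Optional CRS identifier; defaults to the tag stored in the
#'   file (GeoJSON) or `NA`.
#' @return An `eoo_template` at subregion level.
#' @export
load_template <- function(path, id_field = "unit_id",
                          parent_fields = c("bioregion_id", "ecoregion_id"),
                          name_field = NULL, crs_tag = NULL) {
  stopifnot(file.exists(path), length(parent_fields) == 2)
  raw <- if (grepl("\\.shp$", path, ignore.case = TRUE)) read_shapefile(path)
         else read_geojson(path)
  props <- raw$properties
  need <- c(id_field, parent_fields)
  missing_fields <- setdiff(need, names(props))
  if (length(missing_fields))
    stop("template file lacks required fields: ",
         paste(missing_fields, collapse = ", "))
  check_projected(raw$geoms)
  ids <- as.character(props[[id_field]])
  if (anyDuplicated(ids)) stop("unit ids are not unique: field ", id_field)
  validate_unit_geoms(raw$geoms, ids)
  bio <- as.character(props[[parent_fields[1]]])
  eco <- as.character(props[[parent_fields[2]]])
  if (any(is.na(bio) | bio == "" | is.na(eco) | eco == ""))
    stop("every unit needs non-empty parent ids at both coarser levels")
  units <- data.frame(
    unit_id = ids,
    bioregion_id = bio,
    ecoregion_id = eco,
    name = if (!is.null(name_field) && name_field %in% names(props))
             as.character(props[[name_field]]) else ids,
    area_km2 = vapply(raw$geoms, mp_area, 0) / 1e6,
    size_class = NA_character_,
    stringsAsFactors = FALSE)
  geoms <- raw$geoms
  names(geoms) <- ids
  o <- order(units$unit_id)
  new_template(units[o, , drop = FALSE], geoms[o], "subregion",
               crs_tag %||% raw$crs_tag)
}

#' Remove small units (oceanic islands and islets)
#'
#' Units with computed area strictly below `min_area_km2` are dropped.
#'
#' @param template An `eoo_template`.
#' @param min_area_km2 Threshold in km^2 (default 1).
#' @return Filtered template; the number of removed units is reported via
#'   `message()` and stored in attribute `removed`.
#' @export
filter_min_area <- function(template, min_area_km2 = 1) {
  keep <- template$units$area_km2 >= min_area_km2
  if (!any(keep)) stop("min-area filter removed every unit")
  removed <- sum(!keep)
  out <- new_template(template$units[keep, , drop = FALSE],
                      template$geoms[keep], template$level, template$crs_tag)
  if (removed > 0)
    message("filter_min_area: removed ", removed, " unit(s) below ",
            min_area_km2, " km2")
  attr(out, "removed") <- removed
  out
}

#' Fisher-Jenks natural breaks (exact dynamic programme)
#'
#' Partitions sorted values into `k` contiguous classes minimising the total
#' within-class sum of squared deviations from class means. Identical values
#' always share a class; among equal-objective partitions the one with the
#' smallest first break is returned.
#'
#' @param values Numeric vector (finite).
#' @param k Number of classes, `1 <= k <=` number of distinct values.
#' @return List: `breaks` (k-1 interior break values, the upper bound of each
#'   lower class), `assignment` (class index per input value, 1 = smallest),
#'   `objective` (minimised within-class SSD).
#' @export
jenks_breaks <- function(values, k) {
  if (!all(is.finite(values))) stop("values must be finite")
  k <- as.integer(k)
  uv <- sort(unique(values))
  m <- length(uv)
  if (k < 1) stop("k must be >= 1")
  if (m < k) stop("need at least k distinct values (", m, " < ", k, ")")
  w <- as.numeric(table(factor(values, levels = uv)))
  # prefix sums over weighted unique values
  cw <- c(0, cumsum(w))
  cs <- c(0, cumsum(w * uv))
  cs2 <- c(0, cumsum(w * uv^2))
  sse <- function(i, j) { # classes over unique values i..j (1-based)
    W <- cw[j + 1] - cw[i]; S <- cs[j + 1] - cs[i]; S2 <- cs2[j + 1] - cs2[i]
    S2 - S * S / W
  }
  INF <- Inf
  cost <- matrix(INF, k, m)
  split <- matrix(0L, k, m)
  for (j in 1:m) cost[1, j] <- sse(1, j)
  if (k > 1) for (c in 2:k) {
    for (j in c:m) {
      best <- INF; bi <- 0L
      for (i in c:j) { # class c covers unique values i..j
        v <- cost[c - 1, i - 1] + sse(i, j)
        if (v < best - 1e-12 * max(1, abs(v))) { best <- v; bi <- i }
      }
      cost[c, j] <- best; split[c, j] <- bi
    }
  }
  # reconstruct class boundaries over unique values
  upper <- integer(k); j <- m
  for (c in k:1) {
    upper[c] <- j
    i <- if (c == 1) 1L else split[c, j]
    j <- i - 1L
  }
  class_of_unique <- rep(seq_len(k), times = diff(c(0, upper)))
  assignment <- class_of_unique[match(values, uv)]
  breaks <- if (k > 1) uv[upper[-k]] else numeric(0)
  list(breaks = breaks, assignment = assignment,
       objective = cost[k, m])
}

#' Classify template units into three size classes
#'
#' Applies Fisher-Jenks natural breaks with k = 3 to the natural-log unit
#' areas, yielding small / medium / large classes (monotone in area).
#'
#' @param template An `eoo_template` with computed areas.
#' @return A `size_classification`: list with `breaks` (2 interior breaks on
#'   the log-area scale), `class_of` (named character vector unit_id ->
#'   class), and `table` (data frame unit_id, log_area, class).
#' @export
classify_size <- function(template) {
  a <- template$units$area_km2
  if (length(unique(a)) < 3)
    stop("size classification needs at least 3 distinct unit areas")
  la <- log(a)
  jb <- jenks_breaks(la, 3)
  lab <- c("small", "medium", "large")[jb$assignment]
  class_of <- stats::setNames(lab, template$units$unit_id)
  structure(list(breaks = jb$breaks, class_of = class_of,
                 table = data.frame(unit_id = template$units$unit_id,
                                    log_area = la, class = lab,
                                    stringsAsFactors = FALSE)),
            class = "size_classification")
}

#' Attach size classes to a template
#' @param template An `eoo_template`.
#' @param sc A `size_classification` from [classify_size()].
#' @export
set_size_classes <- function(template, sc) {
  template$units$size_class <- unname(sc$class_of[template$units$unit_id])
  template
}

#' Aggregate a subregion template to a coarser level
#'
#' Dissolves child units by parent id. Dissolved geometries are kept as the
#' multipolygon collection of child parts (children tile their parent
#' disjointly, so areas are conserved exactly and even-odd containment tests
#' remain correct).
#'
#' @param template An `eoo_template` at subregion level.
#' @param level `"subregion"` (identity), `"bioregion"` or `"ecoregion"`.
#' @export
aggregate_level <- function(template, level = c("subregion", "bioregion", "ecoregion")) {
  level <- match.arg(level)
  if (level == "subregion") return(template)
  key <- switch(level, bioregion = template$units$bioregion_id,
                ecoregion = template$units$ecoregion_id)
  ids <- sort(unique(key))
  geoms <- vector("list", length(ids)); names(geoms) <- ids
  area <- numeric(length(ids))
  eco <- character(length(ids))
  for (i in seq_along(ids)) {
    sel <- which(key == ids[i])
    parts <- unlist(lapply(template$geoms[sel], unclass), recursive = FALSE)
    geoms[[i]] <- mpoly(parts)
    area[i] <- sum(template$units$area_km2[sel])
    eco[i] <- template$units$ecoregion_id[sel[1]]
  }
  units <- data.frame(unit_id = ids,
                      bioregion_id = if (level == "bioregion") ids else NA_character_,
                      ecoregion_id = if (level == "bioregion") eco else ids,
                      name = ids, area_km2 = area, size_class = NA_character_,
                      stringsAsFactors = FALSE)
  new_template(units, geoms, level, template$crs_tag)
}

#' Template extent as a multipolygon
#'
#' The union of all unit geometries, represented as the (disjoint) collection
#' of unit parts.
#' @param template An `eoo_template`.
#' @export
template_extent <- function(template) {
  mpoly(unlist(lapply(template$geoms, unclass), recursive = FALSE))
}

#' Write a template to GeoJSON
#' @param template An `eoo_template`.
#' @param path Output path.
#' @export
write_template <- function(template, path) {
  write_geojson(template$geoms, template$units, path, crs_tag = template$crs_tag)
}
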