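# Agreement between two range-map sources: area-weighted spatial V-measure
# over the presence/absence partition overlay, and per-unit species-richness
# variation (RMSE) and bias (mean error) at nested biogeographic scales.

#' Presence-absence map
#'
#' A two-category partition of the study extent: presence = map polygons
#' intersected with the extent, absence = the remainder.
#'
#' @param polygons An `mpoly` of presence polygons (or an `eoo_map`, whose
#'   clipped region is used).
#' @param extent An `mpoly` study extent (e.g. [template_extent()]).
#' @param species Species label.
#' @param source Source tag (e.g. `"eoo"`, `"expert"`).
#' @param lattice_n Lattice fallback resolution for non-convex overlays.
#' @return A `pa_map` with exact/lattice presence area bookkeeping.
#' @export
to_presence_absence <- function(polygons, extent, species = "",
                                source = "", lattice_n = 512) {
  if (inherits(polygons, "eoo_map")) {
    species <- if (nzchar(species)) species else polygons$species
    polygons <- polygons$region$polygons
  }
  if (inherits(polygons, "confidence_region")) polygons <- polygons$polygons
  if (is.matrix(polygons) || (is.list(polygons) && !is_mpoly(polygons)))
    polygons <- mpoly(polygons)
  area_extent <- mp_area(extent)
  ia <- mp_intersection_area(polygons, extent, lattice_n)
  if (as.numeric(ia) == 0) message("presence category is empty for ", species)
  structure(list(species = species, source = source,
                 presence = polygons, extent = extent,
                 area_presence = as.numeric(ia),
                 area_extent = area_extent,
                 overlay_method = attr(ia, "method")),
            class = "pa_map")
}

#' @export
print.pa_map <- function(x, ...) {
  cat("<pa_map> ", x$species, " [", x$source, "]: presence ",
      signif(100 * x$area_presence / x$area_extent, 4), "% of extent\n", sep = "")
  invisible(x)
}

#' Overlay two presence-absence maps into a segment area table
#'
#' @param a,b `pa_map` objects over the same extent.
#' @param lattice_n Lattice fallback resolution.
#' @return Data frame: category_a, category_b, area; attribute `method`
#'   records whether the presence/presence cell was computed exactly or on a
#'   lattice.
#' @export
overlay_segments <- function(a, b, lattice_n = 512) {
  total <- a$area_extent
  if (abs(total - b$area_extent) > 1e-6 * total)
    stop("presence-absence maps cover different extents")
  pp <- mp_intersection_area(a$presence, b$presence, lattice_n)
  # the presence polygons may spill outside the extent; their effective area
  # is the within-extent one already computed per map
  pp_val <- min(as.numeric(pp), a$area_presence, b$area_presence)
  tab <- data.frame(
    category_a = c("presence", "presence", "absence", "absence"),
    category_b = c("presence", "absence", "presence", "absence"),
    area = c(pp_val,
             a$area_presence - pp_val,
             b$area_presence - pp_val,
             total - a$area_presence - b$area_presence + pp_val),
    stringsAsFactors = FALSE)
  tab$area <- pmax(tab$area, 0)
  attr(tab, "method") <- attr(pp, "method")
  tab
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spatial V-measure from a segment area table
#'
#' Area-weighted joint probabilities over the overlay cells give
#' homogeneity h = 1 - H(B|A)/H(B), completeness c = 1 - H(A|B)/H(A) and
#' v = 2hc/(h+c) (natural-log entropies; h or c defined as 1 when the
#' corresponding unconditional entropy is 0, v as 0 when h + c = 0).
#'
#' @param segments Data frame with columns category_a, category_b, area.
#' @return List: homogeneity, completeness, v.
#' @export
vmeasure_from_segments <- function(segments) {
  tot <- sum(segments$area)
  p <- segments$area / tot
  pa <- tapply(p, segments$category_a, sum)
  pb <- tapply(p, segments$category_b, sum)
  Ha <- entropy_nats(pa); Hb <- entropy_nats(pb)
  # conditional entropies from the joint
  Hb_given_a <- 0; Ha_given_b <- 0
  for (i in seq_len(nrow(segments))) {
    pij <- p[i]
    if (pij <= 0) next
    Hb_given_a <- Hb_given_a - pij * log(pij / pa[[segments$category_a[i]]])
    Ha_given_b <- Ha_given_b - pij * log(pij / pb[[segments$category_b[i]]])
  }
  h <- if (Hb == 0) 1 else 1 - Hb_given_a / Hb
  cc <- if (Ha == 0) 1 else 1 - Ha_given_b / Ha
  h <- min(max(h, 0), 1); cc <- min(max(cc, 0), 1)
  v <- if (h + cc == 0) 0 else 2 * h * cc / (h + cc)
  list(homogeneity = h, completeness = cc, v = v)
}

#' Spatial V-measure between two presence-absence maps
#'
#' @param a,b `pa_map` objects over the same extent.
#' @param lattice_n Lattice fallback resolution for the overlay.
#' @return List: homogeneity, completeness, v, segments (the overlay table),
#'   method.
#' @export
vmeasure <- function(a, b, lattice_n = 512) {
  seg <- overlay_segments(a, b, lattice_n)
  out <- vmeasure_from_segments(seg)
  out$segments <- seg
  out$method <- attr(seg, "method")
  out
}

#' V-measure across a species set, with summary
#'
#' Species are matched between the two map collections by name (the join
#' key); unmatched species are reported and excluded.
#'
#' @param maps_a,maps_b Named lists of `pa_map` keyed by species.
#' @param exclude Character vector of species keys to drop before
#'   summarising (e.g. a taxonomic group filter).
#' @param lattice_n Lattice fallback resolution.
#' @return List: `table` (species, homogeneity, completeness, v),
#'   `summary` (mean, sd, min, max of v), `unmatched` (excluded keys).
#' @export
vmeasure_batch <- function(maps_a, maps_b, exclude = character(0),
                           lattice_n = 512) {
  keys <- intersect(names(maps_a), names(maps_b))
  unmatched <- union(setdiff(names(maps_a), keys), setdiff(names(maps_b), keys))
  keys <- setdiff(keys, exclude)
  if (!length(keys)) stop("no matched species to compare")
  rows <- lapply(keys, function(k) {
    vm <- vmeasure(maps_a[[k]], maps_b[[k]], lattice_n)
    data.frame(species = k, homogeneity = vm$homogeneity,
               completeness = vm$completeness, v = vm$v,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = c(mean = mean(tab$v), sd = stats::sd(tab$v),
                   min = min(tab$v), max = max(tab$v), n = length(keys)),
       unmatched = unmatched)
}

#' Species x unit presence-absence matrix at a biogeographic level
#'
#' A species is present in a unit when its presence polygon intersects the
#' unit with positive area (boundary touching does not count). Presence at
#' coarser levels is computed at subregion level and aggregated by parent
#' (logical OR), which equals the direct geometric rule for nested units.
#'
#' @param pa_maps Named list of `pa_map` keyed by species.
#' @param template An `eoo_template` at subregion level.
#' @param level Aggregation level.
#' @param min_frac Optional minimum fraction of the unit area that must be
#'   covered (default 0 = any positive intersection).
#' @param lattice_n Lattice fallback resolution.
#' @return Binary matrix, species (rows) x units (columns).
#' @export
presence_matrix <- function(pa_maps, template,
                            level = c("subregion", "bioregion", "ecoregion"),
                            min_frac = 0, lattice_n = 256) {
  level <- match.arg(level)
  units <- template$units
  m <- matrix(0L, length(pa_maps), nrow(units),
              dimnames = list(names(pa_maps), units$unit_id))
  for (sp in names(pa_maps)) {
    pres <- pa_maps[[sp]]$presence
    if (length(pres) == 0) next
    bbp <- mp_bbox(pres)
    for (j in seq_len(nrow(units))) {
      g <- template$geoms[[j]]
      bbu <- mp_bbox(g)
      if (bbu[1] > bbp[3] || bbu[3] < bbp[1] || bbu[2] > bbp[4] || bbu[4] < bbp[2]) next
      a <- as.numeric(mp_intersection_area(pres, g, lattice_n))
      thr <- max(min_frac * units$area_km2[j] * 1e6, 1e-3)  # 1e-3 m2 noise floor
      if (a > thr) m[sp, j] <- 1L
    }
  }
  if (level == "subregion") return(m)
  key <- switch(level, bioregion = units$bioregion_id,
                ecoregion = units$ecoregion_id)
  ids <- sort(unique(key))
  agg <- matrix(0L, nrow(m), length(ids), dimnames = list(rownames(m), ids))
  for (i in seq_along(ids)) {
    agg[, i] <- as.integer(rowSums(m[, key == ids[i], drop = FALSE]) > 0)
  }
  agg
}

#' Per-unit richness from a presence-absence matrix
#' @param pam Binary species x unit matrix.
#' @export
richness <- function(pam) colSums(pam)

#' Richness variation and bias between two map sources
#'
#' RMSE of the per-unit richness difference measures variation; the signed
#' mean error (source A minus source B, i.e. data-driven minus expert)
#' measures bias.
#'
#' @param richness_a,richness_b Named numeric vectors over the same units.
#' @return List: rmse, mean_error, n_units.
#' @export
richness_errors <- function(richness_a, richness_b) {
  if (length(richness_a) != length(richness_b) ||
      (!is.null(names(richness_a)) && !is.null(names(richness_b)) &&
       !identical(names(richness_a), names(richness_b))))
    stop("richness vectors must share one unit index")
  d <- as.numeric(richness_a) - as.numeric(richness_b)
  list(rmse = sqrt(mean(d^2)), mean_error = mean(d), n_units = length(d))
}

#' Richness error summary across nested scales
#'
#' @param pa_maps_a,pa_maps_b Named lists of `pa_map` (matched species are
#'   used).
#' @param template Subregion-level `eoo_template`.
#' @param levels Levels to evaluate.
#' @param lattice_n Lattice fallback resolution.
#' @return Data frame: level, n_units, rmse, mean_error.
#' @export
richness_scale_errors <- function(pa_maps_a, pa_maps_b, template,
                                  levels = c("subregion", "bioregion", "ecoregion"),
                                  lattice_n = 256) {
  keys <- intersect(names(pa_maps_a), names(pa_maps_b))
  if (!length(keys)) stop("no matched species")
  rows <- lapply(levels, function(lv) {
    pa <- presence_matrix(pa_maps_a[keys], template, lv, lattice_n = lattice_n)
    pb <- presence_matrix(pa_maps_b[keys], template, lv, lattice_n = lattice_n)
    re <- richness_errors(richness(pa), richness(pb))
    data.frame(level = lv, n_units = re$n_units, rmse = re$rmse,
               mean_error = re$mean_error, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
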