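# Lightweight planar polygon geometry for projected (equal-area, metre)
# coordinates. Polygons are lists of rings; a ring is an open n x 2 matrix
# (first vertex not repeated). The first ring of a polygon is the exterior
# (counter-clockwise), subsequent rings are holes (clockwise). A multipolygon
# ("mpoly") is a list of polygons. Point-in-region tests use the even-odd
# rule across all rings, so hole semantics need no special casing.

#' Construct a multipolygon
#'
#' @param x A single ring matrix, a polygon (list of ring matrices), or a
#'   list of polygons. Ring orientation is normalised: exterior rings
#'   counter-clockwise, holes clockwise.
#' @return An object of class `mpoly`.
#' @export
mpoly <- function(x) {
  if (is.matrix(x)) x <- list(list(x))
  else if (is.list(x) && length(x) > 0 && is.matrix(x[[1]])) x <- list(x)
  stopifnot(is.list(x))
  polys <- lapply(x, function(p) {
    stopifnot(is.list(p), length(p) >= 1)
    p <- lapply(p, as_ring)
    p[[1]] <- orient_ring(p[[1]], ccw = TRUE)
    if (length(p) > 1) for (j in 2:length(p)) p[[j]] <- orient_ring(p[[j]], ccw = FALSE)
    p
  })
  structure(polys, class = "mpoly")
}

as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 2)
  # drop explicit closure and duplicated consecutive vertices
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3) stop("ring must have at least 3 distinct vertices")
  if (!all(is.finite(m))) stop("ring has non-finite coordinates")
  m
}

#' @export
is_mpoly <- function(x) inherits(x, "mpoly")

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

orient_ring <- function(ring, ccw = TRUE) {
  a <- ring_signed_area(ring)
  if ((a < 0) == ccw) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Area of a multipolygon (m^2), holes subtracted
#' @param mp An `mpoly`.
#' @export
mp_area <- function(mp) {
  if (length(mp) == 0) return(0)
  sum(vapply(mp, function(p) sum(vapply(p, ring_signed_area, 0)), 0))
}

#' Bounding box of a multipolygon
#' @param mp An `mpoly`.
#' @return Named numeric vector `xmin, ymin, xmax, ymax`.
#' @export
mp_bbox <- function(mp) {
  co <- do.call(rbind, unlist(mp, recursive = FALSE))
  c(xmin = min(co[, 1]), ymin = min(co[, 2]), xmax = max(co[, 1]), ymax = max(co[, 2]))
}

# crossing-number parity for one ring, vectorised over points
ring_crossings <- function(ring, px, py) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  cross <- integer(length(px))
  for (e in seq_len(n)) {
    ya <- y1[e]; yb <- y2[e]
    if (ya == yb) next
    straddles <- (ya > py) != (yb > py)
    if (!any(straddles)) next
    xi <- x1[e] + (py[straddles] - ya) / (yb - ya) * (x2[e] - x1[e])
    hit <- straddles
    hit[straddles] <- px[straddles] < xi
    cross <- cross + hit
  }
  cross
}

#' Even-odd point-in-region test
#'
#' @param mp An `mpoly`.
#' @param pts n x 2 matrix of points.
#' @return Logical vector: point inside the region (holes excluded).
#' @export
mp_contains <- function(mp, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  total <- integer(length(px))
  bb <- if (length(mp)) mp_bbox(mp) else c(0, 0, -1, -1)
  inside_bb <- px >= bb[1] & px <= bb[3] & py >= bb[2] & py <= bb[4]
  if (!any(inside_bb)) return(rep(FALSE, length(px)))
  for (p in mp) for (r in p) {
    rb <- c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2]))
    sel <- inside_bb & px >= rb[1] & px <= rb[3] & py >= rb[2] & py <= rb[4]
    if (!any(sel)) next
    total[sel] <- total[sel] + ring_crossings(r, px[sel], py[sel])
  }
  (total %% 2) == 1
}

#' Test whether points lie on a multipolygon boundary
#'
#' Within a relative tolerance of the region's scale; used for
#' boundary-inclusive (closed-region) containment.
#' @param mp An `mpoly`.
#' @param pts n x 2 matrix.
#' @param rel_tol Tolerance relative to the bounding-box diagonal.
#' @export
mp_on_boundary <- function(mp, pts, rel_tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (length(mp) == 0 || nrow(pts) == 0) return(rep(FALSE, nrow(pts)))
  bb <- mp_bbox(mp)
  eps <- rel_tol * sqrt((bb[3] - bb[1])^2 + (bb[4] - bb[2])^2)
  on <- rep(FALSE, nrow(pts))
  for (p in mp) for (r in p) {
    n <- nrow(r)
    jn <- c(seq_len(n)[-1], 1L)
    for (e in seq_len(n)) {
      ax <- r[e, 1]; ay <- r[e, 2]
      bx <- r[jn[e], 1]; by <- r[jn[e], 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      if (L2 == 0) next
      t <- pmin(pmax(((pts[, 1] - ax) * vx + (pts[, 2] - ay) * vy) / L2, 0), 1)
      d2 <- (pts[, 1] - (ax + t * vx))^2 + (pts[, 2] - (ay + t * vy))^2
      on <- on | d2 <= eps^2
    }
  }
  on
}

ring_is_convex <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  xnn <- c(xn[-1], xn[1]); ynn <- c(yn[-1], yn[1])
  cr <- (xn - x) * (ynn - yn) - (yn - y) * (xnn - xn)
  scale <- max(abs(cr), 1e-300)
  all(cr >= -1e-9 * scale) || all(cr <= 1e-9 * scale)
}

# Sutherland-Hodgman: clip `subject` (any simple ring, any orientation) by the
# half-plane a*x + b*y <= c. Orientation of the subject is preserved, so the
# signed area of the output keeps the subject's sign.
clip_ring_halfplane <- function(subject, a, b, c) {
  n <- nrow(subject)
  if (n == 0) return(subject)
  d <- a * subject[, 1] + b * subject[, 2] - c
  if (all(d <= 0)) return(subject)
  if (all(d >= 0)) return(subject[0, , drop = FALSE])
  jn <- c(seq_len(n)[-1], 1L)
  dn <- d[jn]
  keep_v <- d <= 0
  crossing <- (d < 0 & dn > 0) | (d > 0 & dn < 0)
  t <- ifelse(crossing, d / (d - dn), 0)
  ix <- subject[, 1] + t * (subject[jn, 1] - subject[, 1])
  iy <- subject[, 2] + t * (subject[jn, 2] - subject[, 2])
  pos <- cumsum(keep_v + crossing)
  out <- matrix(0, pos[n], 2)
  vi <- which(keep_v)
  out[pos[vi] - crossing[vi], ] <- subject[vi, , drop = FALSE]
  ci <- which(crossing)
  out[pos[ci], ] <- cbind(ix[ci], iy[ci])
  out
}

# Clip any simple ring by a convex ring (counter-clockwise). Returns a ring
# matrix (possibly with < 3 rows when the intersection is empty/degenerate).
clip_ring_convex <- function(subject, clip_ccw) {
  n <- nrow(clip_ccw)
  out <- subject
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # inward half-plane of CCW edge (p_i -> p_j): left side
    ax <- clip_ccw[i, 1]; ay <- clip_ccw[i, 2]
    bx <- clip_ccw[j, 1]; by <- clip_ccw[j, 2]
    # left of edge: (bx-ax)(y-ay) - (by-ay)(x-ax) >= 0  =>  a*x + b*y <= c
    a <- (by - ay); b <- -(bx - ax)
    c <- a * ax + b * ay
    out <- clip_ring_halfplane(out, a, b, c)
    if (nrow(out) < 3) return(out[0, , drop = FALSE])
  }
  out
}

#' Axis-aligned rectangle ring
#' @param xmin,ymin,xmax,ymax Rectangle bounds.
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Clip a multipolygon by a convex ring (exact)
#'
#' Exterior rings and holes are clipped independently; the result remains a
#' valid even-odd region.
#' @param mp An `mpoly`.
#' @param clip_ring Convex ring matrix.
#' @export
mp_clip_convex <- function(mp, clip_ring) {
  clip_ccw <- orient_ring(as_ring(clip_ring), ccw = TRUE)
  out <- list()
  for (p in mp) {
    ext <- clip_ring_convex(p[[1]], clip_ccw)
    if (nrow(ext) < 3 || abs(ring_signed_area(ext)) <= 0) next
    rings <- list(ext)
    if (length(p) > 1) for (j in 2:length(p)) {
      h <- clip_ring_convex(p[[j]], clip_ccw)
      if (nrow(h) >= 3 && abs(ring_signed_area(h)) > 0) rings[[length(rings) + 1]] <- h
    }
    out[[length(out) + 1]] <- rings
  }
  if (length(out) == 0) structure(list(), class = "mpoly") else mpoly(out)
}

mp_all_rings_convex <- function(mp) {
  all(vapply(mp, function(p) all(vapply(p, ring_is_convex, TRUE)), TRUE))
}

# signed intersection area of one ring pair, clip ring convex
ring_pair_area <- function(r_subject, r_clip_convex) {
  clip_ccw <- orient_ring(r_clip_convex, ccw = TRUE)
  out <- clip_ring_convex(r_subject, clip_ccw)
  if (nrow(out) < 3) 0 else ring_signed_area(out)
}

#' Intersection area of two multipolygons
#'
#' Exact when every ring of one operand is convex (Sutherland-Hodgman on the
#' signed ring decomposition); otherwise estimated on a lattice of cell
#' centres over the overlapping bounding box.
#'
#' @param a,b `mpoly` objects.
#' @param lattice_n Lattice resolution per axis for the fallback.
#' @return Area in the squared coordinate unit, with attribute `method`
#'   (`"exact"` or `"lattice"`).
#' @export
mp_intersection_area <- function(a, b, lattice_n = 512) {
  if (length(a) == 0 || length(b) == 0) return(structure(0, method = "exact"))
  ba <- mp_bbox(a); bb <- mp_bbox(b)
  if (ba[1] >= bb[3] || bb[1] >= ba[3] || ba[2] >= bb[4] || bb[2] >= ba[4])
    return(structure(0, method = "exact"))
  swap <- FALSE
  if (!mp_all_rings_convex(b)) {
    if (mp_all_rings_convex(a)) { tmp <- a; a <- b; b <- tmp; swap <- TRUE }
    else return(structure(mp_lattice_intersection_area(a, b, lattice_n), method = "lattice"))
  }
  total <- 0
  for (pb in b) for (rb in pb) {
    s_b <- sign(ring_signed_area(rb))
    for (pa in a) for (ra in pa) {
      total <- total + s_b * ring_pair_area(ra, rb)
    }
  }
  structure(max(total, 0), method = "exact")
}

mp_lattice_intersection_area <- function(a, b, n = 512) {
  ba <- mp_bbox(a); bb <- mp_bbox(b)
  xmin <- max(ba[1], bb[1]); xmax <- min(ba[3], bb[3])
  ymin <- max(ba[2], bb[2]); ymax <- min(ba[4], bb[4])
  if (xmax <= xmin || ymax <= ymin) return(0)
  dx <- (xmax - xmin) / n; dy <- (ymax - ymin) / n
  # half-cell offset; slight irrational shift avoids lattice lines sitting on
  # axis-aligned polygon edges
  eps <- 1e-4 + 1e-5 * sqrt(2)
  xs <- xmin + (seq_len(n) - 0.5 + eps) * dx
  ys <- ymin + (seq_len(n) - 0.5 + eps) * dy
  pts <- cbind(rep(xs, times = n), rep(ys, each = n))
  inA <- mp_contains(a, pts)
  if (!any(inA)) return(0)
  inB <- mp_contains(b, pts[inA, , drop = FALSE])
  sum(inB) * dx * dy
}

#' Clip a multipolygon by another whose rings are all convex
#'
#' Used to clip confidence regions to a template extent built from convex
#' units: the result is the piecewise decomposition of the intersection,
#' one piece per (region polygon x convex unit ring).
#' @param mp An `mpoly` (any shape).
#' @param convex_parts An `mpoly` whose polygons are single convex rings and
#'   which tile the clip region disjointly.
#' @export
mp_clip_pieces <- function(mp, convex_parts) {
  out <- list()
  bb_mp <- if (length(mp)) mp_bbox(mp) else return(structure(list(), class = "mpoly"))
  for (cp in convex_parts) {
    r <- cp[[1]]
    rb <- c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2]))
    if (rb[1] > bb_mp[3] || rb[3] < bb_mp[1] || rb[2] > bb_mp[4] || rb[4] < bb_mp[2]) next
    piece <- mp_clip_convex(mp, r)
    for (p in piece) out[[length(out) + 1]] <- p
  }
  if (length(out) == 0) structure(list(), class = "mpoly") else mpoly(out)
}

## ---- GeoJSON I/O -----------------------------------------------------------

close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

mpoly_to_geojson_coords <- function(mp) {
  lapply(mp, function(p) lapply(p, function(r) {
    rc <- close_ring(r)
    lapply(seq_len(nrow(rc)), function(i) c(rc[i, 1], rc[i, 2]))
  }))
}

geojson_coords_to_mpoly <- function(coords, type) {
  ring_from <- function(rr) do.call(rbind, lapply(rr, function(pt) c(pt[[1]], pt[[2]])))
  if (type == "Polygon") {
    mpoly(list(lapply(coords, ring_from)))
  } else if (type == "MultiPolygon") {
    mpoly(lapply(coords, function(p) lapply(p, ring_from)))
  } else stop("unsupported geometry type: ", type)
}

#' Write polygon features to GeoJSON
#'
#' @param geoms List of `mpoly` objects (one feature each).
#' @param properties Data frame of feature properties (one row per feature),
#'   or NULL.
#' @param path Output file path.
#' @param crs_tag Optional CRS identifier stored as a foreign member.
#' @export
write_geojson <- function(geoms, properties = NULL, path, crs_tag = NULL) {
  feats <- lapply(seq_along(geoms), function(i) {
    props <- if (is.null(properties)) structure(list(), names = character(0))
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "MultiPolygon",
                         coordinates = mpoly_to_geojson_coords(geoms[[i]])))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(crs_tag)) fc$crs_tag <- crs_tag
  txt <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA)
  writeLines(txt, path)
  invisible(path)
}

#' Read polygon features from GeoJSON
#'
#' @param path GeoJSON file with a FeatureCollection of Polygon/MultiPolygon
#'   features.
#' @return List with `geoms` (list of `mpoly`), `properties` (data frame) and
#'   `crs_tag` (string or NA).
#' @export
read_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  if (is.null(js$type) || js$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  geoms <- lapply(js$features, function(f)
    geojson_coords_to_mpoly(f$geometry$coordinates, f$geometry$type))
  props <- lapply(js$features, function(f) {
    p <- f$properties
    if (is.null(p) || length(p) == 0) list(.dummy = NA) else lapply(p, function(v) if (is.null(v)) NA else v)
  })
  keys <- unique(unlist(lapply(props, names)))
  tab <- as.data.frame(
    lapply(keys, function(k) sapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])),
    col.names = keys, stringsAsFactors = FALSE, optional = TRUE)
  names(tab) <- keys
  tab$.dummy <- NULL
  crs_tag <- if (!is.null(js$crs_tag)) js$crs_tag else NA_character_
  list(geoms = geoms, properties = tab, crs_tag = crs_tag)
}

## ---- minimal ESRI Shapefile reader ----------------------------------------

#' Read polygon features from an ESRI Shapefile
#'
#' Minimal reader for shape type 5 (Polygon); attributes come from the
#' sibling `.dbf`. Rings are regrouped into polygons by winding order
#' (shapefile convention: clockwise exterior) and containment.
#'
#' @param path Path to the `.shp` file (a `.dbf` with the same stem must
#'   exist).
#' @return List with `geoms` (list of `mpoly`) and `properties` (data frame).
#' @export
read_shapefile <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 7, size = 4, endian = "big")
  if (hdr[1] != 9994L) stop("not a shapefile: ", path)
  file_len_words <- hdr[7]
  readBin(con, "integer", 2, size = 4, endian = "little") # version, shape type
  readBin(con, "double", 8, size = 8, endian = "little")  # bbox + z/m ranges
  geoms <- list()
  repeat {
    rec_hdr <- readBin(con, "integer", 2, size = 4, endian = "big")
    if (length(rec_hdr) < 2) break
    shp_type <- readBin(con, "integer", 1, size = 4, endian = "little")
    content_words <- rec_hdr[2]
    if (shp_type == 0L) { geoms[[length(geoms) + 1]] <- structure(list(), class = "mpoly"); next }
    if (!shp_type %in% c(5L, 15L, 25L))
      stop("unsupported shape type ", shp_type, " (only Polygon supported)")
    readBin(con, "double", 4, size = 8, endian = "little") # bbox
    counts <- readBin(con, "integer", 2, size = 4, endian = "little")
    n_parts <- counts[1]; n_pts <- counts[2]
    parts <- readBin(con, "integer", n_parts, size = 4, endian = "little")
    xy <- readBin(con, "double", 2 * n_pts, size = 8, endian = "little")
    pts <- matrix(xy, ncol = 2, byrow = TRUE)
    # skip Z/M blocks if present
    consumed_words <- 2 + 16 + 4 + 2 * n_parts / 2 + 8 * n_pts / 2  # in 16-bit words... computed below instead
    read_words <- (4 + 32 + 8 + 4 * n_parts + 16 * n_pts) / 2
    extra <- content_words - read_words
    if (extra > 0) readBin(con, "raw", extra * 2)
    starts <- parts + 1
    ends <- c(parts[-1], n_pts)
    rings <- lapply(seq_len(n_parts), function(i) pts[starts[i]:ends[i], , drop = FALSE])
    geoms[[length(geoms) + 1]] <- assemble_shp_rings(rings)
  }
  dbf_path <- sub("\\.shp$", ".dbf", path, ignore.case = TRUE)
  props <- if (file.exists(dbf_path)) foreign::read.dbf(dbf_path, as.is = TRUE)
           else data.frame(row.names = seq_along(geoms))
  list(geoms = geoms, properties = props, crs_tag = NA_character_)
}

# shapefile winding: clockwise = exterior, counter-clockwise = hole
assemble_shp_rings <- function(rings) {
  rings <- lapply(rings, as_ring)
  sgn <- vapply(rings, ring_signed_area, 0)
  ext_idx <- which(sgn < 0)  # clockwise in shapefile = exterior
  hole_idx <- which(sgn >= 0)
  if (length(ext_idx) == 0) { ext_idx <- seq_along(rings); hole_idx <- integer(0) }
  polys <- lapply(ext_idx, function(i) list(rings[[i]]))
  for (h in hole_idx) {
    pt <- rings[[h]][1, , drop = FALSE]
    owner <- NULL
    for (k in seq_along(ext_idx)) {
      if (ring_crossings(rings[[ext_idx[k]]], pt[1], pt[2]) %% 2 == 1) { owner <- k; break }
    }
    if (is.null(owner)) owner <- 1L
    polys[[owner]][[length(polys[[owner]]) + 1]] <- rings[[h]]
  }
  mpoly(polys)
}
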