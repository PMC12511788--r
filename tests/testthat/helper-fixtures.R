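# Shared fixtures (built in code, cached per test run) and independent
# oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

get_benchmark <- function(seed = 1) {
  cached(paste0("benchmark_", seed), make_benchmark(seed))
}

get_calibration_fixture <- function(seed = 1) {
  cached(paste0("calfix_", seed), make_calibration_fixture(seed))
}

tiny_template <- function(seed = 7) {
  cached(paste0("tiny_", seed),
         generate_template(seed, n_subregions = 12, n_bioregions = 4,
                           n_ecoregions = 2, width = 1e5, height = 1e5))
}

# exhaustive-search oracle for Fisher-Jenks: all contiguous k-partitions of
# the sorted values, minimal within-class SSD
jenks_oracle <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    obj <- sum(vapply(seq_len(k), function(c)
      ssd(v[(cuts[c] + 1):cuts[c + 1]]), 0))
    if (obj < best) best <- obj
  }
  best
}

# independent entropy-based V-measure on a segment table (mutual-information
# formulation, distinct from the conditional-entropy code path)
vmeasure_oracle <- function(segments) {
  p <- segments$area / sum(segments$area)
  pa <- tapply(p, segments$category_a, sum)
  pb <- tapply(p, segments$category_b, sum)
  mi <- 0
  for (i in seq_len(nrow(segments))) {
    if (p[i] <= 0) next
    mi <- mi + p[i] * log(p[i] / (pa[[segments$category_a[i]]] *
                                    pb[[segments$category_b[i]]]))
  }
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  Ha <- H(pa); Hb <- H(pb)
  h <- if (Hb == 0) 1 else mi / Hb
  cc <- if (Ha == 0) 1 else mi / Ha
  if (h + cc == 0) 0 else 2 * h * cc / (h + cc)
}

# minimal single-part polygon shapefile writer (one ring per feature),
# independent of the package reader
write_mini_shapefile <- function(path, rings, fields) {
  shp <- file(path, "wb")
  recs <- list()
  for (i in seq_along(rings)) {
    r <- rings[[i]]
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    # shapefile exterior rings are clockwise
    xs <- r[, 1]; ys <- r[, 2]
    if (sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2 > 0)
      r <- r[rev(seq_len(nrow(r))), ]
    recs[[i]] <- r
  }
  n_words <- function(np) 24 + 8 * np
  total_words <- (100 + sum(vapply(recs, function(r) 8 + 2 * n_words(nrow(r)), 0))) / 2
  allx <- unlist(lapply(recs, function(r) r[, 1]))
  ally <- unlist(lapply(recs, function(r) r[, 2]))
  writeBin(as.integer(c(9994, 0, 0, 0, 0, 0, total_words)), shp,
           size = 4, endian = "big")
  writeBin(as.integer(c(1000, 5)), shp, size = 4, endian = "little")
  writeBin(c(min(allx), min(ally), max(allx), max(ally), 0, 0, 0, 0), shp,
           size = 8, endian = "little")
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    writeBin(as.integer(c(i, n_words(nrow(r)))), shp, size = 4, endian = "big")
    writeBin(5L, shp, size = 4, endian = "little")
    writeBin(c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2])), shp,
             size = 8, endian = "little")
    writeBin(c(1L, nrow(r)), shp, size = 4, endian = "little")
    writeBin(0L, shp, size = 4, endian = "little")
    writeBin(as.numeric(t(r)), shp, size = 8, endian = "little")
  }
  close(shp)
  foreign::write.dbf(fields, sub("\\.shp$", ".dbf", path))
  invisible(path)
}

# size classification with hand-set classes, for thinning arithmetic tests
manual_classification <- function(class_of) {
  structure(list(breaks = numeric(0), class_of = class_of,
                 table = data.frame(unit_id = names(class_of),
                                    log_area = NA_real_,
                                    class = unname(class_of))),
            class = "size_classification")
}

# occurrence set with prescribed per-unit retained counts
occ_with_counts <- function(counts, species = "sp") {
  units <- rep(names(counts), counts)
  n <- length(units)
  rec <- data.frame(record_id = paste0(species, "#", seq_len(n)),
                    x = runif(n), y = runif(n), year = 2000L,
                    unit_id = units, status = "retained",
                    stringsAsFactors = FALSE)
  structure(list(species = species, records = rec,
                 provenance = data.frame(filter = character(0),
                                         removed = integer(0))),
            class = "occurrence_set")
}
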