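test_that("templates load from GeoJSON with computed areas and validation", {
  tm <- tiny_template()
  tmp <- withr::local_tempfile(fileext = ".geojson")
  write_template(tm, tmp)
  got <- load_template(tmp)
  expect_s3_class(got, "eoo_template")
  expect_equal(nrow(got$units), 12)
  expect_true(length(unique(got$units$bioregion_id)) <= 12)
  # areas recomputed from geometry, not read from the attribute table
  expect_equal(sum(got$units$area_km2), 1e10 / 1e6, tolerance = 1e-9)
  expect_error(load_template(tmp, parent_fields = c("nope", "ecoregion_id")),
               "lacks required fields")
})

test_that("geographic-degree coordinates are rejected with a CRS error", {
  tmp <- withr::local_tempfile(fileext = ".geojson")
  ring <- rect_ring(140, -40, 150, -30)  # plausible lon/lat box
  write_geojson(list(mpoly(ring)),
                data.frame(unit_id = "U1", bioregion_id = "B1",
                           ecoregion_id = "E1"), tmp)
  expect_error(load_template(tmp), "projected")
})

test_that("min-area filter removes strictly-below-threshold units", {
  # areas 0.5, 1.0, 2.0 km^2: the 1 km^2 unit is retained
  side <- sqrt(c(0.5, 1, 2)) * 1000
  geoms <- lapply(seq_along(side), function(i)
    mpoly(rect_ring((i - 1) * 3000, 0, (i - 1) * 3000 + side[i], side[i])))
  units <- data.frame(unit_id = c("U1", "U2", "U3"),
                      bioregion_id = "B1", ecoregion_id = "E1",
                      name = c("U1", "U2", "U3"),
                      area_km2 = c(0.5, 1, 2), size_class = NA_character_,
                      stringsAsFactors = FALSE)
  tm <- eoomapr:::new_template(units, setNames(geoms, units$unit_id),
                               "subregion", "test")
  out <- suppressMessages(filter_min_area(tm, 1))
  expect_equal(out$units$unit_id, c("U2", "U3"))
  expect_equal(attr(out, "removed"), 1)
  expect_equal(nrow(filter_min_area(tm, 0)$units), 3)
  expect_error(filter_min_area(tm, 10), "every unit")
})

test_that("Fisher-Jenks matches hand-worked clusters and handles edge cases", {
  jb <- jenks_breaks(c(1, 2, 3, 10, 11, 12, 100, 101, 102), 3)
  expect_equal(jb$assignment, rep(1:3, each = 3))
  expect_equal(jb$breaks, c(3, 12))
  # n distinct values = k: each value its own class, objective zero
  jb2 <- jenks_breaks(c(5, 1, 9), 3)
  expect_equal(jb2$objective, 0)
  expect_equal(sort(unique(jb2$assignment)), 1:3)
  # identical values always share a class
  jb3 <- jenks_breaks(c(1, 1, 1, 1, 9, 9), 2)
  expect_equal(jb3$assignment, c(1, 1, 1, 1, 2, 2))
  expect_error(jenks_breaks(c(1, 2), 3), "distinct")
  expect_error(jenks_breaks(c(1, NA, 3), 2), "finite")
})

test_that("Fisher-Jenks DP equals the exhaustive-search optimum", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    k <- sample(2:4, 1)
    if (k > n) next
    v <- round(rexp(n, 0.1), 3)
    v <- v + seq_along(v) * 1e-6  # force distinct values
    jb <- jenks_breaks(v, k)
    expect_equal(jb$objective, jenks_oracle(v, k), tolerance = 1e-9)
  }
})

test_that("size classification is monotone in area and scale invariant", {
  areas <- exp(c(1, 2, 3, 10, 11, 12, 20, 21, 22))
  geoms <- lapply(seq_along(areas), function(i) {
    s <- sqrt(areas[i] * 1e6)
    mpoly(rect_ring(i * 1e5, 0, i * 1e5 + s, s))
  })
  units <- data.frame(unit_id = sprintf("U%02d", seq_along(areas)),
                      bioregion_id = "B1", ecoregion_id = "E1",
                      name = "x", area_km2 = areas, size_class = NA_character_,
                      stringsAsFactors = FALSE)
  tm <- eoomapr:::new_template(units, setNames(geoms, units$unit_id),
                               "subregion", "test")
  sc <- classify_size(tm)
  expect_equal(unname(sc$class_of),
               rep(c("small", "medium", "large"), each = 3))
  # monotone: every small area below every large area
  a <- tm$units$area_km2
  expect_lt(max(a[sc$class_of == "small"]), min(a[sc$class_of == "large"]))
  # multiplying all areas by a constant shifts logs, classes unchanged
  tm2 <- tm; tm2$units$area_km2 <- areas * 37.5
  expect_equal(classify_size(tm2)$class_of, sc$class_of)
  tm3 <- tm; tm3$units$area_km2 <- rep(4, 9)
  expect_error(classify_size(tm3), "distinct")
})

test_that("aggregation dissolves by parent and conserves area", {
  tm <- tiny_template()
  bio <- aggregate_level(tm, "bioregion")
  eco <- aggregate_level(tm, "ecoregion")
  expect_equal(nrow(bio$units), length(unique(tm$units$bioregion_id)))
  expect_equal(nrow(eco$units), length(unique(tm$units$ecoregion_id)))
  expect_equal(sum(bio$units$area_km2), sum(tm$units$area_km2),
               tolerance = 1e-9)
  expect_equal(sum(eco$units$area_km2), sum(tm$units$area_km2),
               tolerance = 1e-9)
  # parent counts never exceed child counts
  expect_lte(nrow(eco$units), nrow(bio$units))
  expect_lte(nrow(bio$units), nrow(tm$units))
  expect_error(aggregate_level(tm, "continent"))
})
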