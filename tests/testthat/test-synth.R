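test_that("synthetic templates have the requested nested structure", {
  tm <- generate_template(3, n_subregions = 50, n_bioregions = 10,
                          n_ecoregions = 4)
  expect_equal(nrow(tm$units), 50)
  expect_equal(length(unique(tm$units$bioregion_id)), 10)
  expect_equal(length(unique(tm$units$ecoregion_id)), 4)
  # nesting: each bioregion maps to exactly one ecoregion
  nest <- unique(tm$units[, c("bioregion_id", "ecoregion_id")])
  expect_equal(nrow(nest), 10)
  # units tile the extent: areas sum to the extent area
  expect_equal(sum(tm$units$area_km2), 1e12 / 1e6, tolerance = 1e-9)
  expect_error(generate_template(1, n_subregions = 5, n_bioregions = 9),
               "n_ecoregions|n_bioregions")
})

test_that("template generation is byte-deterministic per seed", {
  f1 <- withr::local_tempfile(fileext = ".geojson")
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_template(generate_template(17), f1)
  write_template(generate_template(17), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    generate_template(17)$units$area_km2,
    generate_template(18)$units$area_km2))
})

test_that("unit areas span at least two orders of magnitude at defaults", {
  for (seed in c(1, 7)) {
    a <- generate_template(seed)$units$area_km2
    expect_gte(max(a) / min(a), 100)
  }
})

test_that("species archetypes have the designed mixture structure", {
  rr <- generate_species(5, "range_restricted")
  expect_equal(length(rr$weights), 1)
  ws <- generate_species(5, "wide_ranging")
  expect_gte(length(ws$weights), 3)
  hs <- generate_species(5, "habitat_specialist")
  expect_gte(length(hs$weights), 2)
  for (tr in list(rr, ws, hs)) {
    expect_equal(sum(tr$weights), 1)
    expect_true(all(tr$means >= 0 & tr$means <= 1e6))
    for (S in tr$covs) expect_gt(det(S), 0)
  }
  # wide-ranging 99% HDR dwarfs the range-restricted one (shipped seeds)
  expect_gt(true_hdr(ws, 0.99, lattice_n = 256)$area_km2,
            true_hdr(rr, 0.99)$area_km2)
})

test_that("single-component analytic HDR matches the chi-square ellipse", {
  tr <- generate_species(2, "range_restricted")
  th <- true_hdr(tr, 0.99)
  expect_true(th$exact)
  expect_equal(th$area_km2,
               pi * qchisq(0.99, 2) * sqrt(det(tr$covs[[1]])) / 1e6,
               tolerance = 1e-3)
  expect_equal(mp_area(th$polygons) / 1e6, th$area_km2, tolerance = 1e-3)
  # nesting and symmetry of the ellipse around the mean
  th95 <- true_hdr(tr, 0.95)
  expect_lt(th95$area_km2, th$area_km2)
  ctr <- colMeans(th$polygons[[1]][[1]])
  expect_equal(ctr, unname(tr$means[1, ]), tolerance = 1e-6)
  expect_true(all(th$contains(matrix(tr$means[1, ], 1, 2))))
})

test_that("mixture lattice HDR nests and agrees with the ellipse oracle", {
  tr <- generate_species(4, "habitat_specialist")
  h99 <- true_hdr(tr, 0.99, lattice_n = 512)
  h95 <- true_hdr(tr, 0.95, lattice_n = 512)
  expect_lt(h95$area_km2, h99$area_km2)
  expect_gt(h99$threshold, 0)
  # lattice oracle on a single component reproduces the closed form
  rr <- generate_species(2, "range_restricted")
  lat <- true_hdr(rr, 0.99, lattice_n = 1024,
                  extent = mpoly(rect_ring(0, 0, 1e6, 1e6)))
  expect_equal(lat$area_km2, true_hdr(rr, 0.99)$area_km2, tolerance = 0.01)
})

test_that("occurrence sampling reproduces the mixture and flags outliers", {
  tr <- generate_species(6, "habitat_specialist")
  o <- sample_occurrences(tr, 1500, seed = 2)
  xy <- cbind(o$records$x, o$records$y)
  mix_mean <- colSums(tr$means * tr$weights)
  mix_sd <- sqrt(max(vapply(tr$covs, function(S) max(diag(S)), 0)) +
                   max(rowSums(sweep(tr$means, 2, mix_mean)^2)))
  se <- mix_sd / sqrt(1500)
  expect_lt(abs(mean(xy[, 1]) - mix_mean[1]), 3 * 3 * se)
  expect_lt(abs(mean(xy[, 2]) - mix_mean[2]), 3 * 3 * se)
  expect_equal(sum(o$records$is_outlier), 0)
  o2 <- sample_occurrences(tr, 1000, seed = 2, outlier_rate = 0.02)
  n_out <- sum(o2$records$is_outlier)
  expect_gt(n_out, 5); expect_lt(n_out, 45)
  expect_true(all(is.na(o2$records$component[o2$records$is_outlier])))
  # determinism
  o3 <- sample_occurrences(tr, 1000, seed = 2, outlier_rate = 0.02)
  expect_identical(o2$records, o3$records)
})

test_that("accessibility bias tilts per-unit counts toward accessible units", {
  tm <- generate_template(9)
  bias <- bias_surface(31)
  tr <- generate_species(12, "wide_ranging")
  o <- sample_occurrences(tr, 1200, seed = 13, bias = bias)
  o <- assign_units(preprocess_occurrences(o, template_extent(tm)), tm)
  counts <- table(factor(o$records$unit_id[o$records$status == "retained"],
                         levels = tm$units$unit_id))
  # mean bias weight per unit (coarse within-unit sample)
  wbar <- vapply(tm$units$unit_id, function(u) {
    bb <- mp_bbox(tm$geoms[[u]])
    gx <- seq(bb[1], bb[3], length.out = 6)
    gy <- seq(bb[2], bb[4], length.out = 6)
    pts <- as.matrix(expand.grid(gx, gy))
    inside <- mp_contains(tm$geoms[[u]], pts)
    mean(bias$weight(pts[inside, , drop = FALSE]))
  }, 0)
  dens <- as.numeric(counts) / tm$units$area_km2
  keep <- as.numeric(counts) > 0
  expect_gt(suppressWarnings(cor(dens[keep], wbar[keep], method = "spearman")), 0)
})

test_that("the benchmark bundle is complete, thinned and reproducible", {
  bm <- get_benchmark()
  expect_length(bm$occ, 6)
  expect_setequal(unique(vapply(bm$ranges, function(tr) tr$archetype, "")),
                  c("wide_ranging", "habitat_specialist", "range_restricted"))
  for (o in bm$occ) {
    expect_gte(n_records(o), 100)
    expect_true(meets_min_sample(o))
  }
  expect_equal(nrow(bm$template$units), 100)
  # determinism of the full bundle
  bm2 <- make_benchmark(1)
  expect_identical(bm$occ$range_restricted_5$records,
                   bm2$occ$range_restricted_5$records)
})
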