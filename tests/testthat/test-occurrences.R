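test_that("occurrence CSVs load per species with malformed rows reported", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,x,y,year",
               "spA,100,200,2001",
               "spA,150,250,2002",
               "spB,300,400,1999",
               "spA,oops,250,2003",
               "spA,100,200,2001"), tmp)
  sets <- load_occurrences(tmp)
  expect_named(sets, c("spA", "spB"))
  expect_equal(nrow(sets$spA$records), 3)  # duplicate coordinates retained
  expect_equal(nrow(sets$spB$records), 1)
  expect_equal(unname(attr(sets, "malformed")["spA"]), 1)
  expect_equal(sets$spA$provenance$removed[
    sets$spA$provenance$filter == "malformed"], 1)
  expect_error(load_occurrences(tmp, column_map = c(species = "sp", x = "x",
                                                    y = "y", year = "year")),
               "lacks columns")
})

test_that("preprocessing applies the coordinate, year-cutoff and extent rules", {
  ext <- mpoly(rect_ring(0, 0, 1000, 1000))
  occ <- occurrence_set("sp", rbind(c(500, 500), c(500, 500), c(500, 500),
                                    c(1001, 500), c(NA, 500)),
                        year = c(1989L, 1990L, 2005L, 2000L, 2000L))
  out <- preprocess_occurrences(occ, ext)
  st <- out$records$status
  expect_equal(st[1], "filtered_out_year")    # 1989 removed
  expect_equal(st[2], "retained")             # 1990 kept
  expect_equal(st[3], "retained")
  expect_equal(st[4], "filtered_out_extent")  # outside extent
  expect_equal(st[5], "filtered_out_coords")
  expect_equal(sum(out$provenance$removed), 3)
  # empty input passes through
  empty <- preprocess_occurrences(occurrence_set("sp", matrix(0, 0, 2)), ext)
  expect_equal(nrow(empty$records), 0)
})

test_that("unit assignment is deterministic with lexicographic boundary ties", {
  tm <- tiny_template()
  ext <- template_extent(tm)
  set.seed(3)
  pts <- cbind(runif(200, 0, 1e5), runif(200, 0, 1e5))
  occ <- preprocess_occurrences(occurrence_set("sp", pts), ext)
  occ <- assign_units(occ, tm)
  assigned <- occ$records$unit_id[occ$records$status == "retained"]
  expect_true(all(!is.na(assigned)))
  expect_true(all(assigned %in% tm$units$unit_id))
  # boundary point between two units gets the smaller id
  u2 <- mpoly(rect_ring(0, 0, 10, 10)); u5 <- mpoly(rect_ring(10, 0, 20, 10))
  units <- data.frame(unit_id = c("U5", "U2"), bioregion_id = "B1",
                      ecoregion_id = "E1", name = "x", area_km2 = 1e-4,
                      size_class = NA_character_, stringsAsFactors = FALSE)
  tm2 <- eoomapr:::new_template(units, list(U5 = u5, U2 = u2), "subregion", "t")
  o <- occurrence_set("sp", rbind(c(10, 5)))
  o$records$status <- "retained"
  o <- assign_units(o, tm2)
  expect_equal(o$records$unit_id, "U2")
})

test_that("biogeographic thinning caps at the ceiling of the class mean", {
  sc <- manual_classification(c(U1 = "small", U2 = "small", U3 = "small"))
  occ <- occ_with_counts(c(U1 = 10, U2 = 4, U3 = 1))
  out <- biogeographic_thin(occ, sc, seed = 11)
  counts <- table(out$records$unit_id[out$records$status == "kept"])
  expect_equal(as.integer(counts[c("U1", "U2", "U3")]), c(5, 4, 1))
  expect_equal(unname(attr(out, "caps")["small"]), 5L)
  # all counts under cap: identity
  occ2 <- occ_with_counts(c(U1 = 3, U2 = 4))
  out2 <- biogeographic_thin(occ2, sc, seed = 11)
  expect_equal(sum(out2$records$status == "kept"), 7)
})

test_that("thinning is seed-deterministic and idempotent under frozen caps", {
  sc <- manual_classification(setNames(rep("small", 4), paste0("U", 1:4)))
  occ <- occ_with_counts(c(U1 = 30, U2 = 8, U3 = 2, U4 = 1))
  a <- biogeographic_thin(occ, sc, seed = 5)
  b <- biogeographic_thin(occ, sc, seed = 5)
  kept_ids <- function(o) sort(o$records$record_id[o$records$status == "kept"])
  expect_identical(kept_ids(a), kept_ids(b))
  d <- biogeographic_thin(occ, sc, seed = 6)
  expect_equal(length(kept_ids(d)), length(kept_ids(a)))  # counts match
  # re-thinning an already-thinned set under frozen caps is the identity
  a2 <- a
  a2$records <- a$records[a$records$status == "kept", , drop = FALSE]
  a2$records$status <- "retained"
  rethin <- biogeographic_thin(a2, sc, seed = 99, caps = attr(a, "caps"))
  expect_identical(sort(kept_ids(rethin)), kept_ids(a))
})

test_that("thinning never raises per-unit counts and flattens sampling bias", {
  tm <- tiny_template()
  sc <- classify_size(tm)
  set.seed(8)
  pts <- cbind(runif(600, 0, 1e5), runif(600, 0, 1e5))
  occ <- assign_units(preprocess_occurrences(occurrence_set("sp", pts),
                                             template_extent(tm)), tm)
  out <- biogeographic_thin(occ, sc, seed = 4)
  before <- table(occ$records$unit_id[occ$records$status == "retained"])
  after <- table(out$records$unit_id[out$records$status == "kept"])
  expect_true(all(after[names(after)] <= before[names(after)]))
  caps <- attr(out, "caps")
  cls <- sc$class_of[names(after)]
  expect_true(all(as.integer(after) <= caps[cls]))
  # coefficient of variation within each class does not increase
  for (cl in unique(cls)) {
    u <- names(after)[cls == cl]
    cv <- function(x) if (mean(x) == 0) 0 else sd(x) / mean(x)
    expect_lte(cv(as.numeric(after[u])), cv(as.numeric(before[u])) + 1e-12)
  }
})

test_that("minimum-sample rule sits exactly at the threshold", {
  sc <- manual_classification(c(U1 = "small"))
  occ20 <- biogeographic_thin(occ_with_counts(c(U1 = 20)), sc, seed = 1)
  occ19 <- biogeographic_thin(occ_with_counts(c(U1 = 19)), sc, seed = 1)
  expect_true(meets_min_sample(occ20))
  expect_false(meets_min_sample(occ19))
  occ0 <- occ_with_counts(c(U1 = 1))
  occ0$records$status <- "filtered_out_extent"
  expect_false(meets_min_sample(suppressWarnings(
    biogeographic_thin(occ0, sc, seed = 1))))
  expect_true(meets_min_sample(occ19, n_min = 0))
})
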