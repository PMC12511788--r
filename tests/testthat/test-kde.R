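test_that("reference bandwidth matches the hand-evaluated formula", {
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  bw <- reference_bandwidth(pts)
  h <- 0.5 * (sd(pts[, 1]) + sd(pts[, 2])) * 4^(-1 / 6)
  expect_equal(sqrt(bw$H[1, 1]), h, tolerance = 1e-12)
  expect_equal(h, 0.9165, tolerance = 1e-4)
  expect_equal(bw$H[1, 2], 0)
  # homogeneity: scaling coordinates by c scales h by c
  bw10 <- reference_bandwidth(pts * 10)
  expect_equal(sqrt(bw10$H[1, 1]), 10 * h, tolerance = 1e-12)
  expect_error(reference_bandwidth(rbind(c(1, 1), c(1, 1), c(1, 2))),
               "variance")
})

test_that("plug-in selector approaches the normal-scale optimum on Gaussian data", {
  set.seed(101)
  errs <- vapply(c(100, 400), function(n) {
    median(vapply(1:6, function(r) {
      x <- matrix(rnorm(2 * n), n, 2)
      H <- plugin_bandwidth(x)$H
      Ho <- n^(-1 / 3) * diag(2)
      norm(H - Ho, "F") / norm(Ho, "F")
    }, 0))
  }, 0)
  expect_lt(errs[2], errs[1])   # consistency: error shrinks with n
  expect_lt(errs[2], 0.25)
  expect_error(plugin_bandwidth(cbind(1:30, 2 * (1:30))), "singular")
})

test_that("plug-in selector is affine equivariant and scale homogeneous", {
  set.seed(21)
  x <- rbind(matrix(rnorm(200), 100, 2),
             matrix(rnorm(160, mean = 4, sd = 0.5), 80, 2))
  H <- plugin_bandwidth(x)$H
  A <- matrix(c(2, 0.4, -0.3, 1.2), 2, 2)
  Ht <- plugin_bandwidth(x %*% t(A))$H
  expect_equal(Ht, A %*% H %*% t(A), tolerance = 0.02)
  Hs <- plugin_bandwidth(x * 50)$H
  expect_equal(Hs, 2500 * H, tolerance = 0.02)
})

test_that("density evaluation reproduces kernel superposition values", {
  # single point: density at the point is the kernel mode 1/(2 pi)
  expect_equal(kde_eval(matrix(0, 1, 2), diag(2), matrix(0, 1, 2)),
               1 / (2 * pi), tolerance = 1e-12)
  # two points >= 10 sigma apart: peak at each is 1/(4 pi)
  pts <- rbind(c(0, 0), c(30, 0))
  expect_equal(kde_eval(pts, diag(2), pts), rep(1 / (4 * pi), 2),
               tolerance = 1e-9)
  # lattice evaluation conserves mass within the documented invariant
  set.seed(5)
  x <- matrix(rnorm(400), 200, 2)
  g <- evaluate_density(x, diag(0.1, 2), grid_n = 256)
  expect_gte(g$total_mass, 0.98)
  expect_lte(g$total_mass, 1.001)
  expect_true(all(g$values >= 0))
  # a grid far too small to hold the kernel mass errors out
  expect_error(evaluate_density(x, diag(0.1, 2),
                                grid = list(origin = c(0, 0), delta = 0.05,
                                            nx = 10, ny = 10)),
               "mass")
})

test_that("HDR threshold recovers the Gaussian closed form and prefix rule", {
  n <- 512
  xs <- seq(-5, 5, length.out = n)
  g <- density_grid(outer(dnorm(xs), dnorm(xs)), origin = c(-5, -5),
                    delta = xs[2] - xs[1])
  expect_equal(hdr_threshold(g, 0.99), 0.01 / (2 * pi), tolerance = 0.02)
  expect_equal(hdr_threshold(g, 0.95), 0.05 / (2 * pi), tolerance = 0.02)
  # p = 1 includes every positive cell
  expect_equal(hdr_threshold(g, 1), min(g$values[g$values > 0]))
  # two-cell grid, masses 0.6/0.4: p = 0.95 needs both cells
  g2 <- density_grid(matrix(c(0.6, 0.4), 1, 2), c(0, 0), 1)
  expect_equal(hdr_threshold(g2, 0.95), 0.4)
  expect_equal(hdr_threshold(g2, 0.5), 0.6)
})

test_that("confidence regions match the chi-square area law and nest", {
  n <- 512
  xs <- seq(-5, 5, length.out = n)
  g <- density_grid(outer(dnorm(xs), dnorm(xs)), origin = c(-5, -5),
                    delta = xs[2] - xs[1])
  cr99 <- extract_confidence_region(g, hdr_threshold(g, 0.99), 0.99)
  cr95 <- extract_confidence_region(g, hdr_threshold(g, 0.95), 0.95)
  expect_equal(cr99$area_km2 * 1e6, pi * (-2 * log(0.01)), tolerance = 0.02)
  expect_equal(cr95$area_km2 * 1e6, pi * (-2 * log(0.05)), tolerance = 0.02)
  expect_equal(cr99$n_components, 1)
  expect_lt(cr95$area_km2, cr99$area_km2)
  # the realised mass above threshold honours the reported tolerance
  expect_lt(abs(cr99$mass - 0.99), max(cr99$mass_tol, 5e-3))
  # 99% region geometrically contains the 95% region
  ring95 <- cr95$polygons[[1]][[1]]
  expect_true(all(mp_contains(cr99$polygons, ring95)))
  expect_error(extract_confidence_region(g, 2 * max(g$values), 0.99),
               "empty|exceeds")
})

test_that("mixture HDRs merge components as coverage grows", {
  # equal Gaussians at +/-3: two components at 95%, one at 99%
  n <- 512
  xs <- seq(-8, 8, length.out = n)
  f <- 0.5 * outer(dnorm(xs, -3), dnorm(xs)) +
       0.5 * outer(dnorm(xs, 3), dnorm(xs))
  g <- density_grid(f, origin = c(-8, -8), delta = xs[2] - xs[1])
  cr95 <- extract_confidence_region(g, hdr_threshold(g, 0.95), 0.95)
  cr99 <- extract_confidence_region(g, hdr_threshold(g, 0.99), 0.99)
  expect_equal(cr95$n_components, 2)
  expect_lte(cr99$n_components, cr95$n_components)
})

test_that("EOO composition refuses small samples and clips to the extent", {
  bm <- get_calibration_fixture()
  occ <- bm$occ$range_restricted_5
  small <- occ
  small$records <- small$records[1:30, , drop = FALSE]
  small$records$status <- "kept"
  expect_error(build_eoo(small, bm$template, n_min = 200), "minimum")
  m <- build_eoo(occ, bm$template, grid_n = 256, seed = 1)
  expect_s3_class(m, "eoo_map")
  expect_lte(m$region$area_km2, m$unclipped$area_km2 + 1e-9)
  expect_true(m$params$clip_exact)
  # every kept point inside the template lies within the clip of its own EOO
  expect_equal(m$params$n_used, n_records(occ))
})

test_that("Monte Carlo minimum-sample error agrees with the closed form", {
  r <- kde_min_sample_rmse(n = 20, reps = 400, seed = 3)
  expect_equal(r$rel_mse, r$rel_mse_exact, tolerance = 0.15)
  # the closed form at the optimum is below the classical 0.1 criterion
  expect_lt(r$rel_mse_exact, 0.1)
  # and sample size 20 sits just past the boundary: n = 10 fails it
  expect_gt(kde_mode_rmse_exact(10), 0.1)
})
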