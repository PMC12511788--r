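---
title: "Methods: data-driven extent-of-occurrence mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven extent-of-occurrence mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoomapr)
```

## The estimation problem

Expert-drawn range maps are inconsistent in how precisely they delineate
range edges and subpopulations. `eoomapr` estimates a species' extent of
occurrence (EOO) directly from presence-only occurrence records, anchored to
a nested biogeographic template (operational units such as subregions nested
in bioregions nested in ecoregions, in a projected equal-area CRS). The
estimate is the p% highest-density region (HDR) of a bivariate Gaussian
kernel estimate of the species' utilization distribution (UD), extracted as
polygons rather than grid cells, so the map product carries no arbitrary
raster structure.

Two practical obstacles drive the design. First, presence-only records are
spatially biased toward accessible places, so the raw point pattern is not a
sample from the UD. Second, kernel estimates are sensitive to the bandwidth:
too much smoothing inflates the EOO far beyond plausible range edges.

## Biogeographic thinning

Sampling effort is evened out *per species* across the template before
estimation:

1. Unit areas (km², always computed from geometry) are log-transformed and
   split into three size classes — small, medium, large — by exact
   Fisher–Jenks natural-breaks optimisation (`jenks_breaks()`, an O(kn²)
   dynamic programme over the distinct values, so identical areas always
   share a class; among equal-objective partitions the smallest first break
   is chosen for determinism). Any log base gives the same classes, since
   logs differ by a monotone affine map; we use the natural log.
2. For each size class, the per-unit record count is capped at
   `ceiling(mean(count over occupied units of that class))` and over-cap
   units are subsampled uniformly without replacement. The mean is taken
   over *occupied* units only: including empty units would drive caps toward
   zero and defeat the goal of balancing representation while keeping
   ecological variation. Caps are per species; pooling across species would
   couple unrelated taxa. `ceiling` keeps every cap at least 1 and never
   pushes a unit below the class mean.
3. Randomness is scoped: each unit's subsample comes from a substream seeded
   by `(seed, unit_id)`, so adding or removing one species or unit never
   perturbs another's sample. Exact duplicate records are retained (an
   optional pre-filter exists but defaults to off).

Records are first filtered for missing coordinates, collection year before
1990 (1990 itself is kept; records with no year are treated as failing the
cutoff), and positions outside the template extent; every rule's removal
count is logged in the set's provenance table. A species qualifies for
estimation only with ≥ 20 records after thinning. That threshold matches the
classical minimum-sample analysis for bivariate kernel density estimation:
with the isotropic bandwidth that minimises the exact mean-square error at
the mode of a standard bivariate normal, the relative MSE at the mode drops
below 0.1 at a sample size of about 19–20
(`kde_mode_rmse_exact()` gives the closed form; `kde_min_sample_rmse()`
verifies it by Monte Carlo).

## Bandwidth selection

Two selectors are implemented:

* **Reference (ad hoc) bandwidth** — the isotropic normal-reference rule of
  home-range analysis, `h = 0.5 (sd_x + sd_y) n^(-1/6)`, `H = h² I`
  (units m²). It assumes a unimodal, roughly Gaussian UD and therefore
  over-smooths clustered data.
* **Two-stage plug-in bandwidth** — minimises the asymptotic MISE surrogate

  `PI(H) = (4 pi n)^{-1} |H|^{-1/2} + (1/4) vech(H)' Psi4 vech(H)`

  over symmetric positive-definite 2×2 matrices, where `Psi4` collects the
  fourth-order integrated density-derivative functionals
  `psi_r = ∫ f^{(r)} f`. Data are pre-sphered; the functionals are estimated
  by the Gaussian-kernel double sum with an isotropic pilot whose width
  comes from a normal-scale sixth-order stage (for sphered data the
  bias-annihilating pilot is `g = (16 / (3 n))^{1/8}`, the same width for
  the (4,0)/(0,4) and (2,2) functionals under a Gaussian sixth-order
  reference). The optimisation runs over the unconstrained Cholesky-log
  parameterisation with a Nelder–Mead start at the normal-scale matrix
  `n^{-1/3} I`; for Gaussian truth the PI minimiser coincides with the
  normal-scale optimum `n^{-1/3} Σ`, which the test suite uses as the
  consistency oracle.

  One numerical guard: the sphering covariance is estimated with an
  iterative Mahalanobis trim at the 99.9% chi-square quantile. The trim is
  deterministic and affine-equivariant and leaves clean samples essentially
  untouched, but prevents a handful of gross vagrant records from inflating
  the sphering scale (and hence `|H|`) severalfold. No records are removed
  from the density estimate itself — vagrancy handling is deliberately left
  to the confidence-region level.

## Density lattice and confidence regions

The KDE is evaluated on an internal lattice (default 512×512) padded by 3.5
kernel standard deviations around the data bounding box; a run whose lattice
captures less than 98% of the kernel mass is an error rather than a silent
under-estimate. The HDR threshold is the density of the last cell in the
smallest prefix of cells (sorted by decreasing density) whose cumulative
mass reaches `p`; cells tying with the threshold are included. Region
polygons come from marching-squares contouring of the density field at the
threshold (with a zero border so all contours close), assembled into
polygons with holes by even-odd containment depth; exteriors are
counter-clockwise, holes clockwise, and holes are preserved because they
encode subpopulation structure. The region is then clipped to the template
extent. The lattice is an evaluation device only: the map product is the
polygon set, so "grid-free" here means no presence/absence gridding of the
final map, not the absence of an internal lattice. Clipping happens after
contouring, so the confidence region is defined by the UD alone and the
coastline only trims it.

The calibration sweep (`calibrate_kde()`) tabulates area and component
count for reference/plug-in × 95%/99% per species. On clustered synthetic
data the reference bandwidth produces uniformly larger regions than the
plug-in — the over-smoothing direction that motivates the plug-in + 99%
default (`method = "plugin"`, `p = 0.99` throughout the pipeline).

## Map comparison

Presence-absence maps are two-category partitions of the template extent.
Agreement between two maps is the area-weighted spatial V-measure: with
joint category probabilities `p_ij = area_ij / area_total` from the polygon
overlay, homogeneity `h = 1 − H(B|A)/H(B)`, completeness
`c = 1 − H(A|B)/H(A)` (natural-log entropies; defined as 1 when the
unconditional entropy is 0), and `v = 2hc/(h+c)` (0 when `h + c = 0`), with
the β weight fixed at 1. Overlay areas are computed by exact vector clipping
whenever one operand decomposes into convex rings, and otherwise on a dense
cell-centre lattice whose resolution is reported — the implementation
records which route produced each number.

Richness is compared per unit at the three nested scales: a species is
present in a unit when its presence polygon intersects the unit with
positive area (boundary touching does not count; a minimum-fraction option
exists, default 0). Presence at coarser levels is the logical OR over child
subregions, which for nested units equals the direct geometric rule. The
error decomposition is RMSE (variation) and signed mean error
(data-driven minus expert; bias).

## The synthetic study system

`generate_template()` builds an irregular nested template: Voronoi cells of
seeded points in a rectangular extent (computed exactly by half-plane
clipping, so every unit is convex), with half the seeds concentrated in a
block of 0.5% of the extent so unit areas span more than two orders of
magnitude; contiguous parent regions come from nearest-centre clustering
with connectivity repair over the realised cell adjacency. Species ranges
are Gaussian mixtures in three archetypes: wide-ranging (3–5 broad
components, axis scales 10–18% of the extent), habitat-specialist (2–4
narrow components, 2.5–6%, clustered), and range-restricted (one tight
component, 1.5–4%). Sampling draws from the mixture truncated to the
extent, thins through an accessibility-bias surface (distance decay around
random access lines, `w = 0.2 + exp(−d/80 km)`), replaces a configurable
fraction with uniform vagrants (flagged in ground truth), and assigns years
uniformly. Analytic HDR oracles are available: the exact chi-square ellipse
(area `π q_p √|Σ|`) for single components and a high-resolution lattice,
independent of the KDE code path, for mixtures.

The default benchmark (`make_benchmark()`) uses a 100/20/8 template — the
410/85/37 proportions of a continental system at reduced scale — with draw
sizes 800/600/650 per archetype pair chosen so every species retains at
least 100 records after thinning, and a 2% vagrant rate. The calibration
fixture (`make_calibration_fixture()`) keeps the biased sampling but no
vagrants, so the bandwidth/level comparison reflects the three
distributional structures rather than vagrancy handling.

What the generator does *not* emulate: real coastline geometry and
non-convex units, spatially autocorrelated detection within units, temporal
trends, taxonomic mis-matching, and coordinate uncertainty. Passing
recovery tests on this benchmark therefore shows the estimator chain is
correct under known ground truth, not that any particular real dataset is
bias-free.

## Thinning, vagrancy and the 99% region: a structural interaction

Two findings from the synthetic benchmark are worth stating prominently,
because they delimit what HDR-based EOO estimation can do.

First, *biogeographic thinning amplifies vagrant prevalence*. Thinning caps
dense core units but never touches a vagrant sitting alone in an otherwise
empty unit, so a 2% vagrant share among raw records can become 3–12% of the
records that survive thinning, most severely for range-restricted species
whose cores are crushed hardest.

Second, *a p% HDR cannot exclude more than (1 − p) of the estimate's mass*.
Each record carries kernel mass 1/n, so once the post-thinning vagrant share
exceeds `1 − p` (1% at the default `p = 0.99`), the threshold must fall low
enough to take in most vagrant kernels — inflating the region and attaching
one small component per vagrant. In that regime the 99% region mechanically
*gains* disjunct components relative to the 95% one, and recovery of the
generating range degrades for narrow-ranged archetypes. The same mechanism
operates at smaller scale even without vagrants: an isolated legitimate
record in the far tail of a range can surface as its own component at 99%
but not at 95%. The often-reported field experience that 99% regions are
*more* cohesive than 95% ones, and that they shed vagrants, belongs to the
regime of large datasets whose vagrancy is far below 1% of records; users
applying the pipeline to sparse data should check the post-thinning share
of suspect records against `1 − p` before trusting the region boundary.

## Numerical choices and problem sizes

Geometry is handled by an internal planar-polygon layer (shoelace areas,
even-odd point-in-polygon, Sutherland–Hodgman clipping against convex
rings, lattice-sampled intersection areas otherwise); there is no external
geometry engine, so validity repair is structural only (finite coordinates,
≥ 3 distinct vertices, nonzero area) and irreparable units are a hard
error, never a silent drop. All inputs must share one projected equal-area
CRS; the package checks for degree-like coordinates and refuses them but
performs no reprojection. The test suite exercises the pipeline end to end
at moderate sizes — 12–100-unit templates, 200–800 records per species,
512² density lattices, 300² comparison lattices, plug-in consistency at
n ∈ {100, 400, 1600} with 20 replicates — chosen so the whole suite runs in
a few minutes while each check still measures the property it names.

## Known limitations

* Areas from lattice-fallback overlays are approximate at the lattice
  resolution (reported per call); exact overlay requires one operand with
  convex rings.
* The plug-in selector assumes a nonsingular covariance; exactly collinear
  point sets are an error.
* Confidence-region mass is conserved only up to the lattice resolution;
  the realised mass and its tolerance are reported with every region.
* No boundary-corrected kernels: density mass falling outside the template
  is clipped, so coastal ranges are estimated slightly conservatively.
* Taxonomic reconciliation between data sources is out of scope; joins are
  by a pre-matched species key.
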