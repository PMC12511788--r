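# eoomapr

Reproducible, data-driven mapping of species' **extent of occurrence (EOO)**
from presence-only occurrence records and a nested biogeographic template.

Expert-drawn range maps are subjective and inconsistent in how precisely
they trace range edges and subpopulations, which distorts richness estimates
built on top of them. `eoomapr` replaces the expert polygon with an
estimate computed the same way for every species:

1. **Biogeographic thinning** — template units are classified into
   small/medium/large by exact Fisher–Jenks natural breaks on log area;
   per-unit record counts are capped at the ceiling of the class mean
   (occupied units only) and subsampled without replacement. Species keep
   ≥ 20 records or are refused — the classical minimum for a bivariate
   kernel density estimate to hold relative mode-MSE below 0.1.
2. **Calibrated kernel density estimation** — the utilization distribution
   f̂(x) = n⁻¹ Σᵢ φ_H(x − xᵢ) with a bivariate Gaussian kernel, where the
   bandwidth matrix H is either the ad hoc reference rule
   h = 0.5 (sd_x + sd_y) n^(−1/6), H = h²I, or the two-stage plug-in
   selector minimising PI(H) = (4πn)⁻¹|H|^(−1/2) + ¼ vech(H)ᵀ Ψ̂₄ vech(H).
3. **Confidence regions** — the p% highest-density region (smallest region
   holding p of the probability mass), contoured into polygons with holes
   by marching squares and clipped to the template extent. The pipeline
   default is the plug-in bandwidth with the 99% region.
4. **Evaluation** — agreement between two map sources via the area-weighted
   spatial V-measure (entropy-based homogeneity/completeness, v = 2hc/(h+c)),
   and per-unit species-richness RMSE (variation) and mean error (bias) at
   the three nested template scales.

A synthetic-data module generates Voronoi templates with a 3-level
hierarchy, Gaussian-mixture species ranges in three archetypes
(wide-ranging, habitat-specialist, range-restricted), accessibility-biased
sampling and labelled vagrant outliers — so the whole pipeline is testable
against analytic ground truth without any data download.

## Worked example

```r
library(eoomapr)

# a fully synthetic study system with known ground truth
bench <- make_calibration_fixture(seed = 42)
occ <- bench$occ$habitat_specialist_3
occ
#> <occurrence_set> habitat_specialist_3: 600 records (292 kept)

eoo <- build_eoo(occ, bench$template, method = "plugin", p = 0.99, seed = 42)
eoo
#> <eoo_map> habitat_specialist_3 (plugin, p=0.99): 125019 km2, 1 component(s)

truth <- true_hdr(bench$ranges$habitat_specialist_3, 0.99)
round(truth$area_km2)
#> [1] 91810

ext <- template_extent(bench$template)
vm <- vmeasure(to_presence_absence(eoo, ext, source = "eoo"),
               to_presence_absence(truth$polygons, ext,
                                   species = eoo$species, source = "truth"))
sprintf("v=%.3f (h=%.3f, c=%.3f)", vm$v, vm$homogeneity, vm$completeness)
#> [1] "v=0.696 (h=0.770, c=0.635)"
```

Reading the numbers: of 600 biased draws, 292 survive thinning; the 99%
plug-in region is a single 125,019 km² polygon containing the generating
mixture's 91,810 km² analytic 99% HDR (kernel estimates are wider than the
truth by construction — the kernel adds its own spread). The V-measure of
0.70 against the true range sits in the "strong spatial agreement" part of
its 0–1 scale.

The calibration sweep reproduces the over-smoothing direction that
motivates the defaults — the reference bandwidth always yields the larger
region:

```r
calibrate_kde(bench$occ["habitat_specialist_3"], bench$template,
              grid_n = 384)$table
#>               species    method    p  area_km2 n_components n_used
#>  habitat_specialist_3    plugin 0.95  89191.95            1    292
#>  habitat_specialist_3    plugin 0.99 124999.42            1    292
#>  habitat_specialist_3 reference 0.95  92315.73            1    292
#>  habitat_specialist_3 reference 0.99 130332.89            1    292
```

## Command line

A thin front end over the same functions lives at `inst/cli/eoomap.R`
(subcommands `simulate`, `thin`, `eoo`, `calibrate`, `compare`,
`richness`; flat `key = value` config files, flags override, exit codes
0/1/2 for ok/computational failure/usage).

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","eoomap.R",package="eoomapr"))')" \
  thin --template template.geojson --occurrences occ.csv --out-dir out --seed 1
```

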