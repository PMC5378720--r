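# retmosaic

Spatial regularity and neurite morphometry of retinal cell mosaics.

`retmosaic` is an R package for analysing how labelled retinal cell
populations — melanopsin-expressing retinal ganglion cells (mRGCs) are the
motivating system — are organised across the retinal plane and how their
dendritic arbors are built, and for testing how both change across donor age
groups. It covers the full chain used in whole-mount aging studies of the
human retina:

* **Mosaic statistics** — per-cell nearest-neighbour distances (NND) and
  boundary-clipped Voronoi domain areas (VDA); regularity indices
  (NNRI/VDRI = mean/SD; ≈1.91 for a random pattern, higher for regular
  mosaics); the Clark–Evans dispersion index (DI = observed mean NND over
  the random-pattern expectation `1/(2√ρ)`; 1 for random); Gaussian
  histogram fits; and Monte-Carlo comparison against density-matched
  random-pattern nulls with 95% envelopes.
* **Morphometry** — soma equivalent diameter `2√(A/π)`, minimal-convex-polygon
  dendritic field area, branch-point and terminal-tip counts, and Sholl
  profiles (concentric-circle intersection counts) with their area under
  the curve.
* **Group analysis** — subtype composition percentages, half-open age bins
  (<30, 30–50, 50–70, >70 years), two-way ANOVA (subtype × age group) with
  Tukey HSD post hoc and compact letter displays, Grubbs outlier screening,
  and percent-decline summaries.
* **Synthetic data** — seeded generators for random (CSR) and soft
  exclusion-zone ("dmin") mosaics, stochastic dendritic trees with
  per-subtype presets at the published human mRGC scale, and full
  multi-donor aging datasets with stored ground truth, so the whole pipeline
  is testable without access to primary tissue.

File formats: cell/region tables as CSV (mm coordinates), tracings as
standard 7-column SWC (µm) with a CSV sidecar, plain-text provenance logs.

## Worked example

```r
library(retmosaic)

# a random mosaic of ~500 cells/mm^2 in a 1 mm^2 window
m <- generate_poisson_mosaic(mosaic_spec(unit_square_region(), 500, seed = 7))
mosaic_stats(m, border_buffer = TRUE)
#> mosaic_stats: n = 551
#>   NND  mean 0.02175  sd 0.01186  NNRI 1.834  DI 1.021
#>   VDA  mean 0.001815  sd 0.001031  VDRI 1.761
```

NNRI ≈ 1.91 and DI ≈ 1 are the random-pattern references, so this mosaic is
(correctly) indistinguishable from random. An exclusion-zone mosaic at the
same density is not:

```r
md <- generate_dmin_mosaic(mosaic_spec(unit_square_region(), 500, model = "dmin",
                                       dmin_mean = 0.02, dmin_sd = 0.003, seed = 7))
null_comparison(md, n_reps = 99, seed = 1, statistics = c("nnri", "di"))
#> null_comparison: 99 density-matched CSR replicates (n = 551)
#>   statistic observed null_mean null_sd null_lo95 null_hi95 percentile
#> 1      nnri    3.918     1.873 0.06183    1.7466     1.972        100
#> 2        di    1.337     1.016 0.02183    0.9732     1.059        100
```

The observed NNRI (3.92) sits far above the null envelope [1.75, 1.97]: a
regular mosaic. Composition arithmetic from mean subtype densities
(cells/mm²) reproduces the published shares:

```r
composition_percentages(c(M1 = 0.51, M1d = 2.05, M2 = 0.65, M3 = 0.97))$percent
#>  M1 M1d  M2  M3
#>  12  49  16  23
```

A preset dendritic tree at the displaced-M1 scale:

```r
tr <- generate_tree(sample_tree_spec("M1d", seed = 1), cell_id = "demo", subtype = "M1d")
count_branch_points(tr)   # 17
count_terminal_tips(tr)   # 20  (= branches + 3 primaries)
dendritic_field_area(tr)  # 0.564 mm^2
```

## Analysis workflow

The `analysis/` scripts run the simulated aging study end to end, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R     # 24-donor synthetic study + exports
Rscript analysis/02_mosaic_regularity.R  # CSR anchors + per-subtype null comparisons
Rscript analysis/03_morphometry.R        # 40 preset trees per subtype, metric means
Rscript analysis/04_aging_effects.R      # composition, ANOVA + Tukey letters, declines
```

Step 4 prints, for the default scenario (44% density drop from age 70,
dendritic decline from 50), the age-group letter displays — density:
`lt30=a 30to50=a 50to70=a gt70=b`; dendritic area:
`lt30=a 30to50=a 50to70=b gt70=c` — and the headline declines (≈41% density
drop >70 vs 30–50 under the default seed).

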