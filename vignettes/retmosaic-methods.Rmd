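---
title: "Mosaic regularity and neurite morphometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic regularity and neurite morphometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmosaic)
```

## The scientific problem

Melanopsin-expressing retinal ganglion cells (mRGCs) are the intrinsically
photosensitive ganglion-cell class that drives circadian photoentrainment and
the pupil light reflex. In flat-mounted human retinas they form planar
mosaics of four subtypes — M1 and M2 (somas in the ganglion cell layer,
dendrites in IPL strata S1 and S5 respectively), bistratified M3, and
displaced M1 (M1d, somas in the inner nuclear layer) — at densities of
roughly 0.5–2 cells/mm² in the superior-nasal retina. Two families of
questions are asked of such data:

1. **Spatial organisation.** Is a subtype's mosaic more regular than a random
   (complete spatial randomness, CSR) arrangement of the same density?
2. **Aging.** Do density, dendritic morphology and mosaic regularity change
   across donor age groups (<30, 30–50, 50–70, >70 years)?

`retmosaic` implements the full analysis chain for both, plus a synthetic
data generator that emulates the study design so every pipeline stage can be
validated against known ground truth — important because primary human
retinal material of this kind is not publicly deposited.

## Spatial statistics

For a mosaic of $n$ cells in a window $W$ of area $A$:

* **NND** — each cell's Euclidean distance to its closest neighbour.
* **Voronoi domain area (VDA)** — the area of the plane closer to the cell
  than to any other, clipped to $W$. Clipped areas partition $W$ exactly; we
  verify $\sum_i \mathrm{VDA}_i = A$ to $10^{-6}$ relative at every call.
* **Regularity index** — $\mathrm{RI} = \bar{x} / s$ with $s$ the sample SD
  ($n-1$ denominator, the convention of the mosaic-regularity literature).
  Applied to NNDs it is the NNRI, to Voronoi areas the VDRI. For CSR the
  asymptotic NNRI is $\sqrt{\pi/(4-\pi)} \approx 1.91$; real regular mosaics
  exceed it.
* **Dispersion index** — $\mathrm{DI} = \overline{\mathrm{NND}} \big/
  \frac{1}{2\sqrt{\rho}}$ with $\rho = n/A$; the denominator is the
  Clark–Evans CSR expectation, so DI is 1 for random patterns and larger for
  regular ones.
* **Gaussian histogram fits** — NND and VDA histograms (Freedman–Diaconis
  binning unless overridden) are fitted with
  $a\,e^{-(x-\mu)^2/2\sigma^2}$ by Levenberg–Marquardt least squares,
  initialised from the sample mean, SD and modal count; $R^2$ is computed on
  the binned counts. Non-convergence is flagged, never thrown.
* **Null comparison** — the reference "random pattern with the same density"
  is realised as an exact-$n$ uniform pattern in the same window (conditioning
  on $n$ makes the comparison sharper than a free Poisson count). The
  observed statistic is reported with the null mean, SD, central 95%
  envelope and its percentile. The phrase "same density *and SD*" that
  sometimes accompanies this null in the literature is redundant for a
  homogeneous random pattern — its NND SD is determined by density — so only
  the density-matched null is modelled.

### Edge handling

Two boundary conventions are exposed and off by default:

* `border_buffer` for NND summaries: cells nearer than a margin (one CSR mean
  spacing, $1/(2\sqrt{\rho})$, when `TRUE`) to the window outline are
  excluded from the summary. Uncorrected finite-window CSR NNRI is biased
  high at small $n$ (≈1.99 at $n \approx 200$); the buffer restores the
  analytic anchor, and the CSR validation suites therefore run with it on.
  Defaults stay off because the reference workflow (ImageJ-based) does not
  document an edge correction.
* `exclude_boundary_vda`: Voronoi domains touching the window outline are
  always *flagged*; by default they are kept in the VDRI (again the
  undocumented-default reading), with exclusion available.

### Numerical notes

* Voronoi geometry: Delaunay/Dirichlet tessellation on the bounding box
  (deldir) with each tile clipped to the window polygon (polyclip); areas are
  rescaled by the (≈$10^{-6}$ relative) tessellation slop so the partition
  identity holds exactly. $n = 2$ is handled by direct bisector clipping and
  $n = 1$ owns the whole window; collinear inputs raise a degenerate-geometry
  error.
* Duplicate coordinates are rejected at construction: digitised tracings can
  contain them, and they would produce zero NNDs and degenerate Voronoi
  cells.
* Coordinates are planar millimetres on the flattened whole mount; no
  spherical-eye correction is applied.

## Morphometry

Per traced cell (SWC input, planar camera-lucida convention — all metrics are
computed on the 2D projection; axon nodes are excluded from every dendritic
metric):

* **Soma equivalent diameter** $d = 2\sqrt{A_\text{soma}/\pi}$.
* **Dendritic field area** — convex hull of the dendritic nodes, µm² → mm².
* **Branch points** — dendritic nodes with ≥2 dendritic children. The soma
  never counts (primary-dendrite origins are not branch points) and a
  trifurcation counts once. This "node count" convention is exposed rather
  than hidden because tracing software differs on it.
* **Terminal tips** — dendritic leaf nodes. For strictly bifurcating trees,
  tips = branch points + primaries.
* **Sholl profile** — circles at radii $k\,\Delta r$ (default step
  $\Delta r = 10$ µm, configurable and logged) about the soma centroid, up to
  the first radius at or past the farthest dendritic node. A crossing is a
  *strict straddle*: an edge counts at radius $r$ iff its endpoint distances
  lie strictly on opposite sides of $r$; a tangent edge counts zero. This is
  reproducible and matches segment-intersection counting for edges with
  monotone soma distance.
* **Sholl area** — trapezoidal integral of the profile divided by a fixed
  10 µm reference step, i.e. "summed crossings at 10 µm spacing". Dividing
  by a *fixed* reference rather than the profile's own step is deliberate:
  it makes the value stable under step refinement (halving the step changes
  it by well under 5%) while reproducing the conventional magnitudes at the
  default step.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults mirror the motivating human study.

* **CSR mosaics** — uniform i.i.d. points, count Poisson($\rho A$) or pinned
  at `round(density × area)` (`exact_n`) for density-matched nulls.
* **Soft exclusion-zone ("dmin") mosaics** — the classic regular-mosaic
  simulation: cells are placed sequentially, each candidate drawing an
  exclusion radius Normal(`dmin_mean`, `dmin_sd`) truncated at 0 and being
  accepted only if farther than that radius from every accepted cell. A
  rejection budget of 1000·n candidates bounds runtime with a clear failure
  mode naming the achieved count; a loose disk-packing bound rejects clearly
  infeasible specs upfront. With `dmin_mean = 0` the model degenerates to
  CSR, and regularity grows monotonically with the exclusion radius, so the
  model spans the RI range (~1.2–2.1+) reported for real mosaics.
* **Dendritic trees** — topology first (a randomly chosen tip bifurcates
  until the branch-point target is met exactly, so tips = branches +
  primaries identically), geometry second (radial outward growth with
  angular jitter; every edge keeps a non-negative radial velocity so soma
  distance is monotone along edges — which is what makes strict-straddle
  crossing counts equal dense-sampling counts). Growth is biased toward
  recently extended tips and higher-order branches are shorter and more
  tangential, mimicking the few-long-branches/short-twigs architecture of
  real arbors. The arbor is finally rescaled so the dendritic hull area is
  exactly $\pi\,\texttt{field\_radius}^2$ — `field_radius` is the
  *equivalent radius* of the dendritic field, which pins the field-area
  metric to its target.
* **Subtype presets** (`sample_tree_spec`) — per-cell parameters are drawn
  around the published per-subtype means (soma diameter 19.9–20.8 µm,
  dendritic area 0.43–0.54 mm², branch points 14.6–21.6, tips 18.3–24.8);
  per-cell SDs are reconstructed from the published standard errors at the
  published sample sizes (SEM·√n, n = 400 for somas, ~42 for dendritic
  metrics). Primaries per cell are the subtype's mean tips-minus-branches
  gap (3 for M1/M1d, 4 for M2/M3).
* **Aging scenario** — 24 donors, six per age bin, ages 10–81, one ~1 cm²
  window each. Age effects are step declines (a degenerate piecewise-linear
  form chosen to match how the effects are reported — group-level drops with
  onset ages — without inventing a smooth functional form): density falls
  44% from age 70; dendritic metrics fall 25% from age 50 and 50% from 70
  (the study reports no morphometric percentages, so these are realistic
  choices consistent with its significance pattern). Donor-level biological
  variability is a mean-1 lognormal multiplier with CV 0.2, drawn
  *independently per donor × subtype*: a multiplier shared within a donor
  would correlate the four subtype observations and invalidate the
  fixed-effects ANOVA's independence assumption (pseudo-replication),
  inflating the age-factor type-I error that the validation suite checks.
* **Mosaic models per subtype** — M1d and M3 use the dmin model with
  exclusion radii of 0.27 and 0.22 CSR mean spacings (SD 15% of the mean),
  M1 and M2 are CSR. These fractions were calibrated once, by a
  20-replicate sweep at the study densities in a 1 cm² window, to land the
  finite-sample NNRI on the published per-type values (≈2.01 and ≈1.93);
  at ~100–200 cells the finite-sample NNRI runs above its asymptote, hence
  the small fractions.
* **Seeding** — one root seed; per-donor/per-subtype/per-cell streams are
  derived by counters (`substream_seed`), so adding a donor leaves all other
  donors' data bit-identical.

### What the generator does and does not emulate

It reproduces the study's *design* (sample sizes, densities, regularity
levels, morphometric scales, onset ages) with known ground truth. It does
not emulate: the fovea-centred density gradient across the whole retina
(windows are homogeneous), dendritic beads and their age-related loss,
within-cell stratification depth (S1/S5 are labels, not measured depths),
tortuous dendrite paths (edges are straight segments), or soma-size age
effects. Per-subtype *Sholl-area* separation is weaker in generated trees
than in the published data (generated means run ~240–260 for all subtypes
versus printed 147–211): Sholl area is an emergent property of the growth
geometry, which is shared across presets, while branch/tip counts and field
areas are pinned per subtype. Tests passing on synthetic data therefore
validate the computations and the inference chain, not any biological claim
about real retinas.

## Group analysis

* **Age bins** are half-open — [0,30), [30,50), [50,70), [70,∞) — because
  the reported ranges overlap at their boundaries; a boundary age goes to
  the older bin.
* **Two-way ANOVA** (`value ~ subtype * age_group`) uses Type II sums of
  squares by default (sensible for the mildly unbalanced tables real studies
  produce; Type I available, and the two coincide for balanced designs,
  which the test suite verifies). Empty design cells are an explicit error
  naming the cells. Significant factors (α = 0.05, configurable) get Tukey
  HSD post hoc tests and a compact letter display computed by the
  insert-and-absorb algorithm; the letters satisfy "two groups share a
  letter ⇔ adjusted p ≥ α" exactly, which the suite checks across random
  significance patterns.
* **Grubbs screening** is the two-sided single-outlier test with critical
  value $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$, $t = t_{1-\alpha/2n,\,n-2}$;
  it is applied once per invocation (iterated screening is a caller's
  explicit loop, to keep the multiple-testing behaviour visible).
* **Composition percentages** are shares of summed density, reported
  rounded half-up to integers with the unrounded values retained (they sum
  to exactly 100).

## Validation strategy and problem sizes

Every non-trivial computation is checked against an independent oracle:
NND against O(n²) brute force (exact), Voronoi areas against stratified
Monte-Carlo nearest-site integration with 10⁶ points (≤0.5% relative),
convex hulls against an O(n³) edge-test hull (exact), Sholl crossings
against dense arc sampling at 10⁴ points per edge (exact counts), ANOVA
sums of squares against a hand-computed balanced 2×2 table, and Grubbs
decisions against the published critical value at n = 10. CSR anchors use
100 replicates of n = 2000 (mean NNRI within ±0.03 of 1.91, mean DI within
±0.02 of 1); pipeline-level parameter recovery uses 20 replicate synthetic
studies per scenario (effect and null). These sizes give tight Monte-Carlo
error while keeping the full validation suite in the low minutes on one
core.

## Known limitations

* The NND/VDA Gaussian fit is descriptive (the true CSR NND law is Weibull,
  not Gaussian); $R^2$ quantifies histogram shape, as in the reference
  workflow, and should not be read as a model-selection statistic.
* The dispersion index uses the Clark–Evans expectation without the Donnelly
  edge correction; use the border buffer when comparing small windows to
  the analytic value.
* Mosaics are homogeneous within a window; density gradients across the
  retina are summarised per window, not modelled.
* The ANOVA treats per-donor means as independent observations
  (cross-sectional design); no mixed-effects or longitudinal structure is
  offered, and no multiple-testing correction is applied across metrics.
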