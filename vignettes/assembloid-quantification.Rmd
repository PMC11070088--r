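---
title: "Boundary-referenced quantification of tumor infiltration in assembloids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-referenced quantification of tumor infiltration in assembloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assembloidq)
```

## The measurement model

An assembloid fuses a GFP-labeled tumor spheroid with a neural organoid;
tumor cells then invade the organoid across the fusion interface. The
quantification starts from a multichannel confocal stack and a hand-drawn
closed polygon (the boundary ROI) separating the organoid interior from the
spheroid. The pipeline is:

1. **Maximum-intensity z-projection** per channel (`max_project()`). The
   analysis is two-dimensional from here on.
2. **Point-in-polygon**: every pixel center is classified interior/exterior
   with the even–odd (ray casting) rule (`point_in_polygon()`).
3. **Depth from boundary**: every interior pixel gets the exact minimum
   Euclidean distance to the polygon — the minimum over all boundary
   segments of the clamped point-to-segment distance — scaled by the pixel
   size into µm (`interior_distance_field()`).
4. **Concentric shells**: depths are binned into `n_shells` equal-width
   bands, in absolute µm or as a fraction of the image's maximum depth
   (`bin_shells()`). The shells are the escalating "levels" of infiltration
   toward the organoid center.
5. **Metrics**: per shell, `mean(eGFP)/mean(DAPI)` (`infiltration_metric()`);
   as a scalar, the same ratio over all pixels past a depth threshold
   (`total_infiltration()`). Marker expression (CC3, γH2AX, Ki67) is
   `sum(marker)/sum(DAPI)` over a region, normalized within each group to
   its untreated arm (`marker_ratio()`, `normalize_to_control()`). Per-cell
   infiltration distances for H3K27M-stained material come from Otsu
   thresholding, connected components, and intensity-weighted centroids
   (`h3k27m_distances()`).

Two further assay layers reuse the same machinery: the 2D migration score
(spread area at 24 h over spheroid area at 0 h, `migration_metric()`), and
the statistics used across such studies — relative viability, 4PL
dose–response with IC50, and one-/two-way ANOVA with Dunnett or Tukey
multiple-comparison families.

### Conventions that make pixel counts exact

* Coordinates are 0-based, x rightward, y downward, polygon vertices at
  pixel centers; a pixel is interior iff its center passes the test.
* Points exactly on an edge or vertex count as **interior with depth 0**.
  This keeps the interior/exterior partition exhaustive; the set has measure
  zero, so no shell mean can depend on it.
* Shell edges partition `[0, max depth]` (or `[0, 1]` in percent mode) into
  equal intervals, half-open on the right except the **last shell, which is
  closed**, so the deepest pixel is always assigned and the shells exactly
  partition the interior.
* Distances are computed exactly per segment rather than with a grid
  distance transform: no chamfer anisotropy, and the `O(pixels × vertices)`
  cost is immaterial at the field sizes involved (≤ a few hundred pixels
  square, ≤ ~100 vertices).
* The per-shell metric is a **ratio of means**, not a mean of per-pixel
  ratios: it is robust to single-pixel DAPI zeros and invariant to joint
  positive rescaling of both channels. Shells whose nuclear mean is zero are
  reported as missing, never 0 or ∞.

### Choices where the procedure was genuinely open

* **Shell count** defaults to 10 and is configurable; both absolute-µm and
  percent-depth modes are implemented, and every result carries its binning
  metadata, because neither the count nor the mode is canonical.
* Shell edges are per-image (`[0, max depth]`). A fixed-µm threshold mode
  (`total_infiltration(mode = "past_um")`) is provided for cross-image
  comparability.
* The **interface band** for marker ratios defaults to interior pixels
  within 200 µm of the boundary; the width is an explicit parameter.
* The manual "orthogonal line from the boundary to the cell" measurement is
  replaced by the nearest-boundary distance from the detected centroid; for
  a smooth boundary the orthogonal foot *is* the nearest point, so the two
  coincide up to polygonal discretization.
* The migration score includes the original spheroid body in the spread
  area, which is what makes the 0 h normalization exactly 1.
* ImageJ `.roi` (polygon type only, integer coordinates) and a JSON polygon
  dialect (full double precision) are both supported; other ROI types are
  rejected rather than coerced. Pixel size precedence is manifest override >
  file metadata > error — never a silent default on real data.
* TIFF stacks are written as 32-bit-float pages scaled per channel into
  `[0, 1]` (the portable float TIFF range), with shape, channel names, pixel
  size and scales in a JSON sidecar; round trips are exact to float32
  precision.

## The synthetic-scene generator

The generator (`generate_assembloid_scene()`) emulates the statistical
structure the analysis assumes, not the optics of a microscope:

* an organoid outline as a jittered ellipse (or any simple polygon);
* DAPI⁺ nuclei scattered uniformly in the interior at `nuclear_density`
  (default 0.004 nuclei/µm², ≈ one nucleus per 16 µm box);
* infiltrating GFP⁺ cells whose **depth inward from the boundary is
  exponential** with scale `decay_length_um` (default 50 µm), positioned
  uniformly along the boundary and stepped inward along the local normal;
* marker channels (CC3, γH2AX, Ki67, H3K27M, …) rendered at the tumor-cell
  positions with amplitude proportional to `marker_effect` — a treatment
  effect is a multiplicative change in marker level;
* cells and nuclei rendered as Gaussian blobs with `σ = radius/2`
  (differentiable intensity avoids aliasing artifacts in shell means);
* stacks with few z-planes of decreasing weight, since the analysis begins
  with a max projection — z adds only redundant signal plus noise;
* noise: per-pixel variance `poisson_scale · signal + gaussian_sd²` plus a
  constant background offset, clipped at zero. The signal-dependent term is
  added as a centered Poisson deviate so the rendered signal stays unbiased
  while the variance law holds (testable on flat patches).

Everything is deterministic given `seed`, and the ground truth (polygon,
cell positions with drawn and exact recomputed depths, effects, true areas,
true IC50) is returned alongside, so recovery tests have an oracle.

The exponential depth law was chosen because it gives the infiltration
profile a closed form: the cumulative tumor signal past threshold *t* is
`A·exp(−t/L) + β·N(t)`, an exponential cell term plus a diffuse background
proportional to the qualifying pixel count `N(t)`.
`estimate_decay_length()` recovers `L` from exactly this model. Two
numerical points matter:

* jointly profiling `L` and `β` is ill-conditioned — the exponential and
  area columns become nearly collinear at large `L` — so the default mode
  estimates the per-pixel background from exterior pixels more than 20 µm
  beyond the boundary and fits log-linear on the subtracted signal
  (`background = "profile"` keeps the joint fit for images without a clean
  exterior);
* the default threshold grid stops at 45% of the maximum depth: deeper in,
  the finite organoid truncates the exponential and the log-survival curve
  bends, which would bias the slope.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: no point-spread function or optical sectioning
(PSF convolution is deliberately out of scope), no 3D cell morphology, no
autofluorescence structure or illumination gradients, no brightfield phase
contrast (migration frames are intensity disks), and boundaries are exact
polygons rather than human-drawn outlines with their own variability. The
tests validate the estimators against the generative model they assume;
systematic deviations of real tissue from that model (e.g. non-exponential
invasion, spatially varying background) are not covered.

In the default scene the organoid radius (~100 µm) is only twice the decay
length, so the accepted cell-depth distribution is visibly truncated — as
in a real small organoid where tumor cells reach the center. Depth-law and
recovery validations therefore use large organoids (inradius ≈ 250–280 µm,
2 µm/px) where truncation is negligible.

## The statistical layer

* `one_way_anova()` computes the textbook between/within decomposition;
  zero within-variance with a real difference reports `F = Inf`, `p = 0`.
* `dunnett()` implements many-to-one comparisons from their distributional
  definition: pooled MSE, and familywise-adjusted two-sided p-values from
  the equicorrelated multivariate t distribution with correlations
  `√(λᵢλⱼ)`, `λᵢ = nᵢ/(nᵢ+n₀)`, evaluated with `mvtnorm::pmvt`
  (Genz–Bretz quadrature, absolute tolerance 1e-4, a fixed internal seed
  whose state is restored afterwards). `tukey_hsd()` and the two-way
  variant use the studentized-range distribution (`ptukey`), i.e.
  Tukey–Kramer for unequal sizes. Adjusted p-values are floored at the
  unadjusted ones, so `adjusted ≥ unadjusted` holds identically.
* `two_way_anova_tukey()` computes type II sums of squares from nested
  least-squares fits; on balanced designs (the typical case here) type I,
  II and III coincide and the table equals `aov`'s. Unbalanced input warns,
  naming the convention. Tukey comparisons run on the marginal means of the
  requested factor with the full model's residual error.
* `fit_4pl()` fits `r(d) = bottom + (top−bottom)/(1+(d/IC50)^hill)` by
  least squares on log10 dose with a 4PL-specific multi-start (five IC50
  starts at dose quantiles × two Hill starts); the best converged start by
  RSS wins. Degenerate inputs return diagnostics, not numbers:
  `flat_response`, `no_convergence`, `ic50_outside_dose_range`. The IC50
  standard error is delta-method from the log10-scale fit.
* `significance_tiers()` maps p-values to stars with strict inequalities
  (`p = 0.05` is "ns"), matching figure-legend conventions.

### Validation problem sizes

The test suite validates, among others: exact-distance agreement with a
hierarchically refined dense boundary-sampling oracle (30 polygons × 1,000
interior points, max |Δ| < 1e-9); even–odd vs winding-number classification
(50 polygons × 10,000 points, exact agreement away from edges); shell
partition conservation for 1–37 shells; decay-length recovery within 10%
(20 large-organoid scenes at a true 50 µm); detection of a 50% infiltration
knockdown with 5 images/arm in ≥90% of 100 simulated experiments with ≤10%
null rejections; Dunnett/Tukey familywise error within [0.03, 0.07] over
2,000 Gaussian-null replicates; migration ratio 4.0 ± 2% over 50 noisy
disk pairs; and sub-pixel RMSE for 50 per-cell marker distances. These
sizes were chosen to make Monte-Carlo standard errors small relative to the
tolerances while keeping the suite fast on a single CPU.

## Known limitations

* **IC50 sampling precision.** With eight doses spanning 0.1 nM–100 µM in
  triplicate and 5% multiplicative noise, the Cramér–Rao bound for
  sd(log₁₀ IC50) is ≈ 0.035, so even an efficient unbiased estimator lands
  within ±10% of truth only ~75–80% of the time; reliably tighter recovery
  requires more replication (≈12 at this noise) or lower noise. The
  unweighted least-squares fit is essentially unbiased (<1%) but inherits
  this sampling spread; its RSS-based standard errors report it honestly.
* The decay-length estimator assumes a spatially constant diffuse
  background; structured background (vignetting, autofluorescence bands)
  would bias it.
* `h3k27m_distances()` merges touching cells into one component; reliable
  per-cell distances need resolvable (non-clumped) marker-positive cells.
* Dunnett p-values carry the quadrature tolerance of `pmvt` (~1e-4);
  identical inputs reproduce identical values because the internal seed is
  fixed.
* No geodesic (in-tissue) distances: depth is straight-line Euclidean to
  the boundary, by construction of the measurement model.
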