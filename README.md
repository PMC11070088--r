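# assembloidq

Quantification of tumor-cell infiltration, 2D spheroid migration, and
therapy response in assembloid imaging assays.

## The problem

Fusing a tumor spheroid (e.g. GFP-labeled diffuse intrinsic pontine glioma,
DIPG) with a human neural organoid produces an *assembloid* in which tumor
cells invade brain-like tissue across a well-defined interface. Quantifying
that invasion from confocal stacks requires a boundary-referenced geometry:
a closed polygon drawn around the organoid separates "inside" from
"outside", and every interior pixel is scored by its minimum Euclidean
distance to that boundary. `assembloidq` implements this pipeline for
R users working with multichannel fluorescence stacks, plus the
migration-assay scoring and the statistical layer (dose–response fits and
multiple-comparison families) that such studies report.

A synthetic-scene generator with full ground truth (boundary polygon,
per-cell depths, marker effect sizes, true IC50s) is a first-class module,
so every quantitative claim of the pipeline is validated end to end against
known truth.

## The quantities it computes

For a maximum-intensity z-projection with channels eGFP (tumor) and DAPI
(nuclei), an interior pixel at position *p* has depth
*d(p) = min over boundary segments of ‖p − s‖* (µm). Depths partition the
interior into *K* equal-width concentric shells ("levels" of infiltration),
and:

- per-shell infiltration metric: `mean(eGFP) / mean(DAPI)` over the pixels
  of each shell (a ratio of means);
- total infiltration past a threshold *t*: the same ratio over all pixels
  with `d(p) ≥ t` (absolute µm) or `d(p)/max(d) ≥ t` (percent depth);
- marker ratios: `sum(CC3 or γH2AX or Ki67) / sum(DAPI)` over the whole
  image, the interior, or an interface band, normalized within each group to
  its untreated arm;
- per-cell infiltration distances: Otsu threshold → connected components →
  intensity-weighted centroids → distance to boundary (for H3K27M-stained
  sections);
- migration score: segmented spread area at 24 h / spheroid area at 0 h;
- dose–response: four-parameter logistic
  `r(d) = bottom + (top − bottom) / (1 + (d/IC50)^hill)` with multi-start
  least squares on log10 dose;
- group comparisons: one-/two-way ANOVA with Dunnett (many-to-one,
  multivariate-t adjusted) and Tukey (all-pairs, studentized-range adjusted)
  families, with figure-style significance stars.

## Worked example

```r
library(assembloidq)

# a synthetic assembloid scene with known ground truth
params <- scene_params(seed = 42L)
scene  <- generate_assembloid_scene(params)
scene$stack
#> <image_stack> 256 x 256 px, 3 z-plane(s), 2 channel(s) [DAPI, eGFP], 1 um/px

proj  <- max_project(scene$stack)
field <- interior_distance_field(scene$roi, dim(proj$data)[1:2],
                                 proj$pixel_size_um)
field
#> <distance_field> 256 x 256 px, 28510 interior px, max depth 88.74 um

shells  <- bin_shells(field, n_shells = 5)
infiltration_metric(shell_profile(proj, shells))
#> # A tibble: 5 x 7
#>   shell depth_min depth_max n_pixels tumor_mean nuclear_mean metric
#>   <int>     <dbl>     <dbl>    <int>      <dbl>        <dbl>  <dbl>
#> 1     1       0        17.7     9955       35.2         36.2  0.970
#> 2     2      17.7      35.5     7795       43.9         45.6  0.963
#> 3     3      35.5      53.2     5677       47.8         45.5  1.05
#> 4     4      53.2      71.0     3604       35.7         34.5  1.03
#> 5     5      71.0      88.7     1479       39.6         49.9  0.793

total_infiltration(proj, field, threshold = 25, mode = "past_um")
#> [1] 0.9870915
```

The shell table reads: ~10,000 interior pixels lie within 17.7 µm of the
boundary, and in that band the mean tumor signal is 0.97× the mean nuclear
signal; the scalar above is the same ratio over everything deeper than
25 µm. In this default scene the decay length (50 µm) is comparable to the
organoid radius, so cells reach the center and the profile is nearly flat —
large-organoid scenes show the exponential fall-off.

Dose–response and group comparison:

```r
tab <- generate_dose_response(true_ic50 = 3.1, hill = 1.1, top = 1,
                              bottom = 0.05, cv = 0.05, replicates = 3,
                              seed = 7L)
fit_4pl(tab)
#> <fit_4pl> IC50 = 2.779, hill = 0.955, top = 1.02, bottom = 0.0488 (RSS 0.01791)

ds <- generate_group_dataset(c(NT = 1, KD = 0.5), n_images = 5,
        base_params = scene_params(
          organoid_polygon = ellipse_recipe(128, 128, 100, 90, 64L, 0)),
        control = "NT", seed = 9L)
shared <- interior_distance_field(ellipse_polygon(128, 128, 100, 90, 64L, 0),
                                  c(256, 256), 1)
ds$metric <- vapply(ds$scene, function(s)
  total_infiltration(max_project(s$stack), shared), 0)
dunnett(ds, metric, group, control = "NT")
#> <comparison_family> one_way_dunnett, 1 comparison(s), residual df 8
#> # A tibble: 1 x 8
#>   comparison estimate std.error statistic    df  p.value adj.p.value stars
#>   <chr>         <dbl>     <dbl>     <dbl> <int>    <dbl>       <dbl> <chr>
#> 1 KD - NT      -0.237   0.00241     -98.2     8 1.29e-13    1.29e-13 ****
```

A knockdown arm generated with half the infiltrating cells loses about half
its total-infiltration metric, and five images per arm detect it decisively.

`tidy()` / `glance()` methods return tibbles for every fitted object, and
`autoplot()` / `plot_distance_field()` / `plot_infiltration_profile()` give
ggplot2 figures.

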