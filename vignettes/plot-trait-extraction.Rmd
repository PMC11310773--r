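---
title: "Extracting per-plot crop traits from orthomosaic and DSM rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting per-plot crop traits from orthomosaic and DSM rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plotpheno)
```

## The measurement problem

A phenotyping flight (or tractor run) over a breeding trial yields, after
SfM-MVS reconstruction, two co-registered GeoTIFF rasters per capture
date: an orthomosaic RGB image and a digital surface model (DSM) recording
the elevation of the visible surface — canopy where there is canopy, soil
where there is not. The trial is organised in microplots, small rectangles
each carrying one genotype. Three plot-level traits summarise growth:

* **crop height** — how far the canopy surface stands above the ground;
* **coverage** — what fraction of the plot's ground area the canopy
  projects onto;
* **volume index** — the average canopy height over the whole plot area,
  a height-times-cover proxy for canopy volume.

This vignette describes the models and estimators behind each, the
parameters that matter, and the choices made where more than one
reasonable definition exists.

## The base plane

Heights must be measured from the ground, but under a closed canopy the
ground is not observed. We assume the bare ground of a (small) trial field
is well approximated by a tilted plane

$$ z = a\,x + b\,y + c $$

in the projected (UTM-like) coordinate frame, estimated once from a
capture where enough bare ground is visible, and reused unchanged for all
dates — an absolute reference that makes heights comparable across the
season.

**Rectangle mode** (`base_plane_from_rectangles()`): the user designates
rectangles (any polygons are accepted) where bare soil is visible. All
valid DSM pixel centers inside them enter an ordinary least-squares plane
fit minimising vertical residuals. The fitted plane runs through the
*middle* of the soil surface; to make it a floor rather than a mean, it is
then shifted parallel downward to the deepest retained point
(`shift_to_base()`), after discarding the deepest 5% of points as local
anomalies — pits, shadows, reconstruction noise. Two details are fixed
here deliberately:

* the exclusion count is `floor(f * N)`, so that at most an `f`-share of
  the input points can end up strictly below the returned plane (with a
  ceiling count, a 30-point sample at f = 0.05 would drop 2 points —
  6.7%);
* the plane is never shifted *upward*: if every retained point sits on or
  above the fitted plane it is returned unchanged.

With Gaussian surface noise of standard deviation σ the shift settles
near the 95th percentile of the downward residuals, ≈ 1.64 σ below the
true ground; at the 5 mm noise typical of good reconstructions this is a
≈ 8 mm systematic that all height metrics inherit. It is the price of a
reference that bounds the soil surface from below.

**Line mode** (`base_plane_from_lines()`): crops like potato grow on
ridges, and the sensible reference there is the ridge *crest*, not the
furrow. Sampling a narrow strip gives very few stations across the strip,
so the cross-strip slope of an unconstrained fit is noise. The line mode
therefore regresses elevation on the along-line coordinate only and
constrains the slope normal to the line direction to be exactly zero.
Consequences worth knowing:

* the returned plane cannot represent a real cross-line slope; designate
  lines along the direction in which the field actually falls, or accept
  that the cross-component is flattened (this is the mode's contract, not
  a defect);
* several segments must be near-parallel (within 5°) — one plane cannot
  honour two normal directions. Segments share the fitted slope but keep
  per-segment intercepts, which are averaged after projection to a common
  origin, so crests at different field positions contribute grade but not
  offset noise;
* the sampling half-width defaults to one pixel, the narrowest band that
  still hits pixel centers.

Both modes end with the same downward shift, applied to the sampled
points.

## Height metrics

For every valid pixel in a plot, height is the vertical distance from the
base plane, `z − (a x + b y + c)`. Per plot, `Height100` is the maximum
and `HeightP` for P ∈ {95, 90, 80} is the maximum after discarding the
tallest `ceiling((1 − P/100) · N)` pixels — trimmed maxima. A single
spike (a bird, a matching artifact) moves `Height100` arbitrarily but not
`Height95`; conversely `Height80` tracks the bulk canopy and undershoots
the apex for sparse crops. Choices fixed here:

* the metrics use **all** valid plot pixels, not only vegetation-classified
  ones — the height distribution of the whole plot. A vegetation-masked
  variant exists (`heights_on_vegetation = TRUE`) but is off by default;
  for moderate cover the trimmed maxima land on canopy pixels anyway;
* negative heights (soil pits below the plane) stay in the distribution —
  maxima ignore them;
* exclusion counts use the ceiling, so a 10-pixel plot already excludes
  one pixel at P = 95 ({0, …, 0, 5} → Height95 = 0, which is the robust
  intent of the metric);
* nodata pixels never enter any denominator.

## Coverage

Coverage is estimated by classifying each pixel's color. Each pixel is
described by nine features — normalised R, G, B; H, S, V; and CIELAB L,
a\*, b\* (sRGB, D65 white point, hue 0 for achromatic pixels) — and a
multinomial logistic (maximum-entropy) model with 2–5 classes is fitted to
user-marked training pixels. The contract is the L2-penalised maximum
likelihood estimate on standardised features, a convex problem with a
unique optimum (the ridge penalty removes the softmax gauge freedom), so
the fit is deterministic and any convergent solver gives the same model;
the implementation uses BFGS with an analytic gradient. Defaults:
`l2_strength = 1e-4` on standardised features; intercepts unpenalised;
features standardised by training-set mean and standard deviation.

Per plot, class fractions are counts over classified pixels and coverage
is the summed fraction of the designated vegetation classes. Because the
model is purely chromatic, classes that are not separable by color are
out of reach by construction; per-date models are the recommended workflow
when illumination changes between captures.

## Volume index

$$ \mathrm{VI} = \frac{\sum_{\text{vegetation pixels}} \max(h_i, 0)}{N_{\text{plot pixels}}} $$

in meters (reported in cm ≡ cm³/cm²). Vegetation heights below the base
plane contribute zero, so soil pits can never subtract volume; the
denominator counts valid plot pixels (nodata excluded). VI is exactly
additive over disjoint partitions of a plot (pixel-count-weighted mean),
and bounded by coverage × Height100.

## Margins

Plot polygons often include compacted wheel tracks along the plot edge;
`trim_margin()` shrinks the rectangle concentrically before analysis. The
trim fraction is the **total** share removed from the dimension, split
equally between the two sides (0.2 on the width of a 9 × 1.2 m plot gives
9 × 0.96 m), and defaults to the width side, where machinery runs along
the plot's long axis.

## Geospatial conventions

Rasters are north-up with the world origin at the top-left corner; indices
are 0-based (row, col) with y decreasing as rows grow. Pixel footprints
are half-open ([left, right) × (bottom, top]), so a point on a shared edge
belongs to the pixel with the larger index; a 10⁻⁹-pixel nudge keeps this
rule stable under floating-point rounding. Plot membership is
center-in-polygon (boundary inclusive) — the usual zonal-statistics
default; the equivalence with a brute-force per-pixel test is asserted in
the test suite. A geographic (degree) CRS is a hard error everywhere:
plane equations and distances assume metric coordinates, and EPSG codes
4000–4999 are treated as geographic (a full CRS registry is out of
scope; UTM zones are the expected input). DSMs on a different grid than
the orthomosaic are resampled to it by nearest-neighbor — elevations are
looked up, never invented.

GeoTIFF I/O is implemented directly on the baseline TIFF format
(little-endian, uncompressed, strip-organised) plus the standard
georeferencing tags (pixel scale, tiepoint, GeoKey directory, GDAL-style
nodata), covering exactly the two layouts exchanged here: 8-bit RGB(A)
orthomosaics and 32-bit float single-band DSMs. Shapefile output writes
polygon records (type 5) with clockwise outer rings and a single integer
`plot_id` attribute; the DBF sidecar goes through `foreign`.

## The synthetic field generator

`field_spec()`/`make_field()` produce raster pairs whose ground truth is
known in closed form: a planar ground surface (optionally with
triangular-profile ridges whose crests run along the y axis, aligned with
pixel-center columns so crest pixels sit exactly at crest height), a
canopy block per plot raised by the canopy height above the local
reference level (crest level when ridged), per-pixel independent Gaussian
elevation noise, and crop/soil colors drawn from Gaussian distributions
separated by at least 6 standard deviations. Canopy regions are concentric
rectangles (or discs) whose area equals the requested cover fraction, so
the true cover is computable up to pixel quantisation.

The generator's defaults are the package's reference study conditions:
three 3 × 2.25 m plots at 5 cm ground sampling distance, ground slopes
(0.01, 0.02), 5 mm surface noise, a 0.5 m canopy covering 30% of each
plot, and 0.75 m ridge spacing with 0.3 m ridge height for the ridged
variant — sizes chosen so the full chain runs in seconds while leaving
thousands of pixels per plot. Base planes in the end-to-end scenarios are
estimated from a *bare-ground* capture of the same field (cover and
canopy zero, same seed), mirroring the recommended field workflow; the
ridged scenario slopes along the ridge direction only, because the
line-constrained plane flattens any cross-line slope by construction.

What the generator deliberately does **not** emulate: SfM reconstruction
artifacts (doming, melt at canopy edges, correlated noise), mixed border
pixels, shadows and illumination gradients, or within-plot height
variation. Passing the synthetic recovery tests therefore demonstrates
the correctness of the estimators under their stated model, not
field-level accuracy, which depends on reconstruction quality and
training-sample hygiene.

## Numerical choices and degenerate inputs

* Plane fits center coordinates before solving: UTM eastings/northings are
  ~10⁵–10⁷ m and would otherwise dominate the conditioning of the normal
  equations.
* Ties in all exclusion rules break deterministically (deeper/taller point
  first, then input order), making every estimator reproducible.
* Fewer than 3 points, collinear configurations, empty masks, zero-area
  polygons, missing CRS tags, geographic CRSs, disjoint raster extents and
  non-polygon shapefiles all raise named conditions
  (`plotpheno_<class>`), so batch runs can log and skip rather than die;
  a zero-area plot polygon warns and yields an empty mask.
* Batch CSV output prints heights in cm with 2 decimals and fractions
  with 4, through fixed `sprintf` formats — reruns are byte-identical.

## Known limitations

* One plane per project: terraced or strongly curved fields violate the
  planarity assumption; fit separate projects per terrace instead.
* The line mode's zero cross-slope is a modelling constraint, not an
  estimate.
* The classifier is chromatic only — no texture or spatial context.
* Shapefile support is deliberately minimal (single outer ring per plot,
  one integer attribute); multipart polygons or rich attribute tables are
  out of scope.
* EPSG codes are classified as projected/geographic by range, not by a
  registry; exotic projected codes in 4000–4999 would be wrongly
  rejected.
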