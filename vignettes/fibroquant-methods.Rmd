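---
title: "Methods: layer-resolved trichrome quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer-resolved trichrome quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

## The problem

Masson's trichrome stains collagen (connective tissue, methyl blue) and
cardiomyocyte cytoplasm (ponceau-fuchsin) in contrasting colours, while
adipocyte cytoplasm stays unstained. On a digitised transverse heart slice
this allows fibrosis and fatty replacement to be quantified simultaneously —
but doing so reproducibly requires (i) separating the two stains per pixel,
(ii) classifying tissue types, (iii) resolving the myocardial wall into
anatomically meaningful layers, (iv) placing section-level numbers onto a
standardized circular map of the slice, and (v) comparing conditions with
statistics that respect the repeated-measures structure (eight regions
measured within every heart). `fibroquant` implements all five stages plus a
synthetic phantom generator so that every stage is testable against known
ground truth without access to patient material.

## Stain separation

Brightfield absorbance is modelled with the Beer–Lambert relation. Each pixel's
optical density is

$$\mathrm{OD}_c = -\log_{10}\!\frac{\max(I_c, 1)}{I_{0,c}}, \qquad c \in \{R,G,B\},$$

where $I_0$ is the blank-glass intensity (default $(255,255,255)$; a
white-patch estimate from the 99th-percentile channel intensity is available
for slides with drifting white balance). Intensities of 0 are clamped to 1 so
the OD stays finite. Optical densities are additive across co-localised
stains, so $\mathrm{OD} = c_{\text{blue}} v_{\text{blue}} + c_{\text{red}}
v_{\text{red}}$ with unit stain vectors $v$; colour deconvolution inverts the
$3\times3$ stain matrix whose rows are the two stain vectors plus a residual
channel (their normalised cross product, oriented so its largest component is
positive). The default Masson vectors are the published Ruifrok-convention
pair used by the ImageJ colour-deconvolution plugin; both are configurable
because stain vectors are batch- and scanner-dependent.

Negative concentrations (possible under noise) are clipped at zero in the
blue/red maps; the signed residual channel and the clipped-pixel fraction are
kept as diagnostics. Because the phantom generator renders images through the
same forward model, the composition *synthesis → OD → deconvolution* is an
exact identity on the float path, which the tests exploit as an oracle; after
8-bit quantisation the recoverable accuracy for unit-range concentrations is
about 0.016 OD, and the tests assert 0.02.

Images are assumed to be at the stored working scale (the convention is 10% of
a 20× scan, roughly 5 µm/px); no pyramid logic is applied.

## Tissue classification

Each concentration map is classified by, in order: 2D median filter (disk,
radius 2 px), grayscale dilation (radius 1 px), thresholding, and binary
closing (radius 2 px). The default threshold is Otsu's method computed on the
nonzero map values inside the analysis ROI — deterministic and parameter-free
where a fixed value would be arbitrary; a fixed threshold remains available.

Adipose tissue needs its own detector because adipocytes are *unstained*: on
slides they appear as a "chain-link" of bright vacuoles bounded by thin
stained septa. The detector works on the Rec. 601 luminance:

1. median filter (radius 3 px), threshold at 220 intensity units to obtain
   the stained (dark) mask;
2. binary opening (radius 3 px) removes thin structures; the set difference
   *stained minus opened* isolates the thin septa. (The opposite operand
   order is selectable in the configuration, but since an opening is always a
   subset of its input, *opened minus stained* is empty by set inclusion —
   the implemented direction is the one that actually highlights the
   chain-link.)
3. vacuole interiors are recovered as the unstained holes fully enclosed by
   stained tissue, each hole required to have the area of a plausible single
   adipocyte (30–5000 px², i.e. roughly 12–160 µm diameter at 5 µm/px);
   the upper bound rejects enclosed lumens. This hole-based recovery is what
   makes the detector robust at cluster borders, where septa merge into the
   surrounding stained myocardium and a purely septum-driven fill would leak.
4. closing then opening (radius 3 px each) consolidate septa and vacuoles,
   enclosed interstitial gaps inside chain-link clusters are filled, and
   components smaller than one adipocyte are dropped.

Overlapping detections are resolved with the precedence *adipose >
connective > myocyte*: the adipocyte detector is the most specific, and
septal pixels are stained, so they legitimately trigger the stain
classifiers too. Pixels claimed by no detector become background. Area
percentages are computed per region with the tissue denominator by default
(connective + myocyte + adipose pixels), so the three classes sum to 100%;
this avoids dilution by lumen space between trabeculae. The ROI denominator
(all region pixels) is available as a configuration switch. A region with a
zero denominator reports missing values, never zeros.

None of the morphological radii or thresholds are canonical: they are the
package's defaults for ~5 µm/px imagery, exercised only through
tolerance-based tests, and all are exposed in the configuration.

## Myocardial layers and the equidistant midline

Each section's annotation provides closed-ring boundaries: the tissue outline
(outer ring and, for annular sections, a luminal inner ring), the epicardial
boundary, and the trabecular boundary. Layer masks follow by containment:
epicardium between outline and epicardial boundary, trabecular myocardium
inside the trabecular boundary, compact myocardium between the two. Supported
boundaries are closed rings; annotations drawn as open polylines would first
have to be closed against the outline, which this package does not do.

The compact layer is halved along the equidistant midline: with exact
Euclidean distance transforms $d_{\mathrm{epi}}$ and $d_{\mathrm{trab}}$ to
the two rasterised boundaries (8-connected Bresenham rasterisation, 0-based
pixel centres), outer compact is $\{d_{\mathrm{epi}} < d_{\mathrm{trab}}\}$,
inner compact is $\{d_{\mathrm{epi}} > d_{\mathrm{trab}}\}$, and exact ties go
to the inner half (configurable). The reported midline is the band
$|d_{\mathrm{epi}} - d_{\mathrm{trab}}| < 1$ px, the raster analogue of the
equidistance locus. A midline is feasible when both boundaries exist and the
minimum wall thickness $\min(d_{\mathrm{epi}} + d_{\mathrm{trab}})$ over
compact pixels is at least 4 px — below that the two halves are not
meaningfully distinct. For infeasible sections (thin wall, septal sections
without epicardium) the whole-myocardium area-weighted value (compact +
trabecular) is copied into both compact entries and flagged `"fallback"`.

The epicardium is partitioned and reported, but always flagged excluded from
analysis; it never reaches the schematic or the statistics.

## The standardized slice schematic

A slice layout file records each section's placement polygon on the drawn
slice map, its ventricle, and the centre of the ventricles. Every integer
degree (0–359, clockwise from the configurable anterior direction) is
assigned to the section whose placement the ray from the centre enters first;
the nearest-wall rule resolves rays that cross both ventricular walls in
favour of the wall belonging to the ray's own sector. The schematic shows
three concentric rings (trabecular innermost, then inner and outer compact)
with a 0–100% colour scale; missing degrees render in grey.

Eight anatomical regions group the degrees: six equal LV sectors (anterior,
anterolateral, lateral, posterolateral, posterior, septal) over the LV span
and two RV sectors (posterior, anterior) over the remainder, with ids in the
conventional legend order (1 = LV posterolateral … 8 = RV anterior). The
degree boundaries are operator-defined anatomy, not derivable from pixels, so
the RV span anchor is a configuration value with a declared default
(240°–360°). Per-region values are surface-area-corrected means: each
(section, layer) pair contributes its value weighted by its analyzed area,
over the sections intersecting the region's degree span.

The schematic SVG is written by fixed-precision string assembly, so identical
inputs produce byte-identical files — the property the end-to-end determinism
test asserts. A `ggplot2::autoplot()` method provides the interactive view.

## Statistics

Percentages are right-skewed with variance growing in the mean, so responses
are transformed with $\ln(x + 0.5)$; the natural log is used, and the 0.5
percentage-point offset admits exact zeros (both configurable). The design is
a classical split-plot: condition (control / AC / DCM) between subjects,
region (1–8) within subjects. The condition effect is tested against the
subject-within-condition mean square; region and region×condition against
the subject×region error. Sphericity violations are compensated with the
Greenhouse–Geisser $\hat\varepsilon$ from the pooled within-condition
covariance of subject region-vectors (the standard trace formula on the
contrast-transformed covariance), multiplying the within-stratum degrees of
freedom; $\hat\varepsilon \in [1/(k-1), 1]$ and equals 1 exactly for two
within-levels.

The sums of squares are computed directly from the balanced-design means
algebra rather than through `stats::aov`: base `aov` provides no
Greenhouse–Geisser machinery, and the direct path is fast enough to run the
package's Monte-Carlo calibration (1000 null fits plus a power grid) in
seconds. The test suite cross-checks every statistic against `aov`'s strata
decomposition, against an independently coded textbook oracle, and (for
$\hat\varepsilon$) against `car::Anova`.

Post-hoc Tukey HSD contrasts between conditions are computed on subject means
(averaging over regions, which is exact in a balanced design) via
`stats::TukeyHSD`, and only when the region×condition interaction is *not*
significant at $\alpha = 0.05$: with an interaction present, condition main
effects are not interpretable, and the result object says so explicitly
rather than returning numbers. Subjects with missing regions are rejected,
never imputed — with a handful of hearts per condition, silent imputation
would be misleading.

## The phantom generator

The phantom emulates exactly the features the detectors rely on:

- **colour statistics**: connective tissue rendered at methyl-blue
  concentration 0.9 (a pale variant at 0.35 is used for the false-positive
  control), myocardium at ponceau-fuchsin 0.85, septa at 0.9, vacuole
  interiors near zero, all forwarded through the same stain matrix and
  Beer–Lambert model as the deconvolution, with additive Gaussian intensity
  noise (default SD 4 of 255) and 8-bit quantisation;
- **geometry**: adipocytes as jittered hexagonally packed vacuoles (radius
  5–12 px, i.e. 50–120 µm diameter at 5 µm/px) sharing 1.5 px septal rings —
  the chain-link; connective and myocyte areas as blob-shaped bands of a
  smooth Gaussian random field, assigned by exact pixel counts so the label
  image hits the target fractions; interstitial pixels inside an adipose zone
  are stained like myocardium;
- **slice geometry**: concentric annular sections with configurable
  trabecular depth and epicardial rim. Boundary jitter is applied with
  opposite signs to the two internal rings so the analytic midline radius is
  preserved and jittered fixtures remain checkable against
  $(r_{\mathrm{trab}} + r_{\mathrm{epi}})/2$;
- **statistics**: balanced log-scale repeated-measures data with additive
  condition/region/interaction effects, subject intercepts (SD 0.4) and
  residual noise (SD 0.3) — magnitudes typical of log-transformed tissue
  percentages.

Hexagonal packing (rather than random sequential placement, which saturates
near 55% coverage) is what makes 20% adipose tiles reachable with realistic
interstitial space; the placement zone is found by bisection on a smooth
field threshold, with all randomness pre-drawn so the search is
deterministic. The true fractions reported with every phantom are exact
recounts of the emitted label image, taken relative to tissue pixels to match
the quantifier's default denominator.

The phantom deliberately does **not** model scanner artifacts, stitching
seams, focus gradients, stain-batch variation across laboratories, nuclei,
or the irregular shapes of real dissected specimens. Passing the phantom
tests therefore demonstrates that the algorithms are correct implementations
of their definitions and accurate under controlled colour statistics — not
that the default thresholds transfer to any particular scanner or staining
protocol; the configuration file is the intended vehicle for that
calibration.

## Numerical choices and problem sizes

- All randomness flows through explicit integer seeds; identical seeds give
  bit-identical phantoms and byte-identical pipeline outputs. Output CSVs
  print doubles with six decimals; SVG coordinates with three.
- The test suite verifies fraction recovery on twenty 1024² phantoms at
  (40/40/20)% (mean absolute error below 3 percentage points asserted, the
  observed error is under 2), midline geometry on annuli of radii (50, 60),
  (100, 200) and (150, 170), type-I calibration with 1000 null simulations
  (asserting a rejection rate in [0.035, 0.065] at α = 0.05), and a power
  grid of 500 replicates at three effect sizes. These sizes keep the full
  suite to a few minutes while leaving Monte-Carlo noise well inside the
  asserted bands.
- Degrees exactly on a shared cut edge between two placements may resolve to
  either section (both are geometrically correct); the ray-edge test uses a
  10⁻⁹ tolerance on the segment parameter so no degree is lost between
  adjacent edges.
- `EBImage` supplies the median filter, morphology, connected components,
  hole filling and the exact Euclidean distance transform; `mgcv::in.out`
  rasterises polygons. The Otsu threshold is computed in-package because the
  histogram must be restricted to ROI pixels.

## Known limitations

- Boundaries must be closed rings; open polyline annotations are not
  supported.
- A single centre serves the whole slice; strongly asymmetric ventricles
  might be better served by per-ventricle centres.
- The angular region boundaries are declared configuration, not inferred
  anatomy.
- Stain vectors are fixed per run; automatic per-slide stain estimation
  (Macenko-style) is out of scope.
- The statistics module fits the univariate split-plot with GG correction
  only; likelihood-based mixed models and the Huynh–Feldt correction are
  intentionally not provided.
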