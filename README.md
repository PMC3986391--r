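# fibroquant

Layer-resolved digital quantification of cardiac fibrosis and adipose tissue
on Masson's trichrome stained transverse heart-slice images.

## What it does, and for whom

Pathologists and cardiovascular researchers grading myocardial fibrosis
usually do so semi-quantitatively, in a handful of categories, on small
biopsies. `fibroquant` instead quantifies, per pixel and per myocardial
layer, the percentage of connective tissue (fibrosis), cardiomyocytes and
adipose tissue across a whole transverse heart slice, and places the results
on a standardized circular schematic so that slices, hearts and conditions
(e.g. control vs. arrhythmogenic vs. dilated cardiomyopathy) can be compared
region by region. It is aimed at studies of fibrofatty myocardial
remodelling — cardiomyopathy cohorts, animal models, and histological
validation of imaging — and ships a synthetic phantom generator so the whole
pipeline is testable without patient material.

## The method

1. **Stain separation.** Brightfield RGB is converted to optical density,
   `OD_c = -log10(max(I_c,1)/I0_c)`, and deconvolved with an invertible 3×3
   stain matrix (methyl blue, ponceau-fuchsin, residual; default vectors are
   the published Ruifrok-convention Masson pair) into per-stain
   concentration maps.
2. **Tissue classification.** Each map goes through median filter →
   grayscale dilation → threshold (Otsu within the ROI by default) → binary
   closing. Adipocytes get a dedicated detector that isolates the
   "chain-link" of unstained vacuoles and thin stained septa via a dark
   threshold, an opening that removes bulk tissue, septa extraction by set
   difference, hole-based vacuole recovery with per-adipocyte area bounds,
   and closing/opening consolidation. Overlaps resolve as adipose >
   connective > myocyte.
3. **Layers.** Each section is partitioned into epicardium, compact and
   trabecular myocardium from closed-ring annotations; the compact layer is
   halved along the *equidistant midline* — the locus of pixels equally far
   (exact Euclidean distance transform) from the epicardial and trabecular
   boundaries. Thin walls and septal sections fall back to whole-myocardium
   values, flagged as such. The epicardium is always excluded from analysis.
4. **Slice schematic.** Per-degree ray casting from the ventricular centre
   assigns each of 360 degree bins to a section; values are displayed as
   concentric layer rings with a 0–100% colour scale and grouped into 8
   anatomical regions (6 LV + 2 RV) by area-weighted means.
5. **Statistics.** Region values are log-transformed (`ln(x + 0.5)`) and fit
   with a split-plot repeated-measures ANOVA (condition between subjects,
   region within) under Greenhouse–Geisser correction; Tukey HSD post-hoc
   contrasts run only in the absence of a significant region×condition
   interaction.

See `vignettes/fibroquant-methods.Rmd` for assumptions, parameter defaults
and limitations.

## Worked example

Generate a phantom tile with known composition, then analyse a synthetic
slice end to end:

```r
library(fibroquant)

ph <- generate_trichrome_phantom(phantom_spec(512, 512, seed = 1))
ph$true_fractions
#> # A tibble: 3 × 3
#>   class      pixels fraction
#>   <chr>       <int>    <dbl>
#> 1 connective 104858    0.401
#> 2 myocyte    104858    0.401
#> 3 adipose     51569    0.197
```

The tile targets 40/40/20% connective/myocyte/adipose; the reported
fractions are exact recounts of the emitted ground-truth label image (the
adipose deficit reflects packing constraints). Running the classification
pipeline on `ph$image` recovers these within ~2 percentage points.

```r
d <- generate_rm_dataset(rm_dataset_spec(seed = 2, condition_effects = c(0, 0.6, -0.2)))
fit <- rm_anova_gg(d)
fit
#> Split-plot repeated-measures ANOVA (3 conditions x 5 subjects x 8 regions)
#> Greenhouse-Geisser epsilon: 0.6769
#>                 term stratum df df_corrected   sumsq meansq statistic  p.value
#> 1          condition between  2        2.000 15.6033 7.8016    8.0811 0.005985
#> 2 subject(condition) between 12       12.000 11.5850 0.9654        NA       NA
#> 3             region  within  7        4.738  0.7541 0.1077    0.8180 0.536427
#> 4   region:condition  within 14        9.476  1.1648 0.0832    0.6318 0.772650
#> 5     subject:region  within 84       56.858 11.0619 0.1317        NA       NA
#> Interaction not significant at alpha = 0.05

tukey_hsd(d, fit)
#> Tukey HSD pairwise condition contrasts (subject means over regions):
#>      contrast  estimate conf.low conf.high adj.p.value
#> 1  AC-control  0.768641   0.1825    1.3548     0.01133
#> 2 DCM-control  0.007471  -0.5787    0.5936     0.99936
#> 3      DCM-AC -0.761170  -1.3473   -0.1750     0.01204
```

The dataset was simulated with a condition shift (AC raised by 0.6 log
units, DCM lowered by 0.2) and no interaction: the fit detects the condition
effect (p ≈ 0.006), the within-subject correlation structure deflates the
region degrees of freedom (ε̂ ≈ 0.68), the interaction gate stays open, and
Tukey HSD attributes the difference to the AC contrasts. With
`interaction_effects` set, the gate closes and the post-hoc is reported as
not performed.

A complete slice run (`fq_run_all`) takes a directory with section images,
`roi.json` and `layout.json`, and writes `fractions.csv`, per-degree and
per-region CSVs and the schematic SVGs, all embedding the configuration
hash; `fq_phantom_slice()` creates a ready-made synthetic input directory.
A thin command-line wrapper with subcommands `phantom`, `quantify`, `map`,
`stats` and `run-all` is installed at `inst/cli/fibroquant.R`.

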