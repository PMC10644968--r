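# ki67ng

Quantitative scoring of Ki-67 immunostaining patterns — the *nuclear
gradient* (NG) — in brightfield H-DAB histology images, with the cohort
statistics needed to relate those scores to patient outcome.

## The problem

The Ki-67 labelling index (percent of tumour nuclei staining positive) is
the standard proliferation readout in tumour pathology, but it discards
*where and how* Ki-67 sits inside each nucleus. The intranuclear staining
pattern tracks cell-cycle progression: scattered fine granules with
membrane positivity (NG1, G1-like), one or two dense perinucleolar nodes
(NG2, late G1/S), intense homogeneous nucleoplasmic fill (NG3/4, S/G2),
and peripheral rings or condensed chromosomal masses in mitotic figures
(M). `ki67ng` implements a semi-automated pipeline that classifies every
detected nucleus into these categories and aggregates DAB-positive pixel
counts per category ("NG in pixels") alongside the classical proliferation
index, for pathology image analysts working with tissue-microarray cores
or tumour tiles.

## The method

1. **Colour deconvolution.** An 8-bit RGB tile is transformed to optical
   density, `OD_c = -log10(I_c / 255)`, and unmixed per pixel into
   hematoxylin, DAB and residual concentrations by solving the 3×3 linear
   system given by the stain absorbance matrix (the standard published
   H-DAB vectors by default; Macenko-style extreme-angle estimation per
   tile optionally).
2. **Segmentation and QC.** Nuclei are segmented on the hematoxylin map
   (Gaussian smoothing, automatic global threshold with a configurable
   floor, hole filling, watershed on the distance transform, area gating
   5–400 µm²). Each nucleus is QC-flagged in fixed order:
   `EDGE → OVERLAP (solidity) → BLUR (variance of Laplacian) → WEAK (mean
   DAB OD) → OK`; cores with <10% tumour or excessive blur are invalid.
3. **NG classification.** Per nucleus, DAB-positive pixels (strict
   absorbance threshold θ, default 0.15 OD) are summarised into blob
   (granule/node) censuses, fill fraction, membrane-band positivity and a
   central-void score, then classified by an ordered rule list
   (weak → mitosis → NG3/4 → NG2 → NG1).
4. **Scoring.** 1000 positive nuclei are sampled (deterministic seed),
   DAB-positive pixels are totalled per class and aggregated
   nucleus → core → case; the proliferation index is the percent of
   countable nuclei that are Ki-67 positive.
5. **Statistics.** Spearman correlation with the conventional strength
   bands, two-way ANOVA (tumour type × NG class) with Bonferroni-adjusted
   pairwise tests, chi-squared/Fisher crosstabs, and univariate /
   multivariate Cox proportional-hazards models of progression-free
   disease.

A synthetic-data module generates H-DAB tiles with planted, pixel-exact
ground truth for every pattern, plus a Weibull proportional-hazards cohort
simulator, so every stage is testable against known truth.

## Worked example

Score a synthetic adenocarcinoma-like tile (1024 px at 0.25 µm/px, 160
nuclei, proliferation index calibrated to 4.31%):

```r
library(ki67ng)
gt  <- generate_tile(synth_preset("PAD", seed = 4))
res <- score_tile(gt$tile)

table(res$table$qc_flag)
#>   OK WEAK
#>    6  154

round(proliferation_index(res$table), 2)
#> [1] 3.75

ng_pixel_scores(res$table[res$table$qc_flag == "OK", ])$per_class
#>   ng_class count total_px mean_px
#> 1      NG1     2      291  145.50
#> 2      NG2     0        0    0.00
#> 3    NG3_4     4     4285 1071.25
#> 4  MITOSIS     0        0    0.00
```

All 160 planted nuclei are detected; the 154 Ki-67-negative ones are
flagged `WEAK` (countable negatives), the 6 positives are classified, and
the measured proliferation index (3.75%) sits within sampling error of the
planted 4.31% rate. The pixel mass concentrates in NG3/4, the expected
dominant class for an adenocarcinoma-like positive compartment.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/ki67ng.R synth --preset PAD --tiles 5 --seed 7 --out tiles/
Rscript inst/cli/ki67ng.R score --tiles tiles/ --pixel-size 0.25 --out nuclei.csv
Rscript inst/cli/ki67ng.R stats --nuclei nuclei.csv --clinical clinical.csv --out report/
```

## Documentation

The methods vignette (`vignettes/ki67-nuclear-gradient.Rmd`) describes the
model, every tunable parameter with units and defaults, what the synthetic
generator does and does not emulate, and known limitations.
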