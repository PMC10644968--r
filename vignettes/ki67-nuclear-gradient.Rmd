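---
title: "Scoring the Ki-67 nuclear gradient: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the Ki-67 nuclear gradient: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model each
stage implements, the parameters that matter and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
the numerical choices made where the method description left the design
open.

## 1. Physical model: stains mix linearly in absorbance

A brightfield pixel transmits intensity $I_c = I_0 \cdot 10^{-OD_c}$ per
channel $c \in \{R,G,B\}$ (Beer–Lambert). `rgb_to_od()` therefore computes
$OD_c = -\log_{10}(\max(I_c, 1)/255)$; the clamp at intensity 1 keeps
saturated pixels finite (OD $\approx 2.41$) rather than infinite. In OD
space the signal is modelled as a non-negative mixture of stain absorbance
unit vectors,

$$\mathbf{od} = c_H \mathbf{v}_H + c_D \mathbf{v}_D + c_R \mathbf{v}_R,$$

so `deconvolve()` is one 3×3 linear solve per pixel, with negative
concentrations clipped *after* solving — the unclipped solution
reconstructs the OD exactly, which is what the round-trip tests check.
The default $\mathbf{v}_H, \mathbf{v}_D$ are the standard published H-DAB
vectors; `estimate_stain_vectors()` optionally re-estimates them per tile
by extreme-angle selection in the dominant OD plane (the two stains are
the angular extremes of the stained-pixel cloud), assigning hematoxylin to
the vector with the larger red-OD share (blue dyes absorb red). Any
degenerate estimate falls back to the defaults with
`provenance = "default"`, never an error: a scoring run should not die on
one pale core.

Assumptions worth stating: isotropic pixels, a single global white point
(255), no chromatic aberration, and stains that actually are H-DAB —
the residual channel absorbs the rest.

## 2. Segmentation and the threshold choice

Nuclei are segmented on the hematoxylin concentration map: Gaussian
smoothing (`seg$sigma_um`, default 0.4 µm — about half a chromatin
texture scale, enough to suppress sensor noise without merging
neighbours), a global threshold, hole filling, watershed on the distance
transform (`seg$ws_tolerance`, 1.5 px merge tolerance — below the
half-width of the smallest admissible nucleus), and an area gate
(`seg$min_area_um2` 5, `seg$max_area_um2` 400 µm², bracketing observed
nuclear areas in the calibration cohorts by a wide margin).

The threshold is Otsu's split of the region-of-interest histogram,
**iterated to the midpoint of the two class means** (Ridler–Calvard) and
floored at `seg$min_thr` (0.15 OD). The iteration matters: with a
dominant faint-stroma class, plain Otsu settles well above the half-height
edge of the nucleus profile and systematically undersizes masks — on
calibration tiles with planted mean area 24.4 µm² plain Otsu recovered
18.5 µm², while the class-mean midpoint recovers 24.7 µm². The floor
protects nearly-empty tiles where any global threshold is meaningless.

## 3. Quality control

Flags are assigned in a fixed order, first failure wins, so results are
independent of processing order:

| flag | criterion | default | units |
|------|-----------|---------|-------|
| `EDGE` | mask touches the tile border | — | — |
| `OVERLAP` | solidity < `qc$min_solidity` | 0.85 | — |
| `BLUR` | variance of Laplacian < `qc$min_focus` | 0.005 | intensity² |
| `WEAK` | mean DAB OD in mask < `qc$weak_od` | 0.10 | OD |
| `OK` | otherwise | | |

Solidity uses a Pick-style pixel count of the convex hull (shoelace area
+ perimeter/2 + 1), which is exact enough at nuclear scales and avoids
rasterising hulls. The focus threshold 0.005 was calibrated once as the
logarithmic midpoint between crisp synthetic nuclei (0.06–0.2) and
σ = 4 px blurred ones (≈ 4×10⁻⁴); the original protocol never quantified
"blurred", so this is a package default, not a claim about the study.
Core-level validity requires tumour fraction ≥ 0.10 — the boundary is
inclusive because the exclusion rule is phrased as "less than 10%" — and
a blurred-nucleus fraction ≤ `qc$max_blur_fraction` (0.5) as an artifact
proxy.

**The proliferation-index denominator.** A weakly/un-stained nucleus is
flagged `WEAK`, which excludes it from NG *sampling* but must not exclude
it from the PI denominator: PI is the percent of *countable tumour
nuclei* that are positive, so the denominator is every nucleus whose flag
is `OK` or `WEAK` (morphologically countable) and the numerator the
`OK` non-`NEGATIVE` ones. Any other reading forces PI toward 100% as soon
as negatives are flagged weak.

## 4. NG features and the classification rule list

All scale parameters are µm-denominated and converted by the mandatory
`pixel_size` calibration (default 0.25 µm/px, typical of ×40 scans; the
source protocol never stated its scan resolution, so calibration is a
required user input).

DAB-positive pixels (strictly above `stains$theta`, default 0.15 OD — the
strictness fixes bit-exact counts; the original threshold value was never
published, so θ is a first-class config parameter, global by default with
per-core override) are grouped into connected blobs and sized by
equivalent diameter: blobs within `ng$granule_um` (0.3–1.2 µm) are
granules, within `ng$node_um` (1.5–4.0 µm) nodes. The membrane band is
the outer `ng$rim_um` (0.5 µm) of the mask; the central void compares
positivity in a central disc (40% of the equivalent radius) to the rim
band. Fill fraction is positive pixels over mask area.

Classification is an ordered decision list — specific patterns pre-empt
generic ones because mitotic rings and homogeneous fills also contain
granule-scale blobs:

1. mean DAB OD < 0.10 → `NEGATIVE` (G0);
2. empty centre + peripheral positivity (void ≥ 0.6 and rim ≥ 0.4), *or*
   condensed strongly-positive mass (fill ≥ 0.5 and area z-score ≤ −1)
   → `MITOSIS` (M);
3. fill ≥ 0.7 → `NG3_4` (S/G2);
4. 1–2 nodes → `NG2` (late G1/S);
5. ≥ 3 granules or rim ≥ 0.3 → `NG1` (G1);
6. otherwise `NG1`, flagged as a default assignment.

NG3 and NG4 are deliberately one merged class: the source categorisation
defines "NG pattern 3 (NG3/NG4)" jointly and every downstream table uses
the merged class; the separate display colours are cosmetic. "NG in
pixels" is interpreted as DAB-positive pixel counts within classified
nuclei; because it is not stated whether the published unit is a
per-nucleus mean, per-core total or per-case mean, `ng_pixel_scores()`
exports totals and means at every level of the nucleus → core → case
hierarchy (case = mean over valid cores). Sampling of the 1000 positive
nuclei is uniform without replacement under an explicit seed, across all
supplied tiles by default (the original protocol sampled per tumour
type); per-case sampling is a matter of filtering the table first.

## 5. The synthetic generator

`generate_tile()` paints nuclei in *concentration space* and renders
through the same Beer–Lambert model the analysis inverts. This is
deliberate: stain-model error is isolated to the estimation tests, so
classifier tests measure classification, not unmixing. The default
reference condition is a 1024 px tile at 0.25 µm/px with 420
non-overlapping elliptical nuclei (200 negative / 60 NG1 / 60 NG2 / 60
NG3/4 / 40 mitoses), lognormal areas (mean 30 µm², CV 0.25), faint
stromal counterstain (0.08 OD hematoxylin — real sections are never
glass-clean, and an unstained-tissue class is what makes a global
threshold meaningful), and Gaussian sensor noise (SD 2/255).

Patterns: NG1 plants 5–14 granules (0.9 µm, scaling with nuclear area);
NG2 one or two 2.5 µm nodes within the inner half-radius; NG3/4 a
homogeneous 0.75 OD fill over a 1.3× enlarged nucleus (anisokaryosis);
mitoses a near-continuous ring of overlapping 1.1 µm granules at 90% of
the ellipse radius (prometaphase-like; a chromosome-bar variant is behind
`mitosis_style = "bar"`). The positive classes therefore differ by
construction in at least one planted dimension, making end-to-end
recovery a fair test rather than a tautology; blur and noise knobs exist
to make it hard.

`synth_preset()` encodes the three calibration conditions: carcinoid-like
(mean area 24.38 µm², PI 0.40%, NG1-dominant positives),
adenocarcinoma-like (49.66 µm², 4.31%, NG3/4-dominant) and breast-ductal-
like (33.36 µm², 3.42%, mixed). The morphometry and PI values are
published cohort statistics used as generator calibration; the exact
positive-class mixture fractions are package presets — the source states
only which class predominates.

What the generator does **not** emulate: stromal and immune cells, real
chromatin texture, uneven illumination and scanner colour response,
cytoplasmic DAB carryover, folded or torn tissue, and touching-nucleus
clumps beyond the controlled overlap knob. Passing recovery tests on
synthetic tiles therefore demonstrates the pipeline's internal
consistency at realistic geometry and noise — not performance on clinical
material, which additionally needs the expert tumour-region override and
per-core threshold review the tool exposes.

The cohort simulator draws covariates from documented distributions and
event times from a Weibull proportional-hazards model
($H_0(t) = (t/60)^{1.2}$, months); censoring is uniform on $(0, \tau)$
with $\tau$ solved by root-finding so the expected censored fraction hits
the request.

## 6. Numerical conventions and degenerate inputs

- Coordinates: 0-based, x = column, y = row, pixel-centre origin; one
  convention for tables, polygons and ground truth.
- A pixel exactly at θ is negative; a correlation exactly on a band edge
  belongs to the lower band (0.30 → "very weak"; the printed bands are
  gapped, and intermediate values also fall to the lower band). Note the
  band table disagrees with the source's own prose, which calls
  ρ = 0.83–0.88 "very strong"; the printed table (0.71–0.90 = strong) is
  implemented.
- Ties in Cox partial likelihood: Efron (modern default; the source is
  silent).
- Fisher's exact p sums hypergeometric probabilities ≤ observed with the
  customary (1 + 10⁻⁷) relative slack.
- Constant vectors give `rho = NA` ("undefined"), zero countable nuclei
  give `PI = NA`, zero-event cohorts give "not estimable" report rows;
  none of these crash.
- Empty tiles segment to empty lists; infeasible packing in the generator
  is an error naming the density limit.

## 7. Problem sizes in the shipped tests

Unit tests run on 512 px tiles (~55 nuclei); the end-to-end recovery
check uses one 1024 px reference tile (420 nuclei), the mixture-ordering
check four tiles per preset, and the statistical calibration 100
replicates of n = 500 cohorts — sizes chosen so the full suite completes
in a couple of minutes while keeping every binomial/simulation tolerance
meaningful.

## 8. Known limitations

- The tumour/non-tumour gate is a cellularity heuristic (smoothed
  nucleus-density at 15% of its tile peak); the original step was
  expert-assisted, and the expert mask override is the supported path on
  real material.
- Granule/node censusing by connected components merges puncta closer
  than the resolution limit; heavily overlapping granules read as nodes.
- Solidity-based overlap detection cannot split overlaps that remain
  convex; those pass as single nuclei.
- Chromaticity-based single-stain fallback in vector estimation assumes
  the minority stain is absent, not merely faint.
- No pyramid/whole-slide I/O: tiles and pre-cut TMA cores only.
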