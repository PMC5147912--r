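---
title: "Quantifying nucleocytoplasmic translocation in high-content screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleocytoplasmic translocation in high-content screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hcsreloc)
```

## The assay and its readout

Reporter cell lines expressing a GFP fusion of a shuttling protein (a
FOXO transcription factor, or an NES-bearing export reporter) redistribute
the fluorescent signal between cytoplasm and nucleus when nuclear import or
export is perturbed. In a 96-well imaging screen, each well is photographed
in two channels: DAPI marks nuclei and drives segmentation; GFP carries the
biology. The per-cell readout is the **nucleocytoplasmic ratio**

$$\mathrm{N/C} = \frac{\overline{\mathrm{GFP}}_{\text{nucleus}}}{\overline{\mathrm{GFP}}_{\text{cytoplasmic ring}}},$$

a cell is called *translocated* when N/C strictly exceeds 1.8, and the
well-level statistic is the percentage of translocated cells. Compound
activity is expressed relative to plate controls — vehicle (DMSO) wells
define 0% and wells treated with 4 nM leptomycin B (LMB), a covalent CRM1
export inhibitor, define 100% — and a compound is a primary hit when its
activity strictly exceeds 60%. Plate quality is summarized by the Z′
factor, $Z' = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$.

This vignette explains how `hcsreloc` implements each stage, the
parameters that matter, and what the synthetic-data validation does and
does not establish.

## Segmentation model

Nuclei are segmented from the DAPI channel only. The literature on these
assays typically says no more than "local threshold", so the package uses
the simplest robust member of that family:

* foreground = pixel value > (mean over an odd `block_size` × `block_size`
  window) + `offset`. Default `block_size = 51` px comfortably exceeds a
  nucleus diameter at 10× magnification (~15–20 px here); `offset`
  defaults to 2% of the image dynamic range, which suppresses background
  ripple without eroding dim nuclei.
* The binary map is hole-filled, labeled with 8-connectivity, and
  components below `min_area` (40 px, debris), above `max_area` (1200 px,
  clumps), or touching the image border (their ring would be truncated)
  are removed. There is no watershed splitting of touching nuclei: the
  simulator places cells without contact, and in real data touching nuclei
  are mostly removed by the area cap.

The cytoplasm is never segmented directly. Because the cytoplasm of an
adherent cell surrounds its nucleus, a **circumferential ring** is used as
an unbiased cytoplasmic sample: the pixels whose exact Euclidean distance
$d$ to the nucleus pixel set satisfies `gap < d ≤ gap + width`
(defaults: gap 1 px, width 4 px — narrow enough to stay inside the cell
body for irregular cell shapes). Rings exclude every nucleus; a pixel in
reach of two rings goes to the nearer nucleus, with ties broken by
nearest nucleus centroid and then by lower label id, so the assignment is
deterministic and rings are pairwise disjoint. Distances are computed
with an exact Euclidean distance transform, not morphological dilation,
so the ring definition above holds pixel-for-pixel; the test suite checks
it against a brute-force pairwise-distance oracle on small images.

A per-nucleus count of boundary pixels ("nuclear vertices" — pixels with
at least one 8-neighbour outside the label) is carried through as a
nuclear-shrinkage proxy, since shrinkage accompanies apoptosis and flags
cytotoxic wells.

## Quantification choices

* **Mean, not integrated, intensity** per compartment (configurable).
  The compartments have very different areas and the ring has fixed
  width, so per-pixel means are the area-fair reading of "nuclear over
  cytoplasmic fluorescence intensity"; an `integrated` switch exists for
  comparison.
* **No background subtraction by default.** The ratio of two means over
  nearby pixel sets is already robust to a flat background pedestal of a
  few hundred counts; subtraction is deliberately left out rather than
  silently applied.
* Cells whose ring mean is zero are excluded with a logged reason; wells
  with fewer than `min_cells` (default 50) cells are flagged `low_count`,
  and empty wells are flagged rather than given an undefined percentage.
* The 1.8 threshold and the 60% hit threshold are **strict**
  inequalities, and both live in the run configuration, not in code.

## Z′ factor

The package computes the standard form
$Z' = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$. A variant that divides
only the negative-control term by the mean separation — a bracketing that
occasionally appears in print — is available as
`zprime(..., variant = "as-printed")` for comparison, but the standard
form is the default and the recommended statistic.

## Dose–response model

Activity as a function of concentration is fit with the four-parameter
logistic on $\log_{10}$ concentration,

$$r(c) = \text{bottom} + \frac{\text{top} - \text{bottom}}{1 + (m/c)^{h}},$$

by Levenberg–Marquardt least squares with multi-start initialization
(midpoint starts at the 25th/50th/75th concentration quantiles; Hill
slope starts at 0.5/1/2). The Hill slope's sign is constrained by the
assay direction — positive for activation readouts (translocation),
negative for inhibition readouts (viability) — so `top` is always the
high-response asymptote and IC50 fitting shares the same code path.

The fitted midpoint $m$ is the **relative EC50** (the curve's midpoint).
Since "increases the response by 50%" can also be read as an absolute
crossing, the concentration where the fitted curve crosses a response of
50 is additionally reported (`absolute_midpoint`) whenever bottom and top
bracket 50. Uncertainty is residual-based: the reported `midpoint_se` is
the delta-method standard error from the fit's covariance.

**Honest non-convergence.** `converged = FALSE` (with `midpoint = NA`)
whenever (a) no start converges (`rss = Inf`), (b) the 4PL does not beat
a constant-mean fit in an F-test at α = 0.001 — the expected behaviour
for an inactive compound with a flat response — or (c) the midpoint runs
to the edge of the searched window (two decades beyond the tested
range). This prevents flat or degenerate data from ever yielding a
spurious potency.

**Viability normalization.** MTT absorbance at 570 nm is converted to
percent viability as
$100\,(A_{\text{treated}} - \bar A_{\text{blank}})/(\bar A_{\text{vehicle}} - \bar A_{\text{blank}})$;
vehicle wells average 100% by construction and replicates are averaged
with a standard deviation before fitting.

## The synthetic plate generator

The simulator is first-class, tested code: it is the ground-truth bed on
which every downstream stage is validated.

* **Geometry.** One field per well, 50–300 cells (configurable), each an
  elliptical nucleus (semi-axes drawn uniformly from 5–9 px, matching
  U2OS nuclei at 10× magnification) with a cytoplasmic annulus of
  thickness 6 px. Cells are placed by hard-core rejection sampling so
  footprints never overlap; an over-dense request fails with an explicit
  density error rather than degrading silently. Coordinates are 1-based
  (row, col) in pixel units, the R convention.
* **Intensity.** The DAPI channel renders each nucleus at ~3000 counts
  (log-normal cell-to-cell variation) over a 200-count background. In
  the GFP channel each cell's total signal (log-normal, median ≈ 3.2×10⁵
  counts) is split between nucleus and annulus so that the planted
  mean-intensity ratio equals the cell's true N/C ratio *exactly* before
  noise; cell pixels take their compartment value in place of the
  background so this identity is not perturbed by a pedestal.
* **States.** Each cell is translocated with the well's planted
  probability; its true N/C ratio is drawn log-normally with median 1.0
  (resting) or 3.0 (translocated), sdlog 0.2. These defaults straddle
  the 1.8 cutoff with realistic overlap (≈0.2% of resting and ≈0.5% of
  translocated cells fall on the wrong side). The true within-population
  ratio distributions of the biological assay are not published, so
  these are generator parameters, not biological claims — recovery tests
  validate the *pipeline*, not the biology.
* **Dose dependence.** A generative 4PL (`bottom` fraction at vehicle,
  `top` at saturation, midpoint, Hill slope) maps concentration to the
  planted translocated fraction; positive-control wells are simulated at
  `top`, negatives at `bottom`. Defaults bottom = 0.05, top = 0.90
  emulate the observed control separation of a healthy plate
  (Z′ ≈ 0.7–0.9 at 60–150 cells/well).
* **Noise.** Poisson shot noise on the expected intensity, additive
  Gaussian read noise (sd 30 counts), clipping at zero, quantization to
  16-bit — the standard CCD model. No optics are simulated: no PSF blur,
  vignetting, focus drift, debris, or touching/overlapping cells. Passing
  recovery tests therefore demonstrates correctness of the measurement
  chain under ideal optics, not robustness to every real-world artifact.
* **Determinism.** Every well's seed derives from the plate seed and the
  well id via a rolling hash; identical configuration and seed give
  bit-identical images, ground truth, and CSV artifacts.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(brute-force ring construction; an exhaustive two-stage grid search with
profiled linear parameters for the 4PL) and then exercises the pipeline
end-to-end at sizes chosen to keep the full suite fast while leaving the
statistics well-powered: unit tests use fields of 5–60 cells on 96–420 px
images; EC50 recovery runs a 12-point, 2-fold, triplicate dose plate
(the assay's stated replication) at 150 cells/well on 600×600 px fields,
at both micromolar and nanomolar planted potencies; IC50 recovery uses
20-point triplicate MTT tables with noise at 5% of the vehicle signal;
and the screen-scale test runs 544 compounds (7 plates, 60 cells/well,
5% planted actives) through hit calling, requiring ≥90% recall with all
plate Z′ > 0.5.

With triplicate 12-point designs and per-well binomial sampling noise at
these cell counts, the 4PL midpoint estimator is unbiased with a median
relative error of roughly 8–9%; single-well designs roughly double that,
which is why replicate wells are the default validation condition.

## Known limitations

* No watershed separation of touching nuclei; dense fields in real data
  will undercount cells and bias rings toward open space.
* The ring samples perinuclear cytoplasm; for cells whose GFP is
  concentrated at the membrane or in vesicles the ratio is not a pure
  compartment contrast.
* No spatial plate-effect correction (B-score/median polish) and no
  multiple-testing control: hit calling is a fixed activity threshold by
  design, as in the assay this package models.
* The simulator's noise model omits optics; see above for what recovery
  tests do and do not show.
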