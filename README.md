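# hcsreloc

Analysis of image-based nucleocytoplasmic translocation screens in R.

Many transcription factors — the FOXO tumour suppressors chief among them —
are regulated by shuttling between nucleus and cytoplasm, and compounds that
drive a GFP-tagged reporter into the nucleus can be found with two-channel
(DAPI + GFP) high-content imaging of 96-well plates. `hcsreloc` implements
the complete analysis for such screens, for assay scientists and image
analysts who need a transparent, scriptable alternative to instrument-vendor
software:

- **Nucleus segmentation** on the DAPI channel by local-mean thresholding,
  hole filling, 8-connected labeling, and area/border filtering.
- **Cytoplasmic ring masks**: for each nucleus the pixels with exact
  Euclidean distance `gap < d ≤ gap + width` to the nucleus, partitioned
  between neighbouring cells by nearest nucleus.
- **Per-cell quantification**: the nucleocytoplasmic ratio
  `N/C = mean(GFP_nucleus) / mean(GFP_ring)`; a cell is *translocated* when
  `N/C > 1.8` (strict). The count of nucleus boundary pixels ("nuclear
  vertices") is reported as an apoptosis/shrinkage proxy.
- **Screening statistics**: per-well percent translocated; activity
  normalized to plate controls,
  `activity = 100 (x − μ₋) / (μ₊ − μ₋)`, with the nuclear-export inhibitor
  leptomycin B (4 nM) as the 100% reference; hits called at activity > 60%;
  plate quality by the Z′ factor, `Z′ = 1 − 3(σ₊ + σ₋)/|μ₊ − μ₋|`.
- **Dose–response**: serial-dilution series and four-parameter logistic fits
  `r(c) = bottom + (top − bottom) / (1 + (EC₅₀/c)^h)` on log-concentration
  (Levenberg–Marquardt, multi-start, honest non-convergence for inactive
  compounds), used both for translocation EC50s and MTT-viability IC50s.
- **A synthetic plate simulator** that renders two-channel well images of
  elliptical nuclei with cytoplasmic annuli, partitions each cell's GFP
  between compartments at a known true N/C ratio, draws per-cell
  translocation states from a dose-dependent 4PL model, and applies a
  Poisson + Gaussian camera noise model — so every stage of the pipeline can
  be validated against planted ground truth.

## Worked example: EC50 from simulated plate images

Simulate a dose–response plate (12-point 2-fold series, triplicate wells,
60 cells per field) for a compound with true EC50 = 1.5 µM, then run the
full image → ratio → activity → 4PL pipeline:

```r
library(hcsreloc)

series <- dilution_series(50, 2, 12, "uM")
lay    <- layout_dose_plate("LOM612", series, replicates = 3)
lay    <- lay[lay$role != "empty", ]
model  <- dose_model(bottom = 0.05, top = 0.90, ec50_uM = 1.5, hill = 1)
spec   <- well_spec(n_cells = 60, image_shape = c(360, 360))
plate  <- render_plate(lay, model, spec, seed = 612)
images <- lapply(plate$wells, function(f) list(dapi = f$dapi, gfp = f$gfp))

res <- analyze_plate(images, lay, default_config(min_cells = 20))
res$zprime
#> [1] 0.7592048
head(res$wells[, c("well", "n_cells", "pct_translocated")], 3)
#>   well n_cells pct_translocated
#> 1  A01      60          5.00000
#> 2  A02      60         86.66667
#> 3  A03      60         88.33333
res$fits[["LOM612"]]
#> 4PL fit (increasing): midpoint 1.432 (se 0.13), hill 1.3, bottom 2.71, top 97.3, rss 936.8
```

The Z′ of 0.76 says the control separation is an excellent screening window;
well A01 is a vehicle control (5% of cells translocated), A02–A03 are the
top concentrations (≈87–88%); and the fitted midpoint of 1.43 µM recovers
the planted EC50 of 1.5 µM from images alone. `run_pipeline()` wraps the
same flow and writes per-cell/per-well CSVs, a hit list, a QC JSON and fit
JSON; `inst/cli/hcsreloc.R` exposes it as a small command-line tool.

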