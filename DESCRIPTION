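Package: hcsreloc
Title: High-Content Screening Analysis of Nucleocytoplasmic Translocation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based analysis of GFP reporter nucleocytoplasmic translocation
    screens. Segments nuclei from the DAPI channel by local thresholding, measures
    nuclear and cytoplasmic GFP in circumferential ring masks, computes per-cell
    nucleocytoplasmic ratios and per-well translocation percentages, normalizes
    activity to plate controls, calls hits, computes Z'-factor plate quality, and
    fits four-parameter logistic dose-response curves for EC50/IC50 estimation.
    Includes a synthetic two-channel plate simulator with known per-cell ground
    truth so the full pipeline can be validated without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
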