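Package: fishratio
Title: Automated HER2/CEP17 FISH Signal Quantification in Breast Cancer Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies HER2 gene amplification from dual-probe fluorescence
    in situ hybridization (FISH) images. Detects fluorescent spots in the
    Spectrum Orange (HER2) and Spectrum Green (CEP17) channels with
    area/distance/intensity gates, builds a DAPI counterstain mask, and
    estimates the HER2/CEP17 ratio by two sampling strategies: a
    tile-sampling classifier that places non-overlapping equal squares over
    nuclear material, and a nuclei-sampling classifier that segments
    individual nuclei and supports scripted human-correction edits (add,
    select, delete, split, merge) with automatic ratio updates. Includes
    homogeneously-staining-region (HSR) area-mode counting, ratio-based
    amplification calls (nonamplified / equivocal / amplified), concordance
    tables between methods, and a ground-truth synthetic field generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff,
    png
Config/testthat/edition: 3
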