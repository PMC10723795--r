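Package: nucleoscore
Title: Nucleolar Stress Quantification from High-Content Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies nucleolar stress in multichannel fluorescence images of
    cultured cells. Segments nuclei from a DNA counterstain and nucleoli from a
    fibrillar-center marker (e.g. UBF) with rolling-ball background subtraction,
    and computes the per-cell nucleolar normality score: the nucleolar over
    nucleoplasmic integrated-intensity ratio of a granular-component marker
    (e.g. nucleolin) divided by the same ratio for the fibrillar-center marker.
    Includes plate-level screen analysis (vehicle normalization, k-SD hit
    calling, hypergeometric target-class enrichment), two-component exponential
    FRAP recovery fitting with half-time extraction, phosphosite spectral-count
    filtering rules, and a ground-truthed synthetic generator for images,
    plates, and FRAP traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
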