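Package: punctaquant
Title: Quantification of Fluorescent Puncta and Condensate Accumulation in
    Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying the accumulation of
    biomolecular condensates (such as yeast P-bodies) in wide-field
    fluorescence micrographs: retrospective flat-field/dark-field shading
    correction estimated from the image stack itself, segmentation of
    puncta as the top-percentile intensity pixels, connected-component
    particle analysis yielding per-punctum maximal intensity and
    integrated density per cell, Relative Response Ratio (RRR)
    normalization against negative and positive control constructs, and
    replicate-aware Student's and nested t tests.  A synthetic micrograph
    generator with full ground truth (cells, puncta, shading, noise)
    makes every stage testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
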