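Package: probefish
Title: Design and Quantification Toolkit for Enzymatically Labeled smFISH
    Probe Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for producing and validating enzymatically 3'-end-labeled
    oligonucleotide probe sets for single-molecule RNA fluorescence in situ
    hybridization (smFISH) and RNA affinity capture. Covers antisense probe
    tiling design under GC-content, melting-temperature and spacing
    constraints; degree-of-labeling, concentration and recovery arithmetic
    from UV-Vis spectroscopy, gel densitometry and the HABA/avidin biotin
    assay; a hybridization yield planner; 3D spot detection in two-channel
    image stacks by per-slice local maxima and z-linking; Gaussian-mixture
    decomposition of spot intensities into mRNA copy-number classes; and
    two-channel codetection statistics including the false-positive
    detection rate. A synthetic-data generator with known ground truth
    supports end-to-end validation of the whole pipeline without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
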