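Package: osteolcn
Title: Segmentation and Connectomics of Osteocyte Lacunar-Canalicular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of 2D confocal-style images of the osteocyte
    lacunar-canalicular network (LCN). Provides thresholding segmentation
    pipelines (Otsu-core and Canny-core with shared pre- and post-processing),
    Dice and intersection-over-union evaluation, training machinery for
    pluggable per-pixel classifiers (masked DiceCE loss for partial labels,
    dendrite label dilation, a connected-component fragmentation penalty),
    conversion of three-class label masks into osteocyte graphs with network
    metrics (degree, dead ends, connection length and thickness, shortest
    paths), group comparison by Student's t-test, and a seeded synthetic
    scene generator with exact ground truth for validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tools,
    png,
    tiff,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    EBImage
Config/testthat/edition: 3
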