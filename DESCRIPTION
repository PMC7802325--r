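Package: neuromorph
Title: Multi-Scale Morphometry of Embryonic Brain Surfaces and Apical
    Cell Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-scale morphometric pipeline for embryonic mouse brain
    imaging studies. At the organ scale it measures volume, surface area,
    sphericity, mean cortical thickness and intraocular distance from
    closed triangulated iso-surfaces, including midline separation of the
    lateral ventricles by plane splitting. At the cell scale it quantifies
    apical epithelial packing: neighbour topology, Lewis' and
    Aboav-Weaire's laws, and ellipse-fit cell aspect ratios, from polygonal
    lattices or segmentation label images. A synthetic-data module
    generates ground-truth brain phantoms and (Lloyd-relaxed) Voronoi
    lattices organized as a two-genotype study, and a reporting module
    orchestrates the pipeline into tidy per-sample and per-group tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    tiff,
    png,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
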