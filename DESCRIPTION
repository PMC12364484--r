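Package: haquant
Title: Quantification of Hyaluronan Matrix Architecture in Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for hyaluronan-rich extracellular
    matrix in multichannel fluorescence micrographs of the ischemic glial scar
    and the subventricular zone. Segments the hyaluronan (HABP) signal with an
    automatic threshold, skeletonizes the matrix and measures per-cable
    longest-shortest-path lengths, estimates matrix interconnectivity by
    box-counting fractal dimension, partitions fields into intracellular,
    membrane-band (1 um) and extracellular compartments around segmented
    astrocytes to quantify hyaluronan area, intracellular puncta and CD44
    receptor internalization, computes radial core-to-penumbra intensity
    profiles of lesion markers, and compares cable-length distributions across
    conditions with the Kruskal-Wallis test. Includes a synthetic-micrograph
    generator with exact ground truth (fiber networks, analytic fractals, cell
    scenes, ring-shaped lesions) so every stage is testable without real data,
    plus 2^-ddCt semi-quantification for qPCR tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
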