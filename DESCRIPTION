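Package: phylopaint
Title: Automatic Styling and SVG Rendering of Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch customization of phylogenetic and taxonomic trees driven by
    tab-separated mapping files. Parses and writes Newick trees, computes
    rectangular, circular, and equal-wedge radial layouts, matches mapping-file
    rules to leaves by exact or substring matching, propagates styles from
    leaves to inner nodes so that uniformly styled clades are visually
    contiguous, and renders styled trees to standalone SVG with branch colors,
    leaf labels, leaf dots, bar series, arcs, and support decorations. A color
    gradient generator reduces count tables (classic-style OTU tables) to one
    color per observation via row means, Pielou evenness, or a one-dimensional
    principal-components projection, using cubehelix or color-stop gradients,
    and emits mapping files consumable by the tree styler. Includes seeded
    generators for random trees, count tables, and mapping files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    rlang,
    stats,
    tibble
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr,
    xml2
Config/testthat/edition: 3
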