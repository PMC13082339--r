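Package: phyllidsim
Title: Cell-Based Simulation and Quantification of Moss Phyllid Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional cell-based model of phyllid (moss leaf-like
    organ) morphogenesis in Physcomitrium patens. Cells are polygons refined
    into triangular membrane finite elements; specified anisotropic growth
    (Kpar/Kper along a polarity field derived from a distance field to the
    apical cell) enlarges element rest configurations, elastic equilibrium is
    solved, and residual stresses are released at every step. Positional
    information (cell-count distance from the organ base) controls zonation,
    cell division by a shortest-wall rule, apical-cell oblique divisions,
    midrib specification and differentiation. Includes scenario presets for
    wild-type upper phyllids, pin-mutant and auxin-treated variants and
    juvenile basal phyllids, a cellular quantification toolkit (lineage-based
    area expansion, division counts, principal directions of growth, binned
    basipetal profiles, merophyte contributions), synthetic template and
    lineage fixture generators, and plain-text serialization plus SVG
    rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
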