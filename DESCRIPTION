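Package: footquant
Title: Landmark-Based Foot Morphometry from 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("footquant", "developers", email = "footquant@example.org",
           role = c("aut", "cre"))
Description: Semi-automated anthropometric measurement of 3D foot scans.
    Reads triangle meshes (STL/PLY) and named anatomical landmark files,
    registers each scan into a canonical plantar-plane coordinate frame,
    and derives fifteen standard foot measurements (lengths, widths,
    girths, arch height and index, ankle angle). Companion tools cover
    the reliability analysis of such measurements (two-way ANOVA
    intraclass correlation with absolute agreement, confidence intervals,
    reliability classification, and ICC-based sample-size estimation),
    surface deviation mapping between design meshes with symmetric
    tolerance-band summaries, and a parametric synthetic foot generator
    with rater landmark-noise models so complete reliability studies can
    be simulated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
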