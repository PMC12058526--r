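Package: rotascape
Title: Relative-Orientation Conformational Landscapes from Paired Focused Refinements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformational heterogeneity of two-body
    macromolecules from single-particle cryo-EM metadata. Given two RELION
    STAR particle tables produced by independent focused refinements of two
    rigid bodies of the same particle stack, rotascape computes the
    per-particle relative orientation of one body in the frame of the other
    (z-y-x Euler angles alpha, beta, gamma), builds and interrogates the 3D
    particle-distribution landscape over those angles, detects hotspots,
    exports coordinate-selected particle subsets for external reconstruction,
    recombines C2 symmetry-expanded per-monomer class labels into dimeric
    substates, and evaluates carrier-protein tether-reach constraints on the
    swivel angle. A synthetic-scene generator produces paired refinement
    metadata with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
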