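Package: twistgate
Title: Twist-to-Open Gating Analysis for Hexameric CRAC-Type Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and characterising a putative open-state model
    of a hexameric ion channel (the Orai/CRAC family archetype) from its closed
    structure. Builds anisotropic elastic-network models on C-alpha
    coordinates, scores low-frequency normal modes against a set of gating
    constraints (rigid selectivity filter, released hydrophobic gate, coupled
    cytosolic helices, broken coiled-coil pairing, Cn symmetry), deforms the
    structure along selected modes into an open-state model, and quantifies
    the motion with pore-radius profiles, per-helix rotation angles,
    alternate-chain distances, salt-bridge and contact persistence,
    solvent-accessibility changes, and symmetry order parameters. A reduced
    one-dimensional Poisson-Nernst-Planck solver maps pore geometry and fixed
    charge to current-voltage curves, reversal potentials, and rectification
    indices. A synthetic-fixture generator provides parametric helix-bundle
    channels with known ground-truth gating transforms so the full pipeline is
    testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    RSpectra,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
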