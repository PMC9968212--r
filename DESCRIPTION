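Package: ttmd
Title: Thermal Titration Molecular Dynamics for Docking Pose Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-docking refinement of protein-ligand binding poses by
    thermal titration: a series of simulation windows at progressively
    increasing temperature is scored with a protein-ligand interaction
    fingerprint cosine-similarity function (IFP_CS), summarised by the MS
    coefficient (the slope joining the initial and final state of the
    titration), and used to rank candidate poses by persistence of their
    native binding mode. Includes geometric detection of eight interaction
    classes, a temperature-ramp protocol with early termination, replicate
    aggregation with trimmed means, RMSD and contact-frequency trajectory
    analyses, and a fully synthetic stochastic dynamics backend with known
    ground truth for validation without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
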