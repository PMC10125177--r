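Package: aushell
Title: Construction and Ligand-Shell Analysis of Thiolate-Protected Gold
    Nanocluster Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atomistic models of multifunctional thiolate-protected
    gold nanoclusters by ligand exchange on RS-Au-SR protective units, using
    nested rotational sampling around the S-C and S-Au bonds with a hard
    minimum-distance clash criterion. Provides PEG-thiol linker construction,
    amide conjugation of peptide and drug payloads, enumeration of
    peptide/drug formulation designs, and ligand-shell analysis estimators:
    mass- or unit-weighted radius of gyration, Shrake-Rupley solvent
    accessible surface area attributed per shell component, component-to-core
    distance time series, and radial distribution functions with
    minimum-image convention. Reads and writes XYZ, PDB, GRO and SDF
    structures and multi-model PDB / concatenated XYZ trajectories, and
    includes seeded synthetic fixtures (idealized reference cluster, toy
    staple clusters, toy trajectories with known ground truth).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
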