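# aushell

Atomistic model construction and ligand-shell analysis for multifunctional
thiolate-protected gold nanoclusters.

Ultrasmall Au144(p-MBA)60 clusters — a ~1.7 nm icosahedral gold core
protected by 30 RS-Au-SR "staple" units carrying 60
para-mercaptobenzoate thiolates — are a leading scaffold for targeted
nanodrug delivery. Functional versions are made by ligand exchange:
a targeting peptide or a drug is coupled to a PEG thiol linker by amide
chemistry, and the PEG conjugate replaces one original p-MBA per staple.
`aushell` is for computational chemists who need to *build* such models
reproducibly and *screen* formulation designs before committing to
molecular dynamics.

The package provides:

* **Structures** — XYZ / PDB / GRO / SDF I/O, covalent-radius bond and
  molecule detection, geometric RS-Au-SR staple detection, and a
  deterministic idealized Au144(p-MBA)60 reference-cluster generator
  (144 Au, 60 thiolates, 30 two-ligand protective units).
* **Ligands** — PEG thiol linkers HS–(CH2)n–(EG)m–OCH2–COOH with idealized
  all-anti geometry, EDC/NHS-style amide conjugation as a bond-topology
  operation (net loss of one water), and elongated conformer generation.
* **Builder** — the ligand-exchange placement algorithm: random exchange
  sites (one ligand per staple), nested rotational sampling (10° steps
  about the S–Au bond, 3.6° steps about the S–C bond, inner loop repeated
  per outer trial), acceptance of the first orientation in which every
  incoming-ligand atom clears **1.75 Å** from everything outside it, and
  full-restart semantics when a site exhausts its 3600-orientation grid.
  Plus enumeration of the peptide × drug × ratio design space
  (2 × 7 × 2 = 28 formulations at the study defaults).
* **Shell metrics** — radius of gyration (mass- or unit-weighted),
  per-component Shrake–Rupley SASA (0.14 nm probe, 960 points), ligand
  component–to–core center-of-mass distances, and radial distribution
  functions with minimum-image convention, over static models or
  multi-model PDB / concatenated XYZ trajectories.
* **Fixtures** — seeded toy clusters and toy trajectories with analytically
  known ground truth, so everything is testable offline.

## Worked example

```r
library(aushell)

ref <- generate_reference_cluster()   # idealized Au144(p-MBA)60
ref
#> cluster_model: 984 atoms, 61 molecules
#>   components: GOLD_CORE=144 OL=840
#>   protective units: 30
core_diameter(ref)
#> [1] 1.66            # nm, max Au-Au distance

peptide <- elongate_conformer(conjugate_payload(make_peg_linker(6, 11),
                                                synthetic_peptide_payload()))
drug    <- elongate_conformer(conjugate_payload(make_peg_linker(3, 11),
                                                synthetic_drug_payload()))

res <- build_functionalized_cluster(ref,
  formulation_spec("QS13", "TOR", c(2, 1), 15),   # 10 peptides + 5 drugs
  peptide, drug, builder_config(seed = 7))
res$model
#> cluster_model: 2339 atoms, 61 molecules
#>   components: DL=375 GOLD_CORE=144 OL=630 PL=1190
#>   protective units: 30

min_external_distance(res$model)      # clash criterion, post-hoc
#> [1] 1.754                            # Angstrom, >= 1.75 by construction

radius_of_gyration(ref, weights = "uniform")
#> [1] 1.152                            # nm
sasa_by_component(res$model)$components
#>    DL GOLD_CORE    OL    PL
#>  36.6       0.0  41.1 129.1           # nm^2
```

Reading the numbers: the build keeps all 144 gold atoms fixed, leaves
45 original p-MBA ligands (630 atoms) and installs 10 PEG-peptide plus
5 PEG-drug conjugates, every one at least 1.75 Å from everything around
it. The static reference model reproduces the expected composition and
size of the parent cluster; after functionalization the peptide layer
dominates the solvent-exposed surface, with the gold core fully buried.

The 28-formulation design space:

```r
length(enumerate_formulations())
#> [1] 28
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/aushell.R build --seed 7 --out model.pdb --trace trace.json
Rscript inst/cli/aushell.R enumerate --out specs.tsv
Rscript inst/cli/aushell.R analyze sasa --structure model.pdb --out sasa.tsv
```

See the methods vignette (`vignettes/nanocluster-shell-modelling.Rmd`) for
the model's assumptions, parameter choices and limitations.

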