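---
title: "Modelling multifunctional thiolate-protected gold nanoclusters"
author: "aushell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multifunctional thiolate-protected gold nanoclusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aushell)
```

## The modelling problem

Water-soluble gold nanoclusters of the Au144(p-MBA)60 type are attractive
drug-delivery scaffolds: a ~1.7 nm metal core protected by 30 RS-Au-SR
"staple" units, each carrying two para-mercaptobenzoate (p-MBA) thiolates.
Functional payloads — targeting peptides and small-molecule drugs — are
installed by thiolate-for-thiolate ligand exchange: a PEG thiol linker is
conjugated to the payload by amide coupling, and the PEG-payload conjugate
replaces one original p-MBA per staple.

`aushell` implements the model-construction side of this workflow as a
tested library plus CLI:

* an idealized reference cluster generator (144 Au, 60 p-MBA, 30 staples);
* PEG linker construction, amide conjugation, conformer elongation;
* the ligand-exchange placement algorithm (nested rotational sampling under
  a hard minimum-distance criterion, with full-restart semantics);
* enumeration of the peptide x drug x ratio formulation space
  (2 x 7 x 2 = 28 designs at the study's defaults);
* ligand-shell estimators: radius of gyration, per-component Shrake-Rupley
  SASA, component-to-core distances, and radial distribution functions.

Molecular dynamics itself is out of scope: the estimators consume static
models or externally produced trajectories (multi-model PDB, concatenated
XYZ).

## The placement algorithm

Exchange sites are chosen uniformly at random, at most one ligand per
staple. Each incoming conjugate is added in three phases:

1. its anchor sulfur is superposed on the original ligand's sulfur and its
   S-C axis aligned with the original bonding direction;
2. an outer loop rotates the conjugate about the S-Au bond (the axis through
   the staple's apex gold and the anchor sulfur) in 10 degree steps;
3. an inner loop, repeated for every outer trial, rotates about the S-C bond
   in 3.6 degree steps.

The first orientation in which **every** atom of the incoming ligand is at
least `d_min = 1.75` Angstrom from every atom outside it is accepted, and
sampling stops immediately — this biases accepted orientations toward the
natural (radial) bonding direction. If a site exhausts its
36 x 100 = 3600-orientation grid, the whole build restarts with freshly
drawn sites (the seed advances by one), up to `max_restarts` times. All
peptide conjugates are placed before all drug conjugates. Gold atoms are
never moved.

Two implementation notes:

* The inner loop is evaluated in closed form: each template atom moves on a
  circle about the S-C axis, so each (template atom, environment atom) pair
  forbids a single closed arc of inner angles, `d^2(a) = |v|^2 + r^2 -
  2(P cos a + Q sin a)`. The union of forbidden arcs yields the first open
  grid angle directly. The unit tests verify, against literal nested loops,
  that this returns bit-identical accepted orientations and trial counts.
* The 1.75 Angstrom criterion is applied between the incoming ligand's
  atoms (hydrogens included) and all atoms outside it; intra-ligand bonded
  distances are exempt, as is the anchor sulfur's own bond to the staple
  gold (2.33 Angstrom, which satisfies the criterion anyway).

Restart semantics follow the "run as many times as needed" reading: a
failed placement discards the whole build and redraws sites with the seed
advanced by one, rather than retrying the failed site in place. Which of a
staple's two ligands is replaced is drawn uniformly; nothing in the
procedure's description constrains that choice.

## The idealized reference cluster

No public coordinate set accompanies the study's reference structure, so
the generator constructs an idealized surrogate from literature-typical
Au144(SR)60 geometry: a three-shell icosahedral core (12 atoms at 2.80, 42
at 5.40, 60 at 6.90 Angstrom — vertices, vertices + edge midpoints, and a
face orbit) plus 30 staple gold adatoms at 8.30 Angstrom on the icosahedral
edge-midpoint axes, S-Au bonds of 2.33 Angstrom and near-linear staples
(S-Au-S = 165 degrees), with each sulfur additionally bridging toward one
distinct surface gold atom as in the real staple motif.

Packing 60 p-MBA thiolates clash-free on this surface is the delicate part.
The generator exploits icosahedral symmetry: one generating staple is made
C2-symmetric about its apex axis and replicated by the 60-element
icosahedral rotation group, so every ligand has a congruent environment and
the whole-shell clearance equals one ligand's clearance. The generating
orientation (staple tangent angle, ligand cone tilt and azimuth, ring spin)
is chosen by the same rule the placement algorithm uses: the smallest tilt
from the radial direction that admits a clash-free shell wins, and among
orientations at that tilt the most open packing is taken. For p-MBA this
resolves at a 10 degree cone tilt with 2.09 Angstrom shell clearance; the
scan is deterministic, and its precomputed result is verified (and, for
other ligands, re-run) at generation time.

Static metrics of the generated model: maximum Au-Au distance 1.66 nm,
radius of gyration 1.15 nm (unit weights, see below), total SASA about
60 nm^2. The published counterparts (1.7 nm; 1.17 +/- 0.002 nm;
56.85 +/- 0.73 nm^2) are 500 ns solvated-MD averages, so the static
idealized model is compared loosely (within 5-10%) wherever those values
appear in the tests.

### Which radius-of-gyration convention?

`radius_of_gyration()` defaults to mass weighting, the textbook estimator.
For this cluster, however, mass weighting is dominated by gold (76% of the
mass within 0.85 nm of the center) and yields ~0.8 nm — no physically
plausible Au144(p-MBA)60 geometry can reach 1.17 nm on that convention.
The published reference value is consistent only with unit weights, the
default of the visualization-toolkit scripting commonly used for such
analyses. Both conventions are exposed through the `weights` argument, and
comparisons against the published shell values use `weights = "uniform"`.

## Ligand construction choices

* PEG thiol linkers HS-(CH2)n-(O-CH2-CH2)m-O-CH2-COOH are built with
  idealized geometry (C-C 1.54, C-O 1.43, amide C-N 1.33 Angstrom;
  tetrahedral/trigonal angles), all-anti backbones, and every backbone bond
  registered as rotatable. The study's long (peptide) linker is m = 6, the
  short (drug) linker m = 3, both with n = 11.
* Amide coupling is modelled purely as a bond-topology operation: the
  carboxyl -OH and one amine hydrogen leave (net loss of one water), the
  payload is rigid-translated onto an ideal C-N bond. No charges, no force
  field, no pKa prediction.
* Payload structures are caller-supplied (SDF/PDB) with an explicit
  attach-atom index, since the reacting amine of a real drug is a chemical
  decision, not a geometric one. The bundled stand-ins — an aniline-like
  rigid ring "drug" and an extended oligoglycine "peptide" — are synthetic
  test vehicles, labelled as such, that exercise every code path without
  shipping real drug geometries.
* `elongate_conformer()` sets every rotatable dihedral anti (180 degrees),
  which maximizes outreach for chain-like templates; for branched templates
  where the anti conformer is not the farthest-reaching, the input is
  returned unchanged so outreach never decreases. Bond lengths and angles
  are untouched (verified to 1e-6 Angstrom in the tests).
* Unreacted p-MBA carboxyls are modelled deprotonated (carboxylates),
  matching the fully deprotonated shell assumed for the solution-phase
  system; incoming-ligand protonation follows the input file.

## Analysis estimators

* **SASA** is Shrake-Rupley with a 0.14 nm probe, 960 golden-spiral test
  points per atom and Bondi van der Waals radii (Au 0.166 nm) — the common
  MD-toolchain defaults. Atom areas are summed per component tag
  (GOLD_CORE / OL / PL / DL), so the total is exactly the sum of the
  component areas. Doubling the point count moves an isolated-sphere area
  by under 0.5%.
* **Component-core distance** is the per-frame distance between each ligand
  copy's center of mass and the gold core's center of mass, averaged over
  copies; the published text names the quantity without defining the
  estimator, and center-of-mass-to-center-of-mass is the natural reading.
* **RDF** histograms pair distances in 0.002 nm shells under the
  minimum-image convention and normalizes by shell volume and mean pair
  density, so an ideal gas gives g = 1. Both published group choices are
  supported (counterions vs staple sulfurs, the captioned pairing, and
  counterions vs the gold core); the caller passes the groups.
* Trajectory summaries discard frames before a 30 ns equilibration cutoff
  by default, the time after which the published shell observables level
  off; it is configurable, and the synthetic fixtures use a cutoff of 0.

All estimators are checked against closed forms (point mass, two-mass d/2,
isolated and two-sphere SASA), counting oracles, and O(N^2) reference
loops on small fixtures.

## What the synthetic fixtures do and do not show

The toy cluster (13-atom icosahedral core, k methylthiolate staples), the
rigid-translation trajectory (constant Rg), the ion-shell trajectory (RDF
peak at a constructed radius) and the ideal-gas trajectory (flat RDF) make
every estimator testable against known ground truth with no external data.
They emulate geometry and counting, not physics: passing these tests says
the estimators and the placement algorithm are implemented correctly, not
that the idealized static model reproduces solvated, thermally fluctuating
shell behavior. The published MD-scale observables (time series of the 28
systems, component-distance tables, counterion RDF peak positions) require
actual trajectories and are out of scope here.

## Problem sizes and determinism

All default computations run on a single CPU in seconds to a few minutes:
the reference cluster generates in well under a second from its verified
orientation, a 15-exchange build takes roughly 0.1-10 s depending on how
many restarts the seed incurs, and the full 20-seed build sweep used in the
tests runs in under two minutes. Every stochastic step (site selection,
fixture generation) flows through an explicit seed and restores the
caller's RNG state; identical inputs give byte-identical outputs.

## Known limitations

* The reference cluster is a geometric idealization, not a DFT-optimized
  structure; its static shell metrics stand in for trajectory averages only
  loosely.
* Conjugation translates the payload rigidly; a payload whose input
  conformation folds back over the linker can raise an intra-template clash
  error and should be elongated or re-posed first.
* The placement grid is rigid-body only (no per-site conformer relaxation),
  matching the procedure it implements.
* Periodic boundaries are honored in the analysis estimators only; building
  happens in vacuum.
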