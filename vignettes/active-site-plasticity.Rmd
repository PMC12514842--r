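---
title: "Measuring active-site geometry and plasticity in serine hydrolases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring active-site geometry and plasticity in serine hydrolases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitegeom)
```

## The measurement problem

Serine hydrolases cleave amide and ester bonds with a Ser–His–Asp catalytic
triad, helped by an *oxyanion hole*: backbone amide NH donors that stabilize
the negatively charged oxygen of the tetrahedral intermediate. In the
α/β-hydrolase fold the catalytic Ser sits on a sharp turn between a buried
β-strand of the central sheet and the helix that follows it, with the
His-loop and the oxyanion-loop nearby. Functional differences between
family members — a promiscuous detoxifier like acylpeptide hydrolase versus
a highly specific esterase — show up as *sub-Ångström* differences in how
these elements are arranged and how far they move when a ligand binds.
Measuring differences of 0.5 Å reliably requires strict conventions, which
this package encodes:

1. **A common frame.** Two structures are compared only after each chain of
   the mobile model is rigidly fitted (Kabsch, proper rotations only) onto
   its partner using the backbone N, Cα, C, O atoms of *core segments* —
   the central β-strands plus the post-Ser helix — chosen to exclude the
   mobile loops. Localized loop motions then become measurable
   displacements rather than artifacts of whole-domain motion.
2. **A fixed size statistic.** Active-site "spaciousness" is summarized by
   a triangle of three distances: `d1` = Cα(Ser)–Cα(His), `d2` = Cα(Ser)–
   donor heteroatom, `d3` = donor heteroatom–Cα(His), where the donor
   heteroatom is the backbone N of the *distal* oxyanion donor. Sites in
   which a tyrosine hydroxyl substitutes for the canonical loop (the DPP4
   arrangement) configure that sidechain oxygen instead.
3. **Declared machinery.** Which residues form the triad, which atoms
   donate to the oxyanion hole, and which segments count as loops or core
   are *declarative configuration* (JSON site definitions), never inferred
   from geometry at run time. Curated configs ship with the package.

## Conventions and tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| H-bond cutoff | 3.5 (inclusive) | Å | standard heavy-atom donor–acceptor criterion; no angle term because cryo-EM depositions carry no hydrogens |
| SASA probe radius | 1.4 | Å | water-sized probe, the field's convention |
| SASA sample points | 960 | – | sampling error ≈ area/√n ≈ 1% of an isolated sphere |
| vdW radii | C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 | Å | one pinned published set so outputs are comparable; overridable per element or atom name |
| Clustering cutoff | 1.0 | Å | the trajectory-analysis convention for GROMOS-style neighbor counting on main-chain + Cβ atoms |
| Display rounding | 0.1 | Å | matches the precision at which such shifts are reported; raw values are always retained in JSON output |

Other fixed policies: alternate locations resolve to the highest-occupancy
conformer (ties to the lexicographically smallest altloc ID); author residue
numbering is authoritative; hydrogens and waters are parsed but excluded
from all measurements; ligand (HETATM) atoms are excluded from clustering
selections but *included* as SASA occluders, since a bound ligand genuinely
buries the catalytic serine. Missing atoms are a hard error by default —
a measurement never silently skips atoms.

## Shift direction

"Toward" and "away" need a reference point. We use the centroid of the
configured ligand key atoms in the (core-fitted) holo structure; when no
ligand is configured, the holo catalytic Ser Oγ. An atom's shift is
"toward" when its holo position is closer to that point than its apo
position. Chain-averaged displacements are arithmetic means with sample SD;
single-chain structures report the bare value.

## Open design choices, and how they were resolved

* **Per-chain versus whole-oligomer fitting.** The comparison convention
  this package implements does not state whether a tetramer is fitted as
  one rigid body or monomer by monomer. We fit per chain and average,
  because shifts and triangles are reported per monomer with averages
  "where applicable"; per-chain fitting also makes the statistic robust to
  small inter-subunit rearrangements.
* **Mixture fitting procedure.** Reported SASA distributions come with
  fitted Gaussian "centers", without a stated fitting procedure. We fit a
  two-component normal mixture by EM with a *deterministic* median-split
  initialization, so the fitter needs no random seed and permuting the
  input cannot change the result. Convergence: log-likelihood improvement
  < 1e-8 or 500 iterations. A fit whose means differ by less than the
  larger σ is flagged near-degenerate.
* **Donor atom naming for DPP4.** The tyrosine donor is written "OG1" in
  some sources; Tyr has no OG1 in standard nomenclature, so the shipped
  config uses the hydroxyl oxygen "OH" and documents the discrepancy.
* **Core segment ranges.** The exact β-strand boundaries of the
  acylpeptide-hydrolase core are not published as residue ranges. The
  shipped configs carry curated estimates, loudly labelled as such in
  their provenance fields, and every range is overridable per run.

## Numerical design

* **Kabsch with reflection exclusion.** SVD of the 3×3 covariance with the
  sign of det(V Uᵀ) folded into the smallest singular direction; every
  returned rotation is checked to have determinant +1 within 1e-9. Inputs
  with fewer than 3 points or collinear configurations are rejected.
* **Deterministic SASA.** Sample points come from a golden-spiral lattice
  (no RNG). The lattice is oriented per atom by a local frame built from
  the atom's nearest *occluding* neighbors, with distances rounded before
  ordering so exact ties resolve identically before and after a rigid
  motion. Consequences, both tested: rigidly moving a model changes no
  area by more than 1e-9 (exact zero in practice), and deleting atoms
  beyond occlusion range changes nothing at all. Atoms with fewer than two
  non-collinear occluders fall back to a lab-frame completion; their area
  is either exact (isolated sphere) or axially near-symmetric, so the
  invariance there is only as good as the sampling. Neighbor search is a
  cutoff-filtered all-pairs list — contractually identical to a spatial
  grid, which would only matter at system sizes this package does not
  target.
* **GROMOS clustering ties.** The neighbor-richest frame seeds each
  cluster; ties break to the lowest frame index, which makes the partition
  deterministic and relabeling-consistent (tested against a brute-force
  oracle).

## What the synthetic fixtures do and do not establish

The package tests itself entirely on generated inputs:

* a **toy hydrolase** — a 14-residue chain on a gentle arc with labelled
  triad, two oxyanion donors, loop segments and core segments, replicated
  into a D2-symmetric tetramer. Bonded atoms sit 1.2–1.6 Å apart and
  non-bonded atoms (beyond 1–3 neighbors) at ≥ 2.0 Å, validated at
  generation time before noise is applied;
* **apo/holo pairs** with a planted whole-model rigid motion plus an exact
  per-atom loop displacement toward a planted ligand, so both the
  magnitude and the "toward" classification have ground truth;
* **sphere systems** with analytically known accessible areas;
* **ensembles** alternating between an open and a closed template
  (cluster ground truth) in which the catalytic-Ser SASA of every frame is
  *calibrated by root-finding* against a cage of occluding pseudo-atoms to
  hit a value drawn from a two-normal mixture — by default means 9.0 and
  29.5 Å² with σ 0.5 and 0.6 at equal weight, the compact/relaxed
  two-state picture reported for the wild-type enzyme, used here as
  generator truth. Calibration is accurate to the lattice quantization
  (~0.1 Å²).

Noise defaults follow the measurement setting being emulated: coordinate
noise of 0.1 Å in recovery tests mimics model-building uncertainty at
local resolutions of 2–3 Å; ensemble jitter of 0.02 Å keeps within-state
RMSD far below the 1 Å clustering cutoff, as in a well-equilibrated
trajectory dissected into monomers.

A green suite therefore establishes that the *measurement machinery* is
correct: superposition, triangle arithmetic, shift directions, SASA,
clustering and mixture recovery all agree with independent oracles
(closed forms, a quaternion solver, brute-force enumeration, a
cross-implementation SASA reference). It does **not** establish agreement
with any particular deposited structure: the toy fixtures share none of
the real enzyme's topology (7-bladed propeller, 732 residues), and
reproducing printed values for real accessions requires the deposited
coordinate files, which the offline test environment cannot fetch. The
`compare`/`panel` workflows and the curated configs exist for exactly that
use, with local files.

## Known limitations

* mmCIF support covers the `atom_site` category (coordinates and
  identifiers), not assemblies, symmetry operators or multi-datablock
  files; deposited coordinates are used as-is.
* SASA agreement with any specific external engine is bounded by radii-set
  and sampling choices; cross-implementation agreement was verified at the
  2% level, and exact numeric agreement with published per-trajectory SASA
  values is out of scope.
* The EM fitter is univariate and two-component by design; it refuses
  fewer than 50 observations and zero-variance input rather than
  returning a meaningless fit.
* Residue correspondence across different enzymes comes entirely from the
  site configs; no sequence or structure alignment is performed.
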