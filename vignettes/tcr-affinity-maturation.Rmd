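---
title: "Methods: interface analysis, mutation scanning and binding assays in tcrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface analysis, mutation scanning and binding assays in tcrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrm)
```

`tcrm` implements the computational arc of a structure-based TCR
affinity-maturation campaign: characterize the TCR–pMHC interface, scan
point mutations on a fixed backbone, rank them by a decomposable binding
score, and quantify the resulting affinities from SPR and ELISA data. This
vignette records the models, the parameters that matter, and the design
choices made where more than one defensible convention exists.

## Structure model and partitioning

Coordinates are held as a heavy-atom table (one row per atom) with author
residue numbering and insertion codes as the public convention; internal
indices are contiguous. Hydrogens are never modeled: crystal structures at
the 2–2.5 Å resolutions typical of TCR–pMHC work do not resolve them, so
every criterion in the package (SASA, contacts, energies) is heavy-atom
based. On reading, waters and (by default) non-peptide heteroatoms are
dropped, and alternate locations are resolved to the highest-occupancy
conformer (ties: first in file) to give a deterministic single-conformer
model for scoring.

A complex is partitioned into five roles — TCRα, TCRβ, MHC heavy chain,
β2-microglobulin, peptide. Automatic assignment uses robust topology cues
rather than chain letters (deposited chain identifiers vary): the peptide
is the chain of 8–11 residues, TCR chains carry an intrachain CYS–CYS
disulfide (SG–SG ≤ 2.5 Å), and of the remaining chains the longer is the
MHC heavy chain. When a TCR chain carries both variable- and
constant-domain disulfides, the one earliest in sequence (the variable
domain) anchors the geometry. Multiple copies in an asymmetric unit are
grouped by proximity to each peptide and labelled deterministically.

## Docking geometry

The TCR axis is the vector from the Vα disulfide SG midpoint to the Vβ
disulfide SG midpoint; the peptide axis runs from the N-terminal to the
C-terminal Cα. Crossing-angle conventions differ across the literature, so
the package fixes one and documents it: both axes are projected into the
MHC groove plane and the angle between the projections is reported in
[0, 180°), viewed along the peptide N→C direction. The groove plane is a
total-least-squares fit through the Cα atoms of the α1/α2 helix windows
(defaults: heavy-chain residues 50–85 and 138–175, configurable — the
windows are a convention, not a measurable). The incident angle is the
tilt of the TCR axis out of that plane, |90° − angle(axis, normal)|.
Disulfide anchor points default to SG midpoints, with Cα midpoints as an
option, since published angle values rarely state which was used; the two
differ by well under the ±3° convention spread observed between labs.

One geometric fact worth noting: the Cα atoms of an ideal α-helix lie on a
~2.3 Å cylinder, so the groove-plane fit residual is ~1.6 Å RMS even for
perfectly coplanar helix axes. The residual is reported for transparency
but is not a fit-quality defect; the fitted *normal* is what the angles
depend on, and it is recovered to well under 0.5° on constructed test
complexes.

## SASA and buried surface

Shrake–Rupley SASA uses a deterministic golden-spiral (Fibonacci) point
lattice — no random points — so outputs are bit-reproducible. Defaults:
probe 1.4 Å (water), 960 points/atom; doubling the lattice changes totals
by < 1%. Van der Waals radii come from a single bundled Chothia-style
table (C 1.87, carbonyl C 1.76, N 1.65, O 1.40, S 1.85 Å); absolute SASA
values depend on the radius set, which is why published buried-surface
figures carry a few percent of radius-set uncertainty. Buried surface area
follows the additive convention `SASA(TCR) + SASA(pMHC) − SASA(complex)`;
peptide burial compares the free peptide with the peptide in the MHC
groove (TCR absent). Translation leaves SASA exactly invariant (the
lattice rides on each atom); rotation re-clips a finite lattice, so
rotational invariance holds only to lattice resolution (~1% at 960
points) — the test suite checks both at their respective tolerances.

Contacts are heavy-atom criteria: van der Waals at ≤ 4.0 Å; hydrogen bonds
between donor- and acceptor-capable N/O/S atoms (per-residue capability
tables, no explicit hydrogens) at donor–acceptor ≤ 3.5 Å with an
antecedent–donor–acceptor angle ≥ 120°; salt bridges between Lys/Arg/His
basic nitrogens and Asp/Glu carboxylates (or a C-terminal carboxylate) at
≤ 4.0 Å. These cutoffs are conventional defaults and are configurable.

## The pose energy and binding score

The score is a transparent, strictly pairwise, physics-style function with
the familiar decomposition roles — attractive and repulsive van der Waals,
electrostatics, solvation, hydrogen bonds. It is designed for *ranking*
fixed-backbone point mutations, where relative changes dominate; it is not
a calibrated free-energy function, and no attempt is made to reproduce the
absolute energies of any published force field (the decomposition
*structure* is reproduced, not its numbers — those are specific to the
force field that produced them).

Per heavy-atom pair at distance r (excluding intra-residue pairs and
1-2/1-3 neighbors across the peptide bond):

- **Lennard-Jones**, pair parameters `Rmin = Rmin/2_i + Rmin/2_j`,
  `eps = sqrt(eps_i eps_j)`: for r ≥ Rmin the 12-6 well goes entirely to
  the attractive term; inside Rmin the attractive term is clamped at −eps
  and the remainder becomes repulsion, linearly extrapolated below
  0.6 Rmin so planted hard clashes score steeply but finitely.
- **Electrostatics**: `332.064 q_i q_j / (eps0 r^2)` — a
  distance-dependent dielectric `eps(r) = eps0 r` with eps0 = 10, the
  common choice for fixed-backbone repacking without explicit solvent.
  Charges are a bundled reduced set: formal charges on Asp/Glu/Lys/Arg
  side chains (His neutral), ±0.25 backbone amide dipole charges; with no
  hydrogens, full force-field charge sets are unwarranted.
- **Solvation**: Lazaridis–Karplus Gaussian exclusion with per-element
  ΔG_free, λ = 3.5 Å and atomic volumes; burying polar atoms costs energy,
  burying carbon gains slightly.
- **Hydrogen bonds**: a Gaussian well of depth 1 kcal/mol centred at
  2.9 Å (σ 0.3 Å) between donor/acceptor-capable pairs.

All terms switch smoothly to zero over 5.5–6.0 Å (CHARMM-style C1
switching); continuity across Rmin, the 0.6 Rmin knee and the switching
window is verified numerically in the tests. Term weights default to
`{lj_attr 1.0, lj_rep 0.55, coulomb 1.0, solvation 1.0, hbond 1.0}` — the
down-weighted repulsion follows standard repacking practice, since rigid
rotamers overestimate clashes. Parameter tables ship as versioned TSV
files under `inst/extdata/params/`.

The binding score is the literal subtraction protocol: score the complex,
then the TCR side and the pMHC side separately *on identical, unrelaxed
coordinates*, and subtract componentwise. Because the model is strictly
pairwise, the result equals the sum of cross-partner pair energies exactly
— the suite asserts this against an independent double-loop oracle at
1e-9, and the scanner exploits it for speed.

## Mutation scanning

Design positions are TCR residues with any heavy atom within 8 Å of the
peptide (minimum heavy-atom distance). Published protocols sometimes state
the reference set ambiguously — the peptide alone versus the peptide as
presented, including MHC; both readings are implemented
(`reference = "peptide"` or `"pmhc"`), peptide-alone being the default,
and neither is asserted to reproduce any particular published position
count. Each position is paired with the 20 standard amino acids minus
cysteine (to avoid unpaired cysteines near a disulfide-bonded domain),
*including* the wild-type identity — 19 per position, so 52 positions give
988 candidates; the self-substitution doubles as a built-in neutrality
control (|ΔB| ≈ 0).

Mutant side chains are rebuilt beyond Cβ from idealized internal
coordinates over a deterministic staggered rotamer grid (−60/60/180° per
sp³ χ; −90/0/90° terminal sp², ±90° aromatic ring χ2, two proline pucker
pairs; optional ±30° half-steps on χ1/χ2 mirror extra-rotamer flags).
A statistical rotamer library would be richer; the grid is self-contained,
deterministic, and adequate for ranking — and the library format allows
swapping one in. Only the mutant side chain is repacked and the wild-type
backbone is preserved throughout; a neighbor-shell repack option exists
but is off by default. The rotamer minimizing the interaction energy with
the rest of the structure wins (ties: lowest index). Candidates are ranked
ascending by ΔB = B(mutant) − B(wild type), ties broken lexicographically;
failed candidates are recorded with an error flag rather than dropped.
Scans are pure functions of their inputs — identical inputs and seed give
byte-identical results, fingerprinted in the output.

Double mutants are placed sequentially when the two sites are outside
interaction range (order provably cannot matter on a fixed backbone) and
by exhaustive joint rotamer-pair search when they interact. CDR loop
refinement proposes uniform φ/ψ perturbations (±10° default) on loop
residues, re-closes the chain break by CCD against the fixed C-terminal
anchor (closure RMSD < 0.1 Å over the anchor N/CA/C, otherwise the
proposal is rejected and counted), and accepts by Metropolis at kT = 1
over 100 cycles by default (schedule chosen for desk-scale runtime and
recorded in the output). Rigid ideal geometry gives CCD a limited
reachable set: short extended loops cannot absorb displacement along their
own near-collinear torsion axes, so closure tests use lateral openings on
loops of at least ~8 residues.

## Binding assays

SPR uses the closed-form 1:1 Langmuir model — association
`R(t) = (C ka Rmax / (C ka + kd))(1 − e^{−(C ka + kd)t})`, dissociation
`R(t) = R(t_a) e^{−kd (t − t_a)}` — verified in the tests against direct
ODE integration at 1e-6 RU. Fitting is global (shared ka, kd and, by
default, one Rmax) across the concentration series, in log-parameter space
with Levenberg–Marquardt from three starts spanning ±2 decades, which
removes local-minimum seed dependence in the noise-free case; per-curve
Rmax is a flag. No mass-transport or bulk-shift terms are included — the
underlying experiments were analyzed with a plain 1:1 model, and adding
transport parameters to data that do not constrain them only degrades
identifiability. Whether published affinity tables derive from kinetic or
equilibrium analysis is often unstated per entry, so both fit paths are
provided (`fit_1to1`, `fit_equilibrium`). KD = kd/ka holds exactly by
construction; fold change is KD_reference/KD_variant to 3 significant
figures.

ELISA percent-positive is exactly
`100 (OD_sample − OD_neg) / (OD_pos − OD_neg)` — affine-invariant, not
clamped, with mean ± SEM over replicates (n = 4 by default). Binder
categories (strong ≥ 40%, intermediate ≥ 10%) are configurable defaults
chosen so that verbal categories used for UV-exchange stability data
reproduce; they are not instrument constants.

## Synthetic data: what it does and does not emulate

The toy complex is a geometric idealization, not a homology model: two
ideal α-helices (φ/ψ −57/−47°) as the MHC platform, an extended 9-mer
(VVGAVGVGK) in the groove, a helical β2m stand-in, and two hairpin TCR
variable-domain stand-ins, each with a real CYS–CYS disulfide whose SG
midpoints realize the requested crossing/incident angles *exactly* by
construction (the generator verifies recovery to ±0.5°). Coordinates get
0.02 Å seeded jitter plus a random global rigid motion, so different seeds
share geometry but not coordinates. The planted-clash benchmark rebuilds
one TCR-β tip residue as an arginine whose Cβ overlaps a peptide heavy
atom (< 0.8 × the contact distance); every substitution that keeps Cβ
inherits the clash, so glycine is the unique clash-relieving answer by
construction, and the generator verifies the planted repulsion through the
scorer before returning. Passing these tests demonstrates that the
machinery (geometry recovery, scanning, ranking, fitting) is correct; it
does not demonstrate predictive accuracy on real interfaces, where
backbone plasticity, water-mediated contacts, and crystallographic noise —
none of which the generators emulate — all matter.

Problem sizes were chosen for desk-scale runs: ~700-atom toy complexes,
57-candidate scans on the planted benchmarks (three interface positions ×
19), 20-seed simulate-and-fit affinity recoveries at ~2500 data points per
fit. The acceptance script (`scripts/acceptance.R`) reruns the two
affinity-recovery experiments end to end from a single seed.

## Known limitations

- The energy function is uncalibrated; ΔB values are ranking scores, not
  kcal/mol predictions, and per-term magnitudes depend on the bundled
  parameter tables.
- Fixed-backbone scanning cannot express mutations whose effect requires
  backbone movement; the CCD/MC refinement explores only small local
  perturbations.
- Heavy-atom hydrogen-bond detection accepts some geometrically
  implausible donors that explicit hydrogens would exclude.
- Automatic partitioning assumes a single-peptide class I architecture;
  class II, multi-peptide or scaffolded constructs need an explicit chain
  map.
- The CLI config file is JSON (precedence: flags > file > defaults).
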