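# tcrm — structural analysis and computational affinity maturation of TCR–pMHC complexes

`tcrm` is an R toolkit for the computational side of T-cell receptor (TCR)
engineering against peptide–MHC (pMHC) targets, built around the workflow
used to characterize and affinity-mature TCRs recognizing tumor neoantigens
such as KRAS G12V presented by HLA-A\*11:01. It covers, end to end:

- **Structure handling** — read/write PDB and mmCIF, resolve alternate
  locations, and partition a complex into its five biological roles
  (TCRα, TCRβ, MHC heavy chain, β2-microglobulin, peptide), either from an
  explicit chain map or automatically.
- **Docking geometry** — Kabsch superposition and RMSD; the TCR–pMHC
  *crossing angle* (angle between the vector connecting the two
  variable-domain disulfides and the peptide N→C axis, both projected into
  the MHC groove plane) and the *incident angle* (tilt of that vector out of
  the groove plane).
- **Interface analysis** — Shrake–Rupley solvent-accessible surface area
  (SASA) on a deterministic golden-spiral lattice, buried surface area
  `BSA = SASA(TCR) + SASA(pMHC) − SASA(complex)`, peptide burial, and
  van der Waals / hydrogen-bond / salt-bridge contact maps.
- **Binding score and mutation scanning** — a decomposable pairwise pose
  energy (attractive/repulsive Lennard-Jones, screened Coulomb,
  Lazaridis–Karplus solvation, hydrogen bonds) and the interface score
  `B = E(complex) − E(TCR) − E(pMHC)`. Fixed-backbone point-mutation
  scanning rebuilds only the mutant side chain from a staggered rotamer
  grid and ranks all substitutions (19 per position: the 20 standard amino
  acids minus cysteine, wild type included) by ΔB. Double mutants are
  combined with a joint rotamer search when the sites interact, and CDR
  loops can be refined by cyclic coordinate descent (CCD) plus Metropolis
  Monte Carlo.
- **Binding assays** — closed-form 1:1 Langmuir SPR sensorgram simulation,
  global kinetic fitting (shared ka, kd, Rmax across a concentration
  series), equilibrium fits, KD fold-change tables, and UV-exchange HLA
  ELISA quantification as percent-positive signal.
- **Synthetic data** — seeded generators for a five-chain toy complex with
  exactly known docking geometry, planted-clash design benchmarks, noisy
  sensorgrams, and ELISA plates, so the whole pipeline is testable with no
  downloads.

## Worked example

```r
library(tcrm)

## a synthetic complex built with a 62 deg crossing / 8 deg incident angle
toy  <- build_toy_complex(toy_complex_spec(crossing_angle_target = 62,
                                           incident_angle_target = 8,
                                           seed = 1))
part <- partition_complex(toy$model, "auto")[[1]]
g    <- docking_geometry(part)
#> crossing 62.1 deg, incident 7.9 deg

## interface burial
ba <- buried_surface_area(part)
#> BSA 35 A^2, peptide burial 92 A^2

## point-mutation scan on a planted-clash benchmark: the scanner must find
## the one substitution that removes a hard steric clash at the interface
case <- plant_clash_case(seed = 1)
pos  <- select_design_positions(case$partition, 8)     # within 8 A of peptide
sc   <- scan_mutations(case$partition, enumerate_substitutions(pos), seed = 1)
head(sc$ranking[, c("label", "delta_binding")], 3)
#>    label delta_binding
#> 45  βR7G     -3630.028
#> 49  βR7K     -3624.537
#> 40  βR7R     -3624.207

## SPR: simulate a 0.78-50 uM injection series at KD = 30.8 uM with 1%
## noise, then recover the affinity with a global 1:1 fit
d   <- simulate_sensorgram(ka = 1e4, kd = 0.308, Rmax = 100,
                           conc_series = spr_series_wt, noise_sd = 1, seed = 1)
fit <- fit_1to1(d)
#> kinetic_fit: ka 1.007e+04 1/(M s), kd 0.3108 1/s, KD 3.085e-05 M (30.8 uM)
fold_change(30.8, fit$KD * 1e6)
#> 0.999
```

The scan table reads as: `βR7G` (the planted clashing arginine mutated to
glycine) improves the interface score by far the most, because every other
substitution inherits the clashing C-beta atom; the recovered KD of
30.8 µM matches the simulation ground truth, and a fold change of ~1 means
the fitted variant binds as tightly as the reference.

A command-line interface wraps the same functions
(`exec/tcrm partition|geometry|interface|scan|refine|spr-sim|spr-fit|elisa|synth`),
emitting JSON reports with a reproducibility fingerprint.

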