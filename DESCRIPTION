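Package: tcrm
Title: Structural Analysis and Computational Affinity Maturation of TCR-pMHC Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing and affinity-maturing T-cell receptors
    (TCRs) against peptide-MHC (pMHC) targets. Reads PDB/mmCIF coordinates and
    partitions a TCR alpha/beta - MHC heavy chain - beta-2-microglobulin -
    peptide complex into its five biological roles; computes docking geometry
    (crossing and incident angles), Kabsch superposition and RMSD,
    Shrake-Rupley solvent-accessible surface area, buried surface area and
    interface contact maps; scores poses with a decomposable pairwise energy
    model and the interface binding score B = E(complex) - E(TCR) - E(pMHC);
    performs fixed-backbone point-mutation scanning with rotamer repacking and
    delta-binding-score ranking, double-mutant combination, and CCD plus
    Monte Carlo CDR loop refinement; simulates and globally fits 1:1 Langmuir
    surface plasmon resonance sensorgrams with fold-change reporting; and
    quantifies UV-exchange HLA ELISA plates as percent-positive signal.
    Seeded synthetic-data generators provide ground-truth fixtures for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
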