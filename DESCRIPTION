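Package: idpfel
Title: Conformational Ensembles and Binding Free-Energy Landscapes for
    Coupled Folding and Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of conformational ensembles of intrinsically
    disordered proteins (IDPs) and of their coupled folding and binding
    with folded partners.  Provides multi-model PDB ensemble I/O with
    per-frame statistical weights, residue-residue contact maps from
    side-chain heavy atoms and contact-probability differences, a
    hydrophobic-residue-cluster (HRC) order parameter and classifier,
    dihedral-based per-residue helicity with expanding-window
    uncertainties and helix-axis angles, binding collective variables
    (centre-of-mass distance, native-contact count and the fraction of
    native contacts Q against a reference complex), weighted
    two-dimensional free-energy landscapes with basin detection and
    per-frame state assignment, state-conditioned contact maps and
    indicator projections, Boltzmann-weighted cluster reweighting of
    observables, and a seeded synthetic-ensemble generator with exact
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
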