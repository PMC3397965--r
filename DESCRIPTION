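Package: liddock
Title: Anchored Flexible-Peptide Docking by Replica-Exchange Monte Carlo
    with Conformational Clustering and MM-GB/SA Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling autoinhibitory "lid" segments that occlude
    a receptor binding cleft as pseudo-substrates. Implements
    replica-exchange Monte Carlo docking of a terminally anchored flexible
    peptide under a composite soft-core energy model (torsional and
    nonbonded intramolecular terms, intermolecular van der Waals,
    electrostatic and pairwise desolvation terms), self-consistent rotamer
    optimization of binding-site side chains, conformational similarity
    clustering based on atom-class compatibility, Gaussian spatial
    proximity and the Tanimoto coefficient, knowledge-based and MM-GB/SA
    binding free-energy decompositions with normal-mode entropy, and
    ensemble/trajectory analyses (RMSD, RMSF, hydrogen-bond and
    salt-bridge occupancy, residue contact maps, accessible-surface-area
    changes, side-chain movements and interaction-mimicry tables).
    Deterministic synthetic-system generators provide toy receptors,
    trajectories with planted interactions, conformer sets with planted
    cluster structure, and harmonic systems with closed-form normal modes
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    pracma,
    yaml,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
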