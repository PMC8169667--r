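Package: stunbh
Title: Stochastic Tunnelling Basin-Hopping Search for Coarse-Grained
    Ligand/Receptor Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Global-minimum search for ligand/receptor binding poses of
    coarse-grained (MARTINI-style) bead models in explicit bead solvent,
    combining a stochastic-tunnelling effective potential, basin-hopping
    local minimization, and alternating molecular-dynamics and
    weakened-interaction (DMD) proposal moves under an adaptive Metropolis
    temperature. Includes nudged-elastic-band minimum-energy pathways with
    steered-pulling initial paths, trajectory observables (RMSD, radius of
    gyration, RMSF, residue-by-nucleobase interaction-energy maps, solvent
    shell counts), synthetic benchmark systems (Lennard-Jones clusters,
    pocket-bearing receptor toys, solvation, counterions), and PDB /
    extended-XYZ input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    bio3d,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
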