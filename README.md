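# stunbh

Global-minimum search for ligand/receptor binding poses of coarse-grained
(MARTINI-style) bead models in explicit bead solvent, with pathway and
trajectory analysis. The package is aimed at structural modellers who want
to find where a flexible molecule (e.g. a DNA aptamer) binds a receptor
protein at the coarse-grained level, without running blind microsecond MD.

## The method

The search walks on a transformed energy surface. With `f(x)` the
ligand–receptor interaction energy and `f0` the lowest value found so far,
each proposal is scored by the stochastic-tunnelling effective potential

    E_STUN(x) = ln( (f(x) − f0) + sqrt( (f(x) − f0)² + 1 ) )

which compresses the landscape above `f0` so the Metropolis walk can tunnel
through high barriers, while any `f < f0` is negative, always accepted, and
replaces `f0`. Proposals are generated basin-hopping style: a short
high-temperature NVT run (300 × 10 fs at 600 K) followed by FIRE local
minimization on the physical surface. Every second proposal runs on a
surface whose nonbonded interactions are uniformly weakened to 1/100
("DMD" moves), letting tightly bound fragments rearrange. Acceptance uses
the Boltzmann factor `exp[(STUN_last − E_STUN)/kT]`, with `kT` re-adapted
every 20 steps toward 50% acceptance. The full search repeats this from
many random receptor orientations.

On top of the search, the package provides nudged-elastic-band
minimum-energy pathways (with steered-pulling initial paths), and the
standard observables: RMSD, radius of gyration, per-nucleobase RMSF and
COM-distance traces, residue × nucleobase interaction-energy maps, and
solvent-shell counts.

## A worked example

Recover the global minimum of a 4-bead Lennard-Jones cluster — the regular
tetrahedron at −6 ε (here ε = 5 kJ/mol):

```r
library(stunbh)

cluster <- make_lj_cluster(4, seed = 2)
res <- run_search(cluster$conf, cluster$topo, cluster$ff,
                  n_starts = 1, iters_per_start = 80, seed = 1,
                  settings = stun_settings(objective = "total"))
res
#> stun_search: 1 starts x 80 iterations
#>   best objective: -30 kJ/mol
#>   overall acceptance: 47.5%

round(as.numeric(dist(res$best_conformation$coords)), 3)
#> [1] 5.276 5.276 5.275 5.276 5.276 5.276
```

The best objective is the total energy −30 kJ/mol = −6 ε, and all six
pairwise distances equal 2^(1/6) σ = 5.275 Å: the tetrahedron. The
acceptance rate sits near the 50% target that the adaptive-kT controller
steers toward.

For a binding problem, `make_pocket_system()` builds a pocket-bearing toy
receptor plus ligand, `run_search(..., settings =
stun_settings(objective = "binding"))` searches poses, and
`scan_rigid_poses()` provides a brute-force grid oracle to compare
against. See the vignette (`vignettes/stun-bh-search.Rmd`) for the model,
all tunable parameters, and the design rationale.

A thin command-line front end over the same functions ships in
`inst/cli/stunbh-cli.R` (subcommands `synth`, `search`, `neb`, `analyze`).

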