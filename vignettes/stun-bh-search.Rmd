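---
title: "Global pose search for coarse-grained complexes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global pose search for coarse-grained complexes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stunbh)
```

## The problem

Finding where a flexible ligand (an aptamer, say) binds a receptor protein in
water is a global-optimization problem on a very rugged energy surface.
Plain molecular dynamics gets trapped; plain basin hopping with random moves
mostly proposes clashes. This package implements a search strategy that
combines three ideas on top of a MARTINI-style coarse-grained (CG) bead
model:

1. **Stochastic tunnelling (STUN).** The objective `f` (the
   ligand-receptor interaction energy) is transformed about the best value
   found so far, `f0`:
   `E_stun = ln((f - f0) + sqrt((f - f0)^2 + 1))` — the inverse hyperbolic
   sine of `f - f0`. Everything above `f0` is compressed onto a gently
   growing scale, so the Metropolis walk can cross high barriers; everything
   below `f0` stays resolved and is always accepted (and replaces `f0`).
2. **Basin hopping (BH).** Every proposal is mapped to its local minimum
   before evaluation, so the walk happens on the piecewise-flat surface of
   basin minima rather than on the raw landscape.
3. **MD/DMD proposal moves.** Instead of random coordinate moves, each
   proposal is a short high-temperature MD run (300 steps of 10 fs at
   600 K). On every second iteration the nonbonded interactions are
   uniformly weakened to 1/100 of their physical strength ("DMD" moves),
   which lets tightly bound fragments rearrange; local minimization and the
   objective always use the physical, unscaled surface.

Acceptance follows the three-case Metropolis rule on the transformed
surface, with the temperature parameter `kT` re-adapted every 20 steps
toward a 50% acceptance rate (multiplicative factor 1.2). The full search
repeats this from many random receptor orientations and keeps the global
best.

## The energy model

Internal units are Angstrom, femtosecond, amu, Kelvin, kJ/mol and
elementary charge throughout.

* **Nonbonded**: typed 12-6 Lennard-Jones (Lorentz-Berthelot combination
  unless a pair table overrides it) plus Coulomb screened by a uniform
  relative dielectric (default 15, the usual value for non-polarizable
  MARTINI water). Both terms are multiplied by a quintic switching
  polynomial `S(r)` with `S = 1` at the switch start, `S = 0` at the
  12 A cutoff, and vanishing first and second derivatives at both ends
  (LJ switched from 9 A, Coulomb from 0.5 A). The published protocol fixes
  only the switching *window*; the quintic form is this package's choice
  because it makes both the potential and the forces exactly continuous,
  which the test suite verifies by central differences.
* **Bonded**: harmonic bonds `0.5 k (r - r0)^2` and harmonic angles
  `0.5 ka (theta - theta0)^2`. Directly bonded (1-2) and angle-end (1-3)
  pairs are excluded from nonbonded sums — standard CG practice.
* **Periodicity**: orthorhombic minimum image for nonbonded terms only;
  bonded terms are never wrapped. Non-periodic mode is used for cluster
  benchmarks and pathway toys.

The binding energy is evaluated at fixed geometry by inclusion-exclusion
over single-point energies (complex, complex minus ligand, complex minus
receptor, environment alone), which for a pairwise-additive potential is
*identical* to the ligand-receptor cross-pair sum; the test suite asserts
agreement to 1e-8 kJ/mol on randomly generated solvated systems. A printed
three-term form without the environment correction would instead pick up a
spurious solvent self-energy term; the correction is the standard
thermodynamic-cycle completion and changes nothing for vacuum systems.

## Dynamics and minimization

`run_nvt()` integrates velocity Verlet with Berendsen velocity rescaling
(`lambda = sqrt(1 + (dt/tau)(T0/T - 1))`, default `tau` 100 fs). With
`tau = Inf` the integrator is symplectic NVE; the tests check a drift below
1e-3 kJ/mol over 1000 fs for an LJ dimer and the expected ~4x improvement
when the step is halved. Velocities are resampled from a Maxwell-Boltzmann
draw at the start of every search proposal: local minimization between
iterations destroys any velocity information worth keeping.

`local_minimize()` implements FIRE (adaptive time step, velocity mixing,
restart on uphill power, plus a 0.3 A per-bead displacement cap) with a
conjugate-gradient alternative delegated to `stats::optim`. FIRE runs on
unit-mass dynamics, so its stable step is set by the stiffest curvature in
the model; the synthetic systems keep their stiffest bond constants near
100 kJ/mol/A^2 for this reason.

During proposal moves (only), an optional harmonic spherical container
holds the system together; its radius is fixed once per search start from
the extent of the minimized starting structure plus 5 A. Without it a
cluster at 600 K (where kT roughly equals the LJ well depth) evaporates
irreversibly and the search degenerates. The container is standard
basin-hopping practice, it never enters the objective or the minimization,
and it is a configurable setting.

## Pathways

`pull_path()` prepares an initial adsorption path by steered pulling in the
overdamped (quasi-static) limit: the target of a harmonic center-of-mass
distance restraint (50 kJ/mol/A^2) moves outward in small increments with a
few restrained-minimization steps each, and snapshots at evenly spaced COM
distances are restrained-minimized. The deterministic overdamped limit was
chosen over thermostatted pulling so the same seed gives the same path
exactly; the restraint stiffness and speed are configurable.

`neb_relax()` is a plain nudged elastic band (improved-tangent, spring
constant 10 kJ/mol/A^2, FIRE relaxation, frozen endpoints) with an optional
climbing image. Only ligand and receptor beads define the band metric and
receive the NEB projection; solvent beads relax on the bare physical force.
This avoids the solvent-permutation degeneracy of the path distance while
still letting water redistribute along the pathway. On the quartic double
well `(x^2 - 1)^2` with 16 images the recovered barrier is within 2% of the
analytic value of 1, converging monotonically from below as the image count
is refined (8 to 16 to 32); the climbing image lands on the saddle to 1e-6.

## Trajectory observables

RMSD uses Kabsch superposition (mass-unweighted). The radius of gyration is
the standard mass-normalized form; a compatibility flag provides the
unnormalized variant (dimensionally mass^1/2 * length), which is only
meaningful as a relative stability monitor. RMSF superposes every frame on
the window-mean structure using receptor beads and averages per-bead
fluctuations within each nucleobase (the per-bead profile is also
returned). The interaction map averages, over an analysis window, the
cross interaction energy between every receptor residue and every ligand
nucleobase; its column sums are the per-nucleobase histogram by
construction, and its total equals the time-mean nucleobase-receptor
interaction energy exactly — an identity the tests exploit. The default
highlight threshold, -8.4 kJ/mol, is the level used in the literature to
mark strongly bound residue contacts. Shell counts (`count_within`) use a
strict `<` comparison.

## Synthetic systems

The package validates against systems whose answers are known:

* **LJ clusters** (`make_lj_cluster`): the n = 3 and n = 4 global minima
  are analytic (-3 eps, -6 eps); LJ7 is checked against a multi-start
  minimization oracle. Defaults: sigma 4.7 A, eps 5 kJ/mol, mass 72 amu —
  one CG bead ~ four heavy atoms, and eps of order kT at the 600 K move
  temperature so proposal moves genuinely melt the cluster.
* **Pocket system** (`make_pocket_system`): a U-shaped groove carved as a
  slot into the top face of a compact 4 A lattice block, its floor lined
  with "sticky" beads (eps = 8 kJ/mol against nucleobase beads vs 2
  elsewhere) so the groove-bound pose is the designed optimum. Three
  design constraints matter and were arrived at deliberately: the lattice
  constant (4 A) is smaller than the bead diameter so ligand beads cannot
  intercalate; the receptor is a solid block several layers thick
  everywhere, so it has no soft plate-bending modes (a thin slab, however
  stiff its springs, bends globally and lets the ligand wrap it around
  itself — the strain is invisible to an interaction-energy objective);
  and the ligand ladder is braced (nucleobase-nucleobase rungs and
  diagonals) so its straight designed conformation is its rest shape.
  Without any one of these, the designed pose is *not* the optimum — the
  search (correctly) finds intrusive, wrapped or collapsed poses instead,
  and a rigid-pose oracle is meaningless.
* **Solvation** inserts 72-amu water beads by rejection sampling to a
  target mass density (default 1 g/cm^3), keeping 5 A to all solute beads.
  A universal 5 A minimum among *all* beads at 1 g/cm^3 would exceed the
  random-sequential-adsorption jamming density and can never terminate, so
  the water-water minimum is a separate, smaller parameter (3 A).
  Counterions replace randomly chosen water beads, conserving bead count.

What these fixtures do not emulate: real protein folds and flexibility
spectra, sequence-specific base parameters, polarizable or antifreeze
water variants (an antifreeze bead here is just another type), and
production-scale systems (~23,000 beads, 400,000 search iterations). Passing
tests on these fixtures validates the algorithmic contracts — transforms,
acceptance rules, controllers, integrators, identities — not the
biophysics of any particular complex.

## Validation protocol sizes

The shipped tests run the acceptance controller for 4000 iterations on
LJ13 (reporting acceptance over the second half: a 2000-proposal window
keeps the sampling noise of the estimate near one percentage point),
recover LJ3/LJ4/LJ7 global minima from 20 seeds, and recover the pocket
pose from 5 seeds with 10 starts x 40 iterations each against a two-stage
rigid-pose grid oracle (coarse 3 A / 45 degrees, locally refined at
1 A / 15 degrees, top poses then minimized flexibly). During the pocket
search the per-proposal FIRE budget is capped at 600 iterations — basin
hopping only needs approximate basin assignment, and the final reported
structure is re-minimized with a generous budget. These sizes were chosen
as the smallest at which the stochastic contracts are stable across
seeds.

## Known limitations

* The Berendsen thermostat does not sample a rigorous canonical ensemble;
  it is used here exactly as in the original protocol (proposal moves and
  relaxation), not for free-energy estimation.
* The search objective is the ligand-receptor interaction energy; for
  strongly deformable receptors this objective rewards strain it does not
  pay for. Keep such receptors genuinely near-rigid (as the pocket fixture
  does) or switch to the total-energy objective (`objective = "total"`).
* `pull_path` is quasi-static; it provides NEB *initial* paths, not
  work curves or free energies.
* kT0 = 1 (transformed-surface units), the x1.2 adaptation factor, and
  minimizing DMD-distorted structures under physical parameters are
  documented decisions where the original protocol is silent; all are
  exposed as settings.
```
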