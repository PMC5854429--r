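---
title: "Free-energy estimation for DNA unwrapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy estimation for DNA unwrapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(unspool)
```

# The problem

Nucleosomal DNA must partially unwrap from the histone core before
polymerases, remodellers and repair factors can reach it.  The natural
progress variable for outer-turn unwrapping is the DNA end-to-end distance
`d` (the distance between the two terminal residues), but the free-energy
differences involved — a few kcal/mol per released histone–DNA contact —
are far too small to converge from unbiased simulation.  `unspool`
implements the enhanced-sampling estimation chain used for this problem:

1. **multi-walker adaptive-bias ("flooding") dynamics** along `d` to force
   reversible unwrapping and to generate seed conformations spanning the
   coordinate;
2. **umbrella sampling** on a grid of harmonically restrained windows,
   each carrying the frozen adaptive bias in addition to its restraint;
3. **WHAM** — self-consistent weighted-histogram unbiasing of all windows
   into one distribution `P(d)` and profile `F(d) = -kBT log P(d)`;
4. **reweighting** of the unbiased ensemble onto structural coordinates:
   the total number of unwrapped base pairs `R2`, observable means and
   spreads along `R2`, and two-dimensional landscapes `F(d, R2)`;
5. **structural metrics**: per-end unwrapped counts, residue contact
   ratios stratified by unwrapping progress, end-asymmetry distributions,
   and stitching of per-stage free-energy changes into a total.

Because no trajectories of the original all-atom system are available,
every estimator is validated on synthetic systems with exactly known
answers: analytic one-dimensional potentials, and a coarse bead-on-spool
nucleosome mimic whose site-release free energies are exactly enumerable
(below).

# Units and integrator

Internal units are kcal/mol, Angstrom and picosecond, with
`kB = 0.0019872` kcal/mol/K, so `kB T ~ 0.596` kcal/mol at the working
temperature of 300 K.  Masses are carried in the derived unit
kcal/mol ps^2/A^2; the default mass of 1 gives thermal velocities of
about 0.77 A/ps and removes all unit conversion factors from the
equations of motion.

Sampling uses the BAOAB splitting of Langevin dynamics, chosen for its
accurate configurational averages at moderate timesteps.  With friction
`gamma = 0` it reduces exactly to velocity Verlet, which the tests use to
check energy conservation.  The default friction is 2 ps^-1.  One
Gaussian matrix is drawn from the master stream per step; walker `w`
always consumes column `w`, so the ensemble advances in lockstep with
fixed per-walker substreams and bit-identical reproducibility for a given
seed.

# The flooding stage

The shared bias `U(d)` lives on a uniform grid (resolution `dd = 1` A).
Every step, each in-range walker deposits a Gaussian kernel
(`sigma = dd`, truncated at `4 sigma`, renormalized after truncation)
whose integrated weight is exactly `kB T dt / tau`.  This normalization
makes two properties testable to machine precision: the total deposited
energy equals `kB T / tau` times the summed in-range residence time of
all walkers, and the deposition rate is proportional to the walker count
divided by the flooding time.  One-sided harmonic walls
(`k (d - wall)^2`, force constant 10 kcal/mol/A^2, no 1/2 factor —
the same quadratic convention as the umbrella restraint) confine walkers
to the biased range.

Bias evaluation between nodes uses a Catmull–Rom cubic interpolant whose
derivative is analytic, so biasing forces are smooth and exactly
consistent with the tabulated energies; the tests verify the derivative
against central differences at 1e-5 relative tolerance.

Two diagnostics decide convergence.  The *dropped-energy* profile — the
energy deposited per grid node per 1 ns interval — must become spatially
uniform; its summary metric is the maximum deviation from the spatial
mean divided by that mean.  And the free-energy estimate itself is taken
as the **negative of the bias averaged over the late half of the
snapshots** rather than the single final snapshot: once the landscape is
flat the bias grows uniformly while its shape fluctuates, and averaging
suppresses those fluctuations several-fold (the single-snapshot estimate
fluctuates enough to be unreliable at the few-tenths-kcal/mol level).

# Umbrella refinement and WHAM

Window centers form an inclusive-endpoint grid (`lo + spacing * i`); the
full-scale protocol uses 71 windows spanning 40–180 A and 26 windows
spanning 125–175 A at 2 A spacing.  Windows are seeded by sorting the
flooding walkers and picking, for each center, the walker whose `d` is
closest (ties to the lower walker id, for determinism).  Each window
samples under the combined bias

```
V_i(d) = k (d - d_i)^2 + U_abmd(d),        k = 0.2 kcal/mol/A^2,
```

with no 1/2 factor in the harmonic term, so a flat landscape gives a
stationary window variance of `kB T / (2k)`.  The frozen `U_abmd` is
shared bit-identically by all windows of a stage.  Samples outside the
window range (closed interval — the outermost centers sit exactly on the
range limits) are discarded with a logged count, mirroring the removal
of structurally corrupted extreme-coordinate conformations in the
original protocol.  A configurable burn-in (default 0, i.e. exposed
rather than silently assumed) drops initial relaxation; the analysis
configurations use a few hundred ps.

Where equilibration within single windows is slow — site opening and
closing in the mimic takes ~100 ps — the stage configuration can run
several **independent replicates per window**, seeded from the 1st,
2nd, ... nearest walkers.  WHAM pools replicate windows exactly as it
pools any other windows; replicates diversify the starting branch of
each window and are the main defence against seed-dependent metastable
window ensembles.

The WHAM solver is *binned*: histogram counts on a uniform grid (default
width 1 A, configurable; the mimic analyses use 0.5 A), biases evaluated
at bin centers, and the standard two-equation iteration run to a
tolerance of 1e-8 on `max |dF_j|` (the tolerance is interpreted in
kcal/mol on the iterated window shifts).  All sums are accumulated in
log space, since the frozen adaptive bias can reach tens to hundreds of
kcal/mol and the Boltzmann factors would otherwise overflow.  The first
window anchors `F_1 = 0` during iteration; the final profile is shifted
to `min F = 0`.  Empty bins propagate as missing values — never imputed,
never silently infinite.  Per-sample unbiased weights use the WHAM
denominator evaluated at the sample's *bin center*, which makes the
weighted histogram reproduce the solution's `P` bin-for-bin (an exact
internal-consistency invariant that the tests assert at 1e-12); the cost
is that the bias must vary little within a bin, which is why the output
bin width should stay at or below the bias-grid resolution.  Windows
whose occupied bins touch no other window's are reported by id as
non-overlapping.

Statistical-inefficiency corrections for correlated samples are *not*
applied (a documented limitation; the estimator treats samples as
independent), and binless estimators are used only as test oracles, not
as the primary path.

# Reweighting

Projections onto alternative coordinates are plain weighted tallies of
the per-sample unbiased weights: `P(R2)` sums weights per integer count
(unit-width bins, since unwrapped base pairs are integers), observable
means and spreads are weighted within-bin moments with
`sigma = sqrt(max(mean(A^2) - mean(A)^2, 0))` guarding rounding, and the
two-dimensional `P(R1, R2)` is the joint tally whose marginals reproduce
the one-dimensional projections exactly.  Empty bins are missing, not
zero.  All free energies are `-kB T log P`, min-anchored per profile
(for two-dimensional landscapes, anchored at the global minimum of the
stage).  Changing the temperature rescales every profile linearly
through `kB T`.

# The bead-on-spool mimic

The synthetic nucleosome stands in for the all-atom system.  Two arms of
`n_beads = 10` beads each are anchored to opposite attachment points on
a core cylinder and wrapped along mirror-image helical reference paths
(chord length 4 A on a circle of radius 10 A, arms offset to z = +/-1.5 A);
the reaction coordinate is the distance between the two terminal beads.
Four bonds per arm (every second bond from the third) carry binding
sites, emulating the discrete histone–DNA contact patches spaced a few
base pairs apart; the remaining bonds sit in stiff isotropic traps at
their wrapped reference orientations, so the arm transports its wrapped
geometry rigidly between sites.

Each site bond has two states joined by a smooth capture switch on the
displacement `u` of the bond vector from its wrapped reference:

* **bound** (`u` below the capture midpoint): a soft trap
  `bound_k u^2 - epsilon`, energy gain `epsilon` (default 1 kcal/mol per
  site, configurable per site and per arm);
* **released**: a longer bond (`free_length = 7` A vs the wrapped chord
  of 4 A) with a bending penalty `tension (1 - (b . e)/free_length)`
  toward the arm's exit axis — the straightening of a stiff DNA tangent
  once its contact breaks, zero in the fully extended aligned state.

Releasing a site therefore *lengthens* the end-to-end distance by
several Angstrom, which is exactly what lets a bias along `d` drive
unwrapping, as in the real system.  The tension default (3 kcal/mol) was
chosen so that consecutive release states are separated by more than
their conditional spread in `d`; much weaker coupling leaves high-release
states spread across the whole coordinate where no restraint can enrich
them, and much stronger coupling makes site opening too rare to
equilibrate within windows.  The bound-trap stiffness (0.2 kcal/mol/A^2)
was set, once, so that the exact single-site release cost at 300 K is
close to `epsilon` — making the step heights of the free-energy
staircase directly tunable through the site energies.  Release costs
still vary somewhat between sites (roughly 0.7–1.5 kcal/mol at the
defaults) because each site's reference orientation meets the exit axis
at a different angle; the oracle below accounts for this exactly.

**Why this design admits an exact oracle.**  Every term of the potential
depends on a single bond vector, so the unbiased Boltzmann ensemble
factorizes over bonds.  The partition function of each site bond splits
into bound and released parts computed by two-dimensional Gauss–Legendre
quadrature over bond length and displacement-from-reference (the
azimuthal integral of the tension term is a modified Bessel function);
the free energy over the total released-site count then follows from
enumeration over all `2^(2M)` occupancy states (equivalently, the
convolution of independent two-state sites).  This quadrature +
enumeration oracle is exact to quadrature precision and is what the
full sampling pipeline is measured against.  A reduced site-occupancy
Metropolis sampler provides an additional long-run consistency check of
the enumeration, and unbiased Langevin ensembles of the full bead model
agree with the oracle within sampling error — the factorization is
verified, not assumed.

What the mimic does *not* emulate: sequence heterogeneity, realistic DNA
bending/twist mechanics (roll/rise), electrostatics and ions, explicit
histone structure, or excluded volume.  Passing the recovery benchmarks
therefore demonstrates correctness of the estimation chain — bias
accounting, seeding, restrained sampling, WHAM, reweighting — not
fidelity of any particular nucleosome model.

Between protocol stages the arms are shortened by removing outermost
beads (the toy analog of deleting base pairs from each DNA end), sites
on removed bonds disappearing with them; the stage free-energy changes
along the unwrapped count are summed by the stitching step.

# Structural metrics

A unit (base pair or bead) counts as **unwrapped** when its center has
moved strictly more than 4 A from its reference position *and* the
displacement has a positive component along the core-to-reference
direction.  This conjunction satisfies both common phrasings of the
definition — displacement from the reference structure, and deviation
outward from the core — and both raw variants are available behind a
`mode` flag.  Per-end counts are contiguous from the outermost unit
inward (counting stops at the first wrapped unit), matching progressive
end unwrapping; the non-contiguous tally is attached as an attribute.
**Contacts** are inclusive: a residue contacts the partner group when at
least one inter-group atom pair is within 4 A (so exactly 4.0 A is a
contact, while exactly 4.0 A is *not* unwrapped — the strict/inclusive
asymmetry follows the definitions' wording).  Contact probabilities can
be weighted by the WHAM unbiased weights renormalized within each
stratum of unwrapping progress, or left as raw frame frequencies; both
modes exist because published contact panels rarely state which
convention they use.  The end-asymmetry matrix tallies (total, end1 -
end2) and normalizes each total-count column to 1.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen to make each
benchmark converge comfortably on one CPU: flooding benchmarks use 8
walkers for 2.5–6 ns with `tau` 20–25 ps; umbrella benchmarks use 21–28
windows of 2,000–4,500 ps (up to 3 replicates each) at 2 A spacing; WHAM
output bins are 0.5 A; the exact-sampler WHAM benchmark uses 21 windows
of 20,000 draws.  The full-scale protocol numbers (100 walkers, 15 ns,
71 + 26 windows) appear in the configuration and budget-accounting
layer, which the tests exercise without running dynamics at that scale.

Two protocol adaptations apply to the mimic benchmarks specifically.
The window force constant is lowered to `k = 0.05 kcal/mol/A^2`: a
single site release shifts `d` by ~5 A, which under the analytic
benchmarks' `k = 0.2` costs ~5 kcal/mol of restraint energy and freezes
each window onto one release state; the force constant is an arbitrary
protocol constant, and the softer value restores in-window exchange
while WHAM handles the coarser window resolution.  Likewise the
thermostat friction is lowered to 0.5 1/ps for the mimic runs — a purely
kinetic choice that speeds barrier crossing without touching the sampled
ensemble.

# Known limitations

* Binned WHAM introduces discretization error when the frozen bias or
  the underlying profile varies within a bin; keep bins at or below the
  bias resolution.
* No autocorrelation correction: error bars are not produced, and
  effective sample sizes are overstated for strongly correlated windows.
* The mimic's site kinetics (~100 ps exchange) mean short windows can
  carry seed memory; the replicate mechanism mitigates but does not
  eliminate this.
* The end-to-end distance discriminates release states only as strongly
  as the tension couples extension to release; recovering the last
  one or two release steps is the hardest part of the benchmark and
  dominates its residual error.
* The flooding estimate converges to the free energy only in the slow-
  deposition limit; at finite `tau` it fluctuates around it, which is
  why the umbrella + WHAM refinement exists.
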