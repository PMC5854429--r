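# unspool

Free-energy profiles for nucleosomal DNA unwrapping from multi-walker
adaptive-bias sampling, umbrella refinement and WHAM.

## The problem

The outer superhelical turn of nucleosomal DNA (~147 bp wrapped 1.75
times around the histone octamer) unwraps at a free-energy cost of only a
few kcal/mol per histone–DNA contact — far below what unbiased molecular
dynamics can resolve. The standard estimation chain for this problem
biases the DNA **end-to-end distance** `d`:

1. **Flooding (adaptively biased dynamics), multi-walker.** Many walkers
   share one history-dependent bias `U(d)`; each deposits a Gaussian
   kernel of integrated weight `kB·T·dt/τ` at its current position every
   step, filling free-energy wells until the landscape is flat. The
   per-1-ns deposited energy becoming spatially uniform is the
   convergence diagnostic, and `−U` estimates the profile.
2. **Umbrella sampling.** Windows on an inclusive grid
   `d_i = lo + 2 Å·i` (71 windows over 40–180 Å, then 26 over
   125–175 Å in the second, end-shortened stage), each restrained by
   `V_i(d) = k(d − d_i)² + U_abmd(d)` with `k = 0.2 kcal/mol/Å²` and the
   frozen flooding bias, seeded from the walkers sorted by `d`.
3. **WHAM.** Self-consistent solution (tolerance 1e-8, log-space sums) of
   `P(d) ∝ Σ_i h_i(d) / Σ_j N_j e^{[F_j − V_j(d)]/kBT}`,
   `F_j = −kBT ln Σ_d P(d) e^{−V_j(d)/kBT}`, giving the profile
   `F(d) = −kBT ln P(d)`.
4. **Reweighting** onto the number of unwrapped base pairs `R₂` (a bp is
   unwrapped when displaced outward > 4 Å from its reference position):
   `F(R₂)`, observable means/spreads along `R₂`, and 2-D landscapes
   `F(d, R₂)`.
5. **Structural metrics:** per-end unwrapped counts (contiguous from each
   end), residue contact ratios (contact = any inter-group atom pair
   within 4 Å), end-asymmetry distributions, and stitching of per-stage
   free-energy changes (e.g. 5.5 + 6.0 ≈ 11.5 kcal/mol across the two
   outer-turn stages).

Since no trajectories of the original all-atom system are public, the
package ships synthetic systems with exact answers: analytic 1-D
potentials, and a **bead-on-spool nucleosome mimic** whose per-bond
potentials factorize, so the free energy of every site-occupancy state is
exactly computable by quadrature + enumeration. Every estimator in the
chain is validated against these oracles.

## Worked example

Recover a double-well profile through the full umbrella + WHAM route:

```r
library(unspool)

dw  <- potential_spec("double_well", center = 50, well_separation = 10,
                      barrier = 3, domain = c(35, 65))
sys <- potential_system(dw)

grid    <- build_window_grid(40, 60, 1)        # 21 windows
windows <- run_windows(sys, grid, k = 0.2, duration = 2000, dt = 0.05,
                       record_interval = 10, seed = 7,
                       inits = matrix(grid$centers, nrow = 1))
biases  <- lapply(grid$centers, umbrella_window, k = 0.2)
sol     <- solve_wham(windows, biases, grid = histogram_grid(38, 62, 0.5))
prof    <- free_energy_1d(sol)
prof
#> <fe_profile> over d_A - 48 bins, 35 supported; T = 300 K
#>   F range: 0.0000 .. 8.3920 kcal/mol
round(prof$F[prof$centers %in% c(45.25, 50.25, 55.25)], 2)
#> [1] 0.00 3.11 0.36
```

The two wells sit near 0 kcal/mol and the barrier at ~3.1 kcal/mol — the
value built into the potential is 3 (the full profile range is larger
only because the rarely visited edge bins beyond the windowed region
carry high free energies). `analysis/` contains the full narrative
drivers: `01` flooding on the double well, `02` umbrella + WHAM
cross-checks, `03` the staged spool-mimic protocol with oracle
comparison, `04` asymmetry/contact metrics; each writes CSV/JSON tables
under `results/`.

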