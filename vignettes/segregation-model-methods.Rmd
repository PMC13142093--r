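---
title: "Methods: a loop-extrusion model of chromosome segregation in a minimal cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a loop-extrusion model of chromosome segregation in a minimal cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`chromocycle` simulates a complete cell cycle of a minimal bacterial cell —
a 543,379-bp circular chromosome inside a growing, dividing spherical
membrane crowded with ribosomes — and asks whether SMC (structural
maintenance of chromosomes) loop-extruding complexes suffice to segregate
the two daughter chromosomes. This vignette documents the model, its
parameters and units, the numerical choices, and where the implementation
had to make judgment calls.

## Model overview

Three coupled layers run on two cadences:

1. **A 1D loop-extrusion lattice.** The genome is discretized at 10 bp per
   site. Each SMC occupies two 3-site head footprints that move apart one
   site per iteration (two-sided extrusion). An iteration represents
   `10/v` seconds (40 ms at the reference speed `v = 500` bp/s), and a
   2-second communication tick runs `v/10` iterations.
2. **A 3D bead–spring polymer.** One bead per lattice site (3.4 nm
   diameter). SMC loops become weak harmonic bonds between the two head
   beads. Conformations relax by FIRE energy minimization and overdamped
   Brownian dynamics among fixed membrane (boundary) particles and mobile
   20-nm ribosome crowders.
3. **Cell geometry.** A sphere (R = 200 nm) grows linearly in volume to
   2V0 by minute 65, then divides at constant volume as two overlapping
   spheres whose union area grows linearly until they are tangent 200-nm
   daughters at minute 105. Closed forms for the union volume
   `(8/3)πR³ − (π/12)(4R + d)(2R − d)²` and area `4πR² + 2πRd`
   parameterise the dumbbell; `shape_at()` solves them with nested
   root-finding.

Every 2-s tick: extrusion iterations → replication-fork advance (spawning
daughter beads) → SMC bond rebuild → minimization with the DNA–DNA barrier
lowered to 0.2 kBT (type-II topoisomerase emulation: strands may cross) →
a "swollen" (3σ cutoff) BD relaxation that counteracts SMC-induced
compaction. Every minute: a long basal-diameter BD equilibration,
conformation sampling, ribosome addition, then the membrane geometry
update with the division axis oriented along the daughter
centre-of-mass axis.

## Units and key defaults

| Quantity | Value | Where |
|---|---|---|
| length / energy / time | nm / kBT (T = 310 K) / s | throughout |
| DNA bead diameter σ | 3.4 nm (10 bp) | `force_field()` |
| persistence length | 45 nm → κ_b = lp/σ kBT | `force_field()` |
| backbone / SMC bond | 1000/σ² and 1/σ² kBT/nm², r0 = σ | `force_field()` |
| excluded volume | A(1 + cos πr/r_c); A = 5 (0.2 crossing) kBT | `soft_pair_energy()` |
| BD timestep / viscosity | 25 ns / 1.2 Pa·s | `bd_params()` |
| SMC dwell / speed / count | τ = 100 s, v = 500 bp/s, N = 20 | `sim_config("paper")` |
| unbinding / bypass prob. | 20/(vτ) and iter_s/20 s per iteration | `smc_params()` |
| fork speed | 100 bp/s → 20 beads per fork per tick | `sim_config()` |
| contact map | 1-kb segments, 6-nm cutoff | `detect_contacts()` |
| partitioning radius | 30 nm | `partitioning()` |

Loop coverage `N·v·τ/L` summarises an SMC parameter set; 1.84 at the
reference parameters. Its value, not the individual parameters, predicts
segregation.

## Loop-extrusion rules

- Loading picks a uniformly random position whose six consecutive sites
  (two abutting footprints) are free, on a chromosome copy chosen in
  proportion to its current length; failures defer to the next tick.
- Heads stall against other SMC footprints (when `blocking_enabled`) and
  against replication forks. Fork blockers are never bypassed; SMC
  blockers are bypassed with probability `iter_seconds / 20 s` per
  iteration by relocating the head to the nearest free footprint within
  `bypass_search_sites` (15) sites beyond the obstruction.
- Unbinding is geometric: basal probability `20/(v·τ)` per iteration,
  optionally overridden for stalled SMCs; fork-stalled SMCs follow one of
  three policies (`stall_and_trail`, `unload_immediate`,
  `unload_enhanced`). Unbound SMCs reload immediately, so the bound count
  is conserved and ramps as `round(N(1 + f))` with replicated fraction
  `f`.
- With blocking disabled, occupancy switches from exclusive ids to
  coverage counts and SMCs pass freely through one another.

Replication follows the train-track convention: two forks leave the
origin bead in opposite directions; a replicated mother bead becomes the
left-daughter bead in place while the right-daughter copy is appended
past the genome end, completing at exactly twice the bead count. SMCs
overlapping newly replicated mother sites are evicted and reloaded.

## Initial configuration

The published protocol starts from a fractal-globule conformation; that
generator is external to the paper, so `generate_ring()` substitutes a
hierarchical midpoint refinement of a coarse random closed loop (each
round inserts perturbed edge midpoints, then minimization plus geometric
fix-up passes enforce bond lengths in [0.5σ, 1.5σ], membrane containment,
ribosome clearance and non-overlap). Like a fractal globule it is a
compact, largely unknotted ring threaded through fixed ribosomes, but it
does not reproduce fractal-globule contact statistics at short genomic
distances — adequate here because every production run re-equilibrates
with strand crossing enabled before data are taken.

## Judgment calls (under-specified points)

- **Persistence length 45 nm**: not restated by the simulation section;
  standard dsDNA value, consistent with the bending prefactor used.
- **DNA–ribosome and DNA–membrane cutoffs 11.7 nm**: sum of the bead
  radius (1.7 nm) and particle radius (10 nm); the initial-placement
  clearance reuses the same number.
- **`bypass_search_sites = 15`**: the search range for a bypass landing
  site; nearest-vacant-site semantics with a bounded scan.
- **Partitioning** is reported pooled over both daughters (fraction of
  all daughter beads with no opposite-daughter bead within 30 nm);
  `per_daughter = TRUE` exposes the two fractions.
- **Minute-event ordering**: sampling happens after the long
  equilibration and before ribosome addition and the geometry update, so
  sampled conformations are equilibrated under the geometry they were
  simulated in.
- **Initial radius 206 nm** (vs the 200-nm growth origin): the membrane
  at replication initiation (t = 5 min) already holds the 5-minute
  volume growth.

## Numerics

- Pair interactions use a uniform grid; the cell edge follows the largest
  cutoff involving DNA and per-class scan radii keep the search exact
  (verified against the all-pairs sum to 1e-12) while staying fast for
  the common case where only ribosome–ribosome pairs need 20 nm.
- FIRE minimization treats ribosomes and boundary particles as fixed;
  BD moves ribosomes but never boundary particles. A warning flags BD
  steps exceeding one bead diameter.
- All stochastic draws go through R's RNG in named streams (placement,
  SMC, BD noise) derived from one master seed, so runs are reproducible
  and toggling one subsystem does not perturb the others.
- Knight–Ruiz balancing implements the inner–outer Newton/conjugate-
  gradient scheme with bounded line steps; all-zero rows are removed and
  reinserted.

## Presets and scaled-down testing

`sim_config()` ships three presets: `paper` (full scale; hours of CPU),
`desk` (54,340 bp, reduced relaxation; ~1 h per cycle) and `micro`
(3,000 bp, 36-nm cell, 12-minute cycle; ~3 min per cycle). `micro` keeps
the paper's loop coverage (1.8) and bead density so 1D behaviour and
compaction trends survive, but its cell is only ~25 beads across: the
30-nm partitioning statistic is degenerate at this size (a ball large
enough to contain informative bead counts is no longer small relative to
the cell). The package's own scaled-down segregation check therefore
compares late-cycle daughter radii of gyration between high (1.8) and
low (0.2) loop coverage — the compaction that drives partitioning at
full scale — across paired seeds with a sign test. This scaling choice
is the package's own, made for test-budget reasons; the full-scale
statistic is available via `partitioning()` on `desk`/`paper` runs.

## Reproducing the headline analyses

```{r}
library(chromocycle)

# segregation trend at toy scale
high <- run_cell_cycle(sim_config("micro", seed = 1))
low  <- run_cell_cycle(sim_config("micro", smc = list(tau = 0.4), seed = 1))

# stationary Hi-C-like maps (blocking vs passing vs short dwell)
st <- run_stationary(sim_config("micro", seed = 1), "blocking",
                     n_replicates = 10, t_run_min = 10)
cm <- kr_balance(frames_contact_map(st$frames))
plot(contact_probability_curve(cm)$s, contact_probability_curve(cm)$p,
     log = "xy", type = "l", xlab = "s (bp)", ylab = "P(s)")
```
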