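---
title: "Methods: contact, secondary-structure and dimerization analysis of Cα-trace ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, secondary-structure and dimerization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerlens)
```

## The problem and the model

α-Synuclein is a 140-residue intrinsically disordered protein; its
dimerization is the first step of the aggregation cascade behind
Parkinson's disease. Coarse-grained simulations of two chains produce large
ensembles of Cα-trace snapshots in which free monomers, disordered dimers
and a minority of pre-fibrillar dimers coexist. `dimerlens` implements the
analysis layer for such ensembles. All of its definitions operate on Cα
coordinates only:

* **Contact**: two Cα atoms of different residues at a distance strictly
  below 6 Å. Per snapshot this yields the pair counts n_inter (interchain)
  and n_intra (intrachain, both chains pooled).
* **Dimer**: more than 10 interchain residue pairs at < 5 Å. The 5 Å value
  is anchored to the ~4.8 Å Cα–Cα spacing between same-index residues of
  adjacent chains in in-register parallel fibrils; the count is pair-level
  (a residue contacting several partners contributes several pairs, each
  once). The smallest dimer therefore has 11 close pairs.
* **Native fibril contact (Nfc)**: residue r of chain A and residue r of
  chain B at < 5 Å — the same-index geometry of fibrils. A dimer carrying at
  least 5 *consecutive* Nfcs (strictly adjacent indices, no gaps) is a
  pre-fibrillar dimer (**Dfncs**); all other dimers are disordered.
* **Effective free energy**: for any histogrammed order-parameter pair,
  F = −ln(P/P_max) in kT units, zero at the most probable bin, +Inf where
  unoccupied.

Two cutoffs coexist deliberately: contacts use 6 Å, dimer membership and
Nfcs use 5 Å. They are independent parameters (`compute_contacts(cutoff=)`,
`classify_dimer(cutoff=)`), because the literature definitions genuinely
differ and conflating them changes n_inter by tens of pairs.

## Secondary structure from curvature and torsion

The assignment uses only the pseudo bond angle θ_i (triplet i−1, i, i+1)
and pseudo dihedral τ_i (quadruplet i−1, i, i+1, i+2) of the Cα trace,
avoiding any all-atom reconstruction. The numeric windows are calibrated on
ideal geometry, not transcribed from elsewhere: the ideal α-helix Cα
parametrization (radius 2.3 Å, rise 1.5 Å/residue, 100°/residue) gives
θ = 90.4° and τ = +50.0°, and an extended zig-zag strand with 3.8 Å bonds
and θ = 125° gives τ = 180°. The defaults in `ss_params()` bracket these
values generously:

| parameter | default | role |
|---|---|---|
| `helix_theta` | [80°, 105°] | curvature window for helix candidates |
| `helix_tau` | [30°, 70°] | torsion window (right-handed helix) |
| `strand_theta` | [100°, 155°] | curvature window for extended candidates |
| `strand_tau_abs` | [140°, 180°] | torsion magnitude for extended candidates |
| `min_helix_len` | 4 | shorter helical stretches are not counted |
| `min_strand_len` | 2 | a β-sheet needs two strands of ≥ 2 residues |
| `pairing_cutoff` | 5.5 Å | Cα–Cα cutoff for sheet pairing |
| `min_intra_pair_sep` | 4 | stops near-neighbour self-pairing in hairpins |

Helix candidates in runs of ≥ 4 become H. Extended candidates become E
*only* when paired: residues i and j pair when both are candidates, closer
than the pairing cutoff, and the pairing propagates to (i+1, j+1) (parallel)
or (i+1, j−1) (antiparallel); an isolated close pair is discarded. A residue
bridging two sheets keeps all its pairs, but per-residue sheet statistics
count it once per snapshot and orientation.

**Junction convention.** τ_i needs residue i+2, so the last residues of a
structured segment lack a dihedral of their own; candidacy therefore accepts
τ_i *or* τ_{i−1} in-window. Even so, the first and last one-to-two residues
of a planted segment have mixed geometry and drop to coil. Ground-truth
labels in the generator treat junctions as coil for the same reason, and the
recovery tests score interior residues (100% precision is required
everywhere; recall is measured away from junctions).

**Two-state statistics.** Snapshot (α, β) counts are accumulated over
residues 1–95 (N-terminal 1–60 + NAC 61–95; the acidic C-terminus
contributes no discriminating structure). Snapshots with α = 0 form the
helix-free B state, the rest the HB state; `cumulative_dos_curve()`
references F to the maximum probability on the α = 0 axis and errors when no
B snapshot exists, because the reference state is then undefined.

## Landscapes and minima

`effective_landscape()` bins integer samples with bin width 5 on both axes
(the histogram is over raw contact counts, where unit bins are too noisy at
typical ensemble sizes). `find_minima()` smooths P before detection.
The smoothing kernel is a 3×3 binomial ([1 2 1]⊗[1 2 1]/16) with zero
padding rather than a uniform box: a box kernel turns an isolated
single-bin basin into a 3×3 plateau with no *strict* local minimum, whereas
the binomial kernel keeps a strict peak and — because every isolated peak is
scaled by the same central weight — preserves the depth difference
−ln(P_i/P_1) between separated basins exactly. Minima are occupied cells
strictly below all 8 neighbours, reported within a depth window (default
1 kT) of the global minimum, sorted by F with (x, y) lexicographic
tie-breaking for determinism.

## The synthetic generator

`sample_ensemble()` stands in for undeposited trajectories. Its defaults
*are* the study conditions of the wild-type system: 31% of snapshots are
dimers; 8.33% of dimers carry the native-contact interface; the planted
Dfncs interface is the 18-residue in-register parallel window 78–95 at
4.8 Å spacing (the longest consecutive native-contact run reported for the
wild type); the transient helix 53–65 is planted in both chains; per-chain
radii of gyration follow the two-component mixture 33.5 Å (60%) / 42.2 Å
(40%) with σ = 2.5 Å, the wild-type dimer clustering. Disordered dimers get
a register-shifted (shift 1) 14-residue contact patch: > 10 close pairs, so
they classify as dimers, but zero same-index contacts. Monomer snapshots
keep the chains > 10 Å apart.

Construction details that matter for downstream validity:

* Virtual bonds are 3.8 Å everywhere (helix template bonds are 3.83 Å, the
  chord of the ideal parametrization); coils are self-avoiding walks with a
  4.0 Å minimum non-bonded separation.
* Chain compactness is controlled by a single knob (extension persistence
  vs centroid attraction) and per-chain Rg targets are met by bisection on
  that knob with common random numbers — never by rescaling coordinates,
  which would corrupt the bond-scale features the assignment depends on.
* Dimer interfaces are pinned first and the tails grown outward with
  opposite normal biases under a 6 Å interchain clearance for all grown
  points. Cross pairs *within* the interface block sit near
  √(4.8² + 3.4²) ≈ 5.9 Å in any β-sheet geometry, so the 6 Å clearance
  exempts the block itself.
* `helix_fraction` (default 1) controls the share of snapshots carrying the
  planted helix; it exists so mixed B/HB ensembles can be generated for the
  two-state statistics and is generator plumbing, not a biophysical claim.
* Everything is seeded and bitwise reproducible; `plant_dimer()` retries
  with regrown coils (bounded, seeded) when a placement clashes and errors
  with a diagnostic afterwards.

What the generator does **not** emulate: thermodynamic weights (snapshots
are drawn from a label plan, not a Boltzmann distribution), force-field
energetics, side chains, sequence-dependent contact propensities, and the
correlation between compactness and secondary structure seen in real
ensembles. Passing tests therefore demonstrate that the analysis recovers
*planted* structure exactly; they do not validate biophysical accuracy on
real trajectories.

## Observables

* **Rg**: root-mean-square Cα distance from the centroid; dimer Rg pools
  the 280 positions, per-chain Rg is exposed for monomer/dimer comparisons.
* **GMM**: expectation–maximisation over k = 1..4 with equal- and
  unequal-variance models, selected by BIC (`mclust`); the fit is
  deterministic given the seed. At least 50 samples are required.
* **FRET proxy**: E = 1/(1 + (d/R₀)⁶) with R₀ = 60 Å and d the Cα distance
  plus a 20 Å offset (twice the dye-centre-to-Cα distance); 7.5 and 15 Å
  offsets are exposed as parameters. E = 0.5 exactly at Cα distance
  R₀ − offset; this is an orientation-averaged single-R₀ approximation and
  nothing more.
* **Chou–Fasman profile**: sliding window (15 residues) over the 1978
  β-sheet conformational parameters with weights falling linearly from 1 at
  the centre to 0.10 at the edges, normalised by the weight sum; termini
  use truncated windows. Peak positions are read off as local maxima with
  plateau handling (left edge wins).

## Numerical choices and degenerate inputs

* Strict inequalities at every cutoff (a pair at exactly 5.0 Å is not a
  contact), so boundary behaviour is testable.
* Near-collinear triplets give NA angles, never exceptions; chains shorter
  than 4 residues are rejected for geometry.
* Ties in minima are broken lexicographically; ties in B/HB at α = 0 are
  exact integer comparisons.
* A missing Cα in a PDB model is a hard error naming model, chain and
  residue; zero models is a hard error.
* Population partitions use D = round(f·N/(1+f)) (dimers), round(g·D)
  (Dfncs), N − 2D (free monomers) — exact integer arithmetic.

## Problem sizes

The test suite runs ensembles of 6–60 snapshots and mixture fits on 2000
draws; the acceptance script uses 200 snapshots (≈ 60 s on one CPU). These
sizes were chosen so the planted-count checks are exact and the mixture
recovery is well inside its ±1 Å tolerance.

## Known limitations

* The curvature/torsion windows are calibrated, not fitted to a reference
  assignment; on real (noisy) traces the helix/strand recall at segment
  junctions is conservative by design.
* 3₁₀/π helices and β-bridges are out of scope (minimum lengths 4 and 2).
* The fibril-reference extraction assumes adjacent chains stack along the
  principal axis of the chain centroids; exotic polymorph topologies may
  need a user-supplied chain pairing.
* FRET photophysics beyond the single-R₀ approximation and SAXS curve
  prediction are out of scope.
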