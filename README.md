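# dimerlens

Analysis of coarse-grained α-synuclein dimerization ensembles from Cα traces.

α-Synuclein is a 140-residue intrinsically disordered protein whose
aggregation is the molecular hallmark of Parkinson's disease. Its very first
aggregation step — dimerization — produces a heterogeneous mixture of
disordered dimers and a minority of pre-fibrillar dimers that already carry
the in-register intermolecular β-sheet geometry of mature fibrils.
`dimerlens` implements the complete desk-side analysis of such two-chain
Cα-trace ensembles (e.g. snapshots from coarse-grained molecular dynamics of
the wild type and the familial variants A30P, E46K, A53T), for structural
bioinformaticians who need the classification, secondary-structure and
observable layers without the original trajectories.

## What it computes

* **Dimer classification.** Two chains form a dimer when more than 10
  residue pairs have an intermolecular Cα–Cα distance < 5 Å.
* **Contacts and landscapes.** A contact is a Cα pair of different residues
  at < 6 Å. Per-snapshot counts (n_inter, n_intra) are histogrammed into a
  dimensionless effective free-energy landscape F = −ln(P/P_max) (kT units)
  with local-minimum extraction; per-residue mean intermolecular contacts
  and 140×140 contact-probability maps summarise where along the sequence
  chains touch.
* **Secondary structure from Cα geometry.** Helix and strand states are
  assigned from the pseudo bond angle θ_i (curvature) and pseudo dihedral
  τ_i (torsion) of the Cα trace — no all-atom reconstruction. Helices need
  ≥ 4 consecutive residues; strands become β-sheet only when paired
  (≥ 2 consecutive pairs, consistent register), with parallel/antiparallel
  orientation and intra/inter scope. Snapshot (α, β) counts over residues
  1–95 split the ensemble into helix-free (B) and helix-bearing (HB) states
  with a cumulative density-of-states curve.
* **Native fibril contacts.** Residue r carries an Nfc when chains A and B
  have their residue-r Cα atoms at < 5 Å — the same-index contact of
  in-register parallel fibrils. A dimer with ≥ 5 consecutive Nfcs is a
  pre-fibrillar dimer (Dfncs). Contour lengths for AFM comparison follow
  L = 2 × (140 − r_first + 1) × 3.8 Å.
* **Experiment-facing observables.** Radius of gyration with
  Gaussian-mixture (EM + BIC) clustering; interchain residue-90 distance
  distributions; an approximate FRET efficiency E = 1/(1 + (d/R₀)⁶) with
  R₀ = 60 Å and d the Cα distance + 20 Å dye offset; Chou–Fasman β-sheet
  propensity profiles (window 15, edge weight 0.10).
* **Synthetic labelled ensembles.** A seeded generator plants ideal helices,
  strands, in-register/shifted/antiparallel interfaces at 4.8 Å spacing and
  multi-component Rg mixtures, with a ground-truth label table, so every
  stage is testable without the original trajectories.

## Worked example

```r
library(dimerlens)

spec <- ensemble_spec(n_snapshots = 50, dimer_fraction = 0.3,
                      dfncs_fraction_of_dimers = 0.2, seed = 11)
gen <- sample_ensemble(spec)

sum(sapply(seq_len(50), function(i) classify_dimer(gen$ensemble[[i]])$is_dimer))
#> [1] 15
sum(sapply(seq_len(50), function(i) classify_dfncs(gen$ensemble[[i]])$is_dfncs))
#> [1] 3

res <- run_pipeline(list(input = spec, outdir = "run1"))
res$manifest$nfc_max_run$length     # longest consecutive native-contact run
#> [1] 18

fit <- fit_rg_mixture(unlist(lapply(seq_len(50), function(i)
  radius_of_gyration(gen$ensemble[[i]], "chain"))))
fit
#> <gmm_fit> 2 components; ensemble average 37.5 A
#>     mean    sd weight
#> 1 33.445 2.649  0.523
#> 2 41.884 2.649  0.477
```

The generator planted 15 dimers (30% of 50), 3 of them pre-fibrillar, each
carrying the default 18-residue in-register interface over residues 78–95 —
and the classification and native-contact layers recover exactly those
numbers from the coordinates alone. The Rg mixture fit recovers the
two-component generating mixture (means 33.5 Å / 42.2 Å) from just 100
per-chain samples.

`run_pipeline()` writes per-snapshot labels, contact counts, residue
profiles (helix, intra-/inter-sheet, Nfc probabilities), contact maps, the
(n_inter, n_intra) landscape with its minima, and a JSON manifest; re-running
with the same seed reproduces every output byte for byte.

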