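---
title: "Models and methods behind foldscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foldscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

foldscape analyses conformational ensembles of DS119, a de novo designed
36-residue βαβ mini-protein. This vignette explains the models behind
each module, the tunable parameters, and the design choices made where
the problem left the design open. It states no empirical result that
the package's tests and `scripts/acceptance.R` do not themselves
compute.

## Order parameters

All landscape axes are scalar functions of a conformation:

* **Whole-fold RMSD, α-RMSD, β-RMSD.** Least-squares (Kabsch)
  superposition followed by RMSD over the *same* atom set. The
  whole-fold measure uses the mainchain (N, CA, C, O) of residues
  5–10 ∪ 14–27 ∪ 29–34 because the tails and loops of DS119 are
  flexible and would dominate a full-chain RMSD; α-RMSD uses 14–27 and
  β-RMSD 5–10 ∪ 29–34. Fitting and measuring on the same atoms is the
  simplest defensible convention when a fit set is not otherwise
  specified; the alternative (fit on the whole fold, measure per
  segment) mixes segment and global deviation and is deliberately not
  used.
* **Radius of gyration.** Mass-weighted over heavy atoms. Hydrogens are
  excluded: they contribute little mass, and ensembles with and without
  explicit hydrogens then give comparable values.
* **W9–W34 distance.** Euclidean distance between the centroids of the
  nine indole-ring heavy atoms of Trp9 and Trp34. "Aromatic group" is
  operationalised as the ring centroid because it is symmetric,
  complete-atom-set checked, and insensitive to ring flips.
* **Hydrophobic-core SASA.** Shrake–Rupley point sampling over the heavy
  atoms of Ile8, Val10, Leu17, Leu20, Ala24, Ile29, Val31 and Phe33;
  occluders are *all* heavy atoms of the frame. Defaults: probe 1.4 Å,
  960 points per sphere (Fibonacci lattice, deterministic), radii
  C 1.70, N 1.55, O 1.52, S 1.80 Å. The lattice is fixed in the lab
  frame, so SASA is rotation-invariant only to within sampling error
  (≈1% at 960 points; doubling the point count moves values by < 2%).
* **Secondary structure.** A minimal dictionary-style assignment over
  {H, E, C}. Mainchain hydrogen bonds use the Kabsch–Sander
  electrostatic proxy `E = 27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
  kcal/mol with a bond when `E < −0.5`; amide hydrogens are rebuilt
  from the previous residue's carbonyl when absent, prolines donate
  nothing, and residues with missing backbone atoms are labelled `X`
  and dropped from helix-content denominators. Helices need two
  consecutive i→i+4 turns, so chain termini can never be `H`; strands
  come from the parallel/antiparallel bridge patterns and may pair
  across chains. The richer 8-state alphabet (3-10/π helices, turns,
  bends) is out of scope: helix content and strand pairing are all the
  downstream analyses consume.

The Boltzmann constant used throughout is 0.0019872041 kcal mol⁻¹ K⁻¹,
defined once.

## Free-energy landscapes

`build_landscape()` bins order-parameter pairs on a half-open grid
(`[lo, hi)`, last bin closed) and sets `F = −k_B T ln(count/N)`,
offset so the lowest occupied bin is zero; empty bins are `+∞`. The
estimator uses raw bin probability, not density — with uniform bins the
two differ by a constant, and only differences between bins are treated
as physically meaningful. Absolute basin depths depend on an arbitrary
offset and are therefore never reported as such.

**Basins** are found by watershed flooding: bins below a ceiling
(`f_max` above the global minimum, default 1.0 kcal/mol in
`find_basins()`) are processed in order of increasing F and join their
lowest assigned neighbour (8-connectivity); where two basins meet, the
shallower is absorbed unless its relief exceeds `merge_depth`
(0.5 kcal/mol). The merge depth mirrors the scale of the barriers the
analysis is meant to resolve (a few tenths of a kcal/mol to ~1
kcal/mol); minima separated by less relief than that are indistinguishable
from sampling noise at desk-scale ensemble sizes.

**Barriers** are minimax path costs: over all 8-connected paths of
finite-F bins between two basin minima, the path whose maximum F is
smallest, found with a Dijkstra-type widest-path search. Forward and
reverse barriers share the saddle, so
`barrier(a→b) − barrier(b→a) = min_F(b) − min_F(a)` exactly. The
implementation is verified in the tests against an independent
exhaustive oracle (smallest threshold at which the two bins become
connected).

**Smoothing** (`smooth_landscape()`) convolves the *counts* with a
Gaussian kernel before the free-energy transform, conserving mass. The
monomer pipeline detects basins on a lightly smoothed grid (σ = 0.6
bins on a 0.25 Å grid) because raw multinomial noise can dig spurious
one-bin bridges between neighbouring basins; the ridge between the two
closest planted states survives this kernel while single-bin noise
does not, which is what fixed the choice. Quantities read off bins
(minima) are taken from the raw grid.

**Parameter recovery** (`recover_planted_landscape()`) estimates each
well minimum by a count-weighted quadratic fit of `−k_B T log p` over
the 5×5 bin core around the smoothed argmin — interpolating away bin
discretisation — and the barrier as the smoothed saddle probability
against the fitted shallow minimum. On the planted two-well calibration
surface (ΔF = 1.0, barrier 2.0 kcal/mol, wells of width 1.5 Å placed
10 Å apart, T = 300 K, 10⁵ Metropolis samples) this recovers ΔF to
about ±0.06 and the barrier to about −0.15/+0.05 kcal/mol across
seeds; the residual barrier bias is the noise-seeking of the minimax
search on a stochastic surface and is documented rather than corrected.

## Contact analysis

A residue contact is a heavy-atom pair strictly closer than 4.5 Å.
Within a chain, pairs must satisfy `|i − j| ≥ 3`; the strict reading
(i and i+3 may touch, i and i+2 may not) was chosen, and the
separation is a parameter for users who prefer ≥ 4. Cross-chain pairs
have no separation filter. The generic search uses a neighbour-grid
(cell list) at the cutoff length; the two-chain fast path evaluates the
cross-distance matrix directly. Both are property-tested against an
all-pairs scan.

Mainchain hydrogen bonds between segments reuse the Kabsch–Sander
criterion — one hydrogen-bond definition package-wide — and persistence
is the longest run of strictly consecutive bonded frames (a single
bond-free frame breaks the run; no tolerance window, the simplest
deterministic rule).

## The dimer pipeline

* **Binding**: earliest time from which the minimum inter-chain
  heavy-atom distance stays below 4.5 Å for a 5 ns persistence window.
  The cutoff reuses the contact definition; 5 ns excludes grazing
  collisions. A contact-count criterion is available as an alternative
  through the contact series.
* **Flat stage**: the earliest 50 ns window in which the least-squares
  slope of the inter-chain contact-pair count is at most 0.05
  contacts/ns, extended while consecutive windows keep passing.
  Interface statistics use the first 400 ns of the stage (shorter
  stages are used whole and flagged).
* **Interface maps**: contact probability per cross-chain residue pair
  over the statistics window; per-residue marginals (fraction of frames
  with any cross-chain contact); candidate segments are maximal runs of
  residues with marginal ≥ 0.3. The common-segment report counts, per
  residue, the simulations where it falls in a detected segment on
  either chain, and reports maximal runs supported by a majority.
* **Average structure**: all stage frames are iteratively superposed
  (heavy atoms) onto the running mean until the mean moves < 0.01 Å;
  the representative snapshot is the stage frame with the smallest
  heavy-atom RMSD to that average (earliest on ties).
* **Projection**: each chain of the snapshot is extracted as a monomer,
  its (β-RMSD, α-RMSD) computed against the reference, and classified
  against the monomer basins — `in` a basin's bin set, `near` within a
  one-bin Chebyshev margin, else `far`.

## Synthetic ensembles and what they do (not) show

The generators replace multi-microsecond MD campaigns, which are out of
scope; they emulate the *statistics* the analyses consume, not the
physics.

* **Mock reference.** Built from the printed sequence with ideal
  geometry: NeRF chain extension with standard bond lengths/angles,
  helix at (φ, ψ) = (−57°, −47°), strands at (−119°, 113°) paired as a
  parallel sheet whose register is chosen by maximising Kabsch–Sander
  bonds under a steric veto, loops as geometric connectors, CB stubs,
  and full indole rings on the tryptophans oriented into the
  least-crowded rotamer. It passes the package's own structural checks
  (DSSP pattern, sheet contact block, ≥ 2 Å non-bonded clearance) and
  is a stand-in for an experimental reference model, which can be read
  with `read_pdb()` as a drop-in.
* **Planted landscapes.** Gaussian-well mixtures over
  (β-RMSD, α-RMSD). The five-state default places the native-like F'
  at (6.0, 1.8) Å and the helix-intact/termini-separated I3 at
  (15.0, 1.9) Å, with I1 (6.0, 5.0), I2 (6.0, 3.5) and U (15.0, 3.6)
  completing the layout; planted minima follow the states' relative
  stabilities (spanning ≈ 0.85 kcal/mol) above an arbitrary background,
  and the common width 0.45 Å keeps adjacent states separated by
  ridges of ≥ ~1.3 kcal/mol, resolvable at the default grid. Sampling
  is by 50 independent Metropolis walkers (step 1.3 Å, 300 burn-in
  sweeps, thinning 8 — set for walker decorrelation, checked by the
  recovery variance), bit-identical for a fixed seed.
* **Decoration.** A sampled (β, α) point becomes a 3D conformation by
  blending the reference toward a globally aligned extended template:
  helix residues toward the α target; the C-terminal strand, loops and
  termini toward the β target. The N-terminal strand 5–10 keeps its
  native internal geometry — the β deviation is realised as displacement
  of the partner strand — which mirrors the dominant deformation of the
  planted states (native-like N-strand whose pairing is broken) and
  gives the aggregation generator a well-defined N-terminal docking
  edge. Blend factors are solved by bracket/bisection on the measured
  RMSD to within 0.15 Å (acceptance band 0.75 Å); unreachable targets
  are an error, not a silent clamp. Decoration is geometric: bond
  lengths in blended regions are not physical, energies are undefined,
  and no claim about real DS119 conformers follows from it — what
  passing tests show is that the *analysis chain* recovers what was
  planted.
* **Dimer scripts.** Two decorated chains; a search phase (≥ 10 Å
  apart), a linear approach, and a bound phase in which chain B is
  docked against chain A by antiparallel (or parallel, whichever
  engages more residues) apposition of the scripted interface segments,
  with the roll about the near-collinear segment axis scanned
  explicitly and the pose settled to a 2.2 Å closest approach — chosen
  so that all six interface residues sit inside the 4.5 Å contact
  shell. Per-frame Cartesian noise (0.12 Å) provides thermal jitter;
  an optional slow rocking of the bound pose is available but off by
  default because a static pose keeps the contact count stationary,
  which is what the flat-stage detector's slope tolerance assumes. The
  default campaign: eight runs, binding times 30–750 ns, six with the
  5–10 N-terminal interface, one helix-face (16–21), one never-binding.

## Problem sizes

The default analyses are sized for a single CPU: 60 000 sampled points
for the five-state monomer landscape (0.25 Å bins), 10⁵ samples for
the two-well calibration, 100 decorated frames per basin for contact
maps, and eight 1 200 ns scripted dimer runs at 2 ns frame spacing.
The decorated-ensemble recovery property is exercised at 6 000 frames
with its tolerance widened from the 10⁵-sample figure by the
corresponding √n factor.

## Known limitations

* The mock reference is idealised; its absolute SASA/Rg values are
  plausible but not experimental. Real reference models drop in via
  `read_pdb()`.
* The landscape estimator treats each temperature independently; no
  multi-temperature reweighting (WHAM/MBAR) is provided.
* Secondary structure is limited to H/E/C.
* The minimax barrier on a sampled surface is biased slightly low
  (noise-seeking); the calibration quantifies the size of the effect.
* Binary trajectory formats (DCD/XTC) are not read; multi-model PDB and
  extended XYZ are the exchange formats, with the reader/writer pair
  round-trip tested.
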