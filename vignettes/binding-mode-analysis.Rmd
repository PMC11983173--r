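---
title: "Binding-mode analysis of protein-ligand MD trajectories with mdmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode analysis of protein-ligand MD trajectories with mdmodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmodes)
```

## The analysis problem

A protein-ligand molecular-dynamics trajectory samples, over microseconds,
a handful of recurring binding arrangements — *binding modes* — plus the
thermal motion around each of them. Questions a modeller asks of such a
trajectory are: how many distinct modes were visited and with what
populations; which receptor-ligand and intra-receptor hydrogen bonds
persist; what binding energy should be reported when the ligand does not
sit in a single pose; and, for enhanced-sampling (metadynamics) runs,
where the free-energy minima lie along the chosen collective variables.
`mdmodes` implements this analysis chain as composable pieces, each
testable in isolation against planted ground truth.

## The clustering model

Frames sampled from the trajectory (optionally at a stride coarser than
the storage interval, via `sampleFrames()`, to reduce short-term
correlation) are described by a small set of geometric descriptors
(`buildFeatures()`):

* center-of-mass distance between the ligand and each named pocket
  residue (one column per residue, Angstrom);
* RMSD of the protein backbone (atoms N, CA, C, O) relative to the
  reference frame;
* RMSD of the ligand after superposing each frame on the backbone
  (the fit is *not* repeated on the ligand, so this measures ligand
  motion within the receptor frame);
* RMSD of the user-named interacting residues.

All RMSDs use a Kabsch least-squares superposition. The reference
structure defaults to the first frame; which residues count as
"interacting" is system knowledge the caller must supply — the package
deliberately has no heuristic for it.

Each column is standardized to mean 0 and standard deviation 1
(population denominator). Constant columns carry no information and are
dropped with a warning rather than dividing by zero. PCA
(`pcaReduce()`) then keeps the smallest number of components whose
cumulative explained variance reaches the target fraction (default
0.90); component signs follow the convention that the largest-magnitude
loading is positive, so scores are reproducible.

K-means++ (`kscan()`) is run for every k in 2..10, `n_init = 10`
restarts each, keeping the restart with the lowest within-cluster sum
of squares (WSS). Four internal validation indices score each k:

* **SI** — mean silhouette width;
* **DI** — Dunn index, the minimum inter-cluster point distance over
  the maximum intra-cluster diameter;
* **pSF** — Calinski-Harabasz pseudo-F, `(B/(k-1)) / (W/(n-k))`;
* **WSS** — the elbow criterion.

`selectK()` lets SI, DI and pSF vote for their argmax and WSS for its
elbow, and returns any k winning at least three of the four votes. The
elbow is operationalized as the k with the largest positive second
difference of WSS — the sharpest change of slope — because "look for
the kink" needs a concrete rule before it can be tested. When no k
collects three votes the k with the most votes wins, ties broken toward
smaller k: parsimony is the only defensible default when the indices
genuinely disagree. The vote and decision path are attached to the
result, so a pipeline never silently hides an ambiguous selection.

`fitModel()` reports clusters ordered by population: W% (percent of
frames, rounded to integers for display — rounded values need not sum
to exactly 100) and the *centroid frame*, the sampled frame nearest in
reduced space to the cluster mean. The unrounded fractions are kept and
are what the energy aggregation uses.

## Hydrogen-bond networks

`detectHBonds()` applies the standard geometric criterion:
donor-acceptor heavy-atom (N/O) distance at most 3.5 Angstrom and
donor-H-acceptor angle at least 150 degrees, for some hydrogen bonded
to the donor — hence explicit hydrogens are required, and their absence
is an error rather than a silent empty result. Arg/Lys/His side-chain
nitrogens paired with Asp/Glu side-chain oxygens within 4.0 Angstrom
are additionally reported as class `salt_bridge` (no angle condition),
with the basic residue named first so the pair key is canonical.

Occupancy (`occupancy()`) is the percentage of analysed frames in
which a residue pair satisfies the criterion; aggregation is at
residue-pair level (a pair is present in a frame when *any* of its atom
pairs qualifies), because that is the level at which interaction
networks are compared across systems. Sub-threshold occupancies are
tracked continuously; the stability threshold (default 60%,
*inclusive*, since an interaction present in exactly 60% of frames is
not meaningfully different from one at 60.01%) is applied only at
reporting time by `stableInteractions()`. `compareNetworks()` splits
stable interactions into a shared core and per-system differential
sets, printing `"NOB"` (not observed) for pairs a system never formed.

## Binding-energy aggregation

The package never computes molecular-mechanics, DFT or neural-network
potential energies itself: those come from external scorers as
per-structure tables (`readEnergyTable()`). What it owns is the
arithmetic around them:

* `bindingEnergy()` — the end-point difference
  `dG_b = G_complex - G_ligand - G_receptor` (kcal/mol), more negative
  meaning stronger predicted binding;
* `rescoreMlAni()` — the linear two-backend combination
  `alpha * dG_DFT + beta * dG_ANI + gamma`, whose coefficients are
  external calibration output and therefore *require* a provenance
  note; the default `(1, 0, 0)` passes the first backend through;
* `weightedAverage()` — the cluster-weighted mean of per-centroid
  energies using the unrounded cluster fractions, so heavily populated
  modes dominate the reported value. Exact fractions (not the rounded
  display W%) are used, since rounding error would otherwise leak into
  an energy.

## Metadynamics post-processing

`fesFromHills()` reconstructs a free-energy surface as the negative of
the summed Gaussian bias. For well-tempered runs the deposited bias
underestimates the free energy by the factor `(T + dT)/dT`; supplying
`bias_factor` (gamma = (T + dT)/T, a *required* input whenever scaling
is wanted, because it cannot be inferred from a hill log) applies the
`gamma/(gamma - 1)` rescale. Surfaces are normalized to minimum 0.
`averageFes()` takes the cell-wise mean over replicas and
re-normalizes; averaging then normalizing differs from normalizing then
averaging only by a constant, which normalization removes.

`findMinima()` reports strict local minima (2-connected in 1-D,
8-connected in 2-D) whose basin prominence — the lowest rim level at
which the basin merges into a deeper one, found by a flooding pass —
is at least `depth_cut` (default 0.5 kcal/mol; shallower dimples are
indistinguishable from deposition noise). Basins are labelled A, B,
C, ... purely by increasing free energy; no geometric identity is
claimed for a label. Exact value ties on adjacent cells form a plateau
and are not strict minima; on real (noisy) surfaces ties have measure
zero, and the tests construct their grids to avoid them.

`hillConvergence()` monitors the well-tempered signature that hill
heights decay as minima flood: it reports windowed mean heights, a
Kendall-type pairwise-sign trend statistic in [-1, 1] (strictly
decreasing window means give -1, flat gives 0), and a `converging`
flag when the last window falls below half the first (configurable).

## The synthetic generator: what it emulates, and what it does not

`generateSystem()` builds a ground-truthed toy: an idealised helical
receptor (4 backbone atoms per residue), a rigid ring-shaped ligand,
and planted structure at every level the pipeline measures:

* **Binding modes.** The ligand occupies one of up to five planted
  poses per frame. Mode visits are contiguous blocks of at least
  `min_dwell` frames (exact per-mode frame counts, so the planted
  fractions are honoured exactly), mimicking metastability rather than
  i.i.d. shuffling. Displacement directions are radial/axial with
  respect to the helix — tangential moves would alter ligand-residue
  distances only to second order — with near-equal pairwise pose
  distances whose minimum equals `mode_separation`.
* **Receptor response.** Pocket residues follow a fraction
  (`induced_fit`, default 0.3) of the ligand displacement, which is
  what makes the RMSD descriptors informative, as in real induced-fit
  binding. The N- and C-terminal quarters swing slowly about a hinge
  (`tail_flex`, default 0.8 Angstrom, AR(1) with lag correlation 0.9),
  reproducing the enhanced terminal mobility real RMSF profiles show.
  Without such slow internal motion a rigid toy receptor produces a
  pathological feature column: the backbone RMSD of every frame sits
  at a sharp white-noise floor and the reference frame becomes an
  isolated many-sigma outlier — an artifact of white-noise toys that
  real, time-correlated trajectories do not have.
* **Thermal noise.** Per-coordinate jitter is AR(1) in time
  (`noise_rho`, default 0.6): stored MD frames are short-term
  correlated — the very reason stride sampling exists.
* **Hydrogen bonds.** Scheduled donor-H-acceptor triples are placed
  exactly on (2.9 Angstrom, linear) or off (5.5 Angstrom) the
  criterion per frame, with exact-count random schedules, so realised
  occupancies match targets to within one frame. These atoms are
  exempt from jitter; blurring the criterion geometry would turn an
  exactness test into a statistical one.
* **Bookkeeping realism.** The whole complex undergoes a rigid-body
  random walk (translation + rotation), which every descriptor must
  ignore; emitted files are real PDB and DCD, so tests exercise the
  actual parsers.

What the toy does *not* emulate: force-field physics, solvent, real
protein geometry, rugged within-mode energy landscapes, slow
mode-mixing, or atom-count scales beyond a few hundred. Passing the
planted-recovery tests therefore demonstrates that the pipeline
recovers structure *of the kind it assumes* — well-separated metastable
modes — not that it would resolve marginally separated modes in a real
system. The `toyWalker()` companion provides the metadynamics oracle:
overdamped Langevin dynamics on an analytic double well with
well-tempered deposition (initial height 0.4 kcal/mol, width 0.2
Angstrom — standard deposition settings), whose exact barrier the FES
reconstruction must recover.

## Numerical and design choices

* Units are Angstrom, picoseconds and kcal/mol throughout; formats are
  converted on read. Frame indices are 1-based in R fashion; reports
  carry simulation times.
* The sampling stride is a configuration parameter defaulting to the
  trajectory's native storage interval — analyses are reported at the
  stride actually achievable, never at an assumed constant.
* Superposition requires at least 3 non-collinear atoms; the rotation
  is always a proper rotation (determinant +1).
* SASA uses Shrake-Rupley with Bondi radii, probe 1.4 Angstrom and 960
  near-uniform (golden-spiral) sphere points; the operation takes an
  explicit selection and reports for that group in isolation, since
  "SASA of the system" is ambiguous between protein, ligand and
  complex. Coincident atoms of equal radius count once.
* RMSF superposes all frames once more onto the first-pass mean
  structure (one iteration) before measuring fluctuations about the
  time-averaged positions.
* K-means++ restarts default to 10 per k, best-of by WSS; every stage
  of the pipeline is deterministic given its seed.
* The k-scan reports all per-k index values; a report always shows all
  k weights of the fitted model, whether or not they sum to a round
  number after integer rounding.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run entirely on synthetic
systems sized for quick, repeatable verification: receptors of 10-24
residues, trajectories of 50-1000 frames, 10 independent seeds for the
end-to-end recovery check, 100 random pairs for the superposition
oracle, 1500 hills for the walker. These sizes were chosen so each
statistical check has comfortable resolution (e.g. occupancy exact to
0.1% at 1000 frames) while a full run stays interactive.

## Known limitations

* XTC trajectories are not read (no R-native reader); DCD and
  multi-model PDB are supported. Convert XTC upstream.
* Periodic-boundary effects are not handled: trajectories are assumed
  whole-molecule and un-imaged.
* The hydrogen-bond criterion requires explicit hydrogens; topologies
  without them fail loudly rather than approximating with
  heavy-atom-only geometry.
* Ligand RMSD is not symmetry-corrected; chemically equivalent atom
  relabellings will inflate it.
* `findMinima()` labels basins by depth only; tracking a basin's
  identity across systems is the caller's interpretation.
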