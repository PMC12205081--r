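---
title: "thermolock: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermolock: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermolock` is a desk-scale pipeline for studying how a disordered,
phase-separating protein domain can sense heat through a breakable
intramolecular β-strand "lock".  The biological picture it emulates:
a prion-like domain (PrLD) rich in aromatic stickers shows
lower-critical-solution-temperature (LCST) phase behaviour — heating
*promotes* condensation — and carries two short sequence segments that
pair into an intramolecular β-strand at low temperature, occluding the
interactions needed for condensation until heat melts the lock.  The
package provides (i) a coarse-grained polymer simulator that generates
conformational ensembles with these properties, (ii) the trajectory
metric suite used to diagnose them, (iii) the Δcontact / lock-detection
inference, (iv) a forward FRET-lifetime predictor, and (v) the
label-free proteomics enrichment statistics used for interactome
mapping, with planted-truth generators throughout.

## 1. The coarse-grained polymer model

Each residue is two beads: a backbone bead (radius 0.125 nm) and a
side-chain bead (radius 0.225 nm) joined by stiff harmonic bonds
(backbone bond 0.38 nm, side-chain bond 0.30 nm, k = 500 kJ/mol/nm²)
with a soft backbone angle term (θ₀ = 120°, k = 2 kJ/mol/rad²).  One or
two chains live in a periodic 7 nm cube and all distances use the
minimum image.  Energies are in kJ/mol, temperatures in K, and
k_B = 0.0083144621 kJ/(mol·K); the Monte Carlo sweep is the unit of
"time" (an all-atom nanosecond has no meaningful coarse-grained
equivalent).

Four residue categories — aromatic `sticker`, `hydrophobic_spacer`,
`polar_spacer`, `flexible` — carry attraction well depths (defaults
5.0, 2.8, 1.0, 0.5 kJ/mol).  Side-chain beads at sequence separation
≥ 2 (or on different chains) attract through a truncated-shifted
Lennard-Jones well of depth `sqrt(eps_i * eps_j)`; all other bead
pairs are purely repulsive (WCA).

**LCST encoding.**  Without explicit water the entropic driving force
of LCST behaviour must be made explicit: for sticker and hydrophobic
pairs the well depth is scaled by `1 + α (T − T_ref)/T_ref` with
α = 5 and T_ref = 298 K, so the chain is *more* sticky when hot.  This
term produces the compaction-on-heating (falling Rg and SASA, rising
contacts) and the increase of intermolecular contacts in two-chain
runs that characterise LCST domains.

**Transient backbone hydrogen bonds.**  Backbone beads of residues at
sequence separation ≥ 3 (or on different chains) share a weak
isotropic Gaussian well (minimum 0.30 nm, width 0.06 nm, nominal depth
3.5 kJ/mol) carrying the same LCST factor: dehydration of the
collapsing chain strengthens effective backbone hydrogen bonding.
Counted hydrogen bonds (the 0.35 nm / 30° rule on the pseudo-amide
geometry below) therefore rise with heating, through compaction and
through the well itself.

**Pseudo-amide geometry.**  Each residue's amide axis is the cross
product of its local backbone tangent and its side-chain direction.
In a β-strand whose side chains stand perpendicular to the sheet this
axis lies in the sheet plane pointing at the partner strand on either
side — exactly how backbone N–H and C=O point both ways out of a
strand.  The hydrogen-bond detection convention places donor and
acceptor on the backbone bead with pseudo-hydrogens 0.1 nm out along
both directions of this axis.

**The lock.**  A `lock_spec` plants an antiparallel registry
(25↔82 … 30↔77 by default) with three energetic ingredients modelling
a real β-hairpin:

* the *core ladder* — a directional well between the paired residues'
  backbone beads (Gaussian minimum 0.34 nm, width 0.05 nm, modulated
  by the squared alignment of both amide axes with the pair
  direction), of temperature-independent (enthalpic) depth
  `epsilon_lock` = 15 kJ/mol per pair;
* *cross-strand side-chain packing* — Gaussian wells (minimum 0.5 nm)
  between the registry pairs' side-chain beads and their diagonals,
  nominal depth 5 kJ/mol, which give the paired segments the dense
  mutual side-chain contacts a sheet shows;
* a weak *zipper extension* of the register towards the chain ends
  (pairs (i, 107−i) for i = 17…24), nominal depth 0.65 ×
  `epsilon_lock`, through which the folded hairpin tethers the chain
  termini.

The packing and zipper terms are polar, hydrogen-bonded, solvent-
exposed contacts: enthalpy-dominated, so their strength falls with
temperature as `1 − α_enth (T − T_ref)/T_ref` (floored at 0) with a
steep `enthalpic_alpha` = 16 — by 310 K they retain about a third of
their reference strength and by 316 K essentially none.  Lock opening
on heating therefore emerges from the melting of these enthalpic
flank terms combined with the falling βε of the fixed core and the
LCST-growing sticker/backbone melt that competes for the segments.
The calibration targets used when freezing these constants were a
predominantly formed wild-type lock at 280 K and a predominantly open
one at 310 K, together with the qualitative Rg/SASA/contact/H-bond
temperature trends; the constants live in the presets and the energy
model and are configurable.

**Presets** (`build_preset()`): `wt` (stickers on a regular 6-residue
grid inset from the termini, with aromatics at 27 and 78 inside the
lock segments and at 84 next to the zipper), `y_to_s` (sticker depths
lowered to the polar-spacer level; lock retained), `m1` / `m2` (four
alanine-like substitutions in the first or second lock segment;
`epsilon_lock = 0`, so packing and zipper are inactive too), and
`no_lock_homopolymer`.  The true domain sequence is not public; the
presets encode positional information only (sticker spacing, lock
registry, mutated positions).

## 2. Sampling

`mc_sweep()` runs Metropolis Monte Carlo: one sweep attempts
`n_beads` moves drawn from local bead displacements (80%, Gaussian
σ = 0.06 nm), crankshaft rotations of short internal backbone windows
(10%) and pivots of the shorter chain end (10%).  Non-finite proposals
are rejected.  `run_remd()` runs one replica per ladder rung
(default 8 rungs, 280–316 K, geometric spacing) with nearest-neighbour
configuration swaps attempted every 20 sweeps on alternating even/odd
pairs.  Because the Hamiltonian is temperature-dependent (the LCST
scaling), swaps use the general two-sided criterion
`min(1, exp(−β_i[E(x_j;T_i)−E(x_i;T_i)] − β_j[E(x_i;T_j)−E(x_j;T_j)]))`,
which reduces to the familiar `min(1, exp((β_i−β_j)(E_i−E_j)))` when
the energies are temperature-independent.  Swaps use potential energy
only: the box is fixed, so there is no pressure–volume term.

The starting structure mimics a folded structure-prediction model: the
chain is laid out as a compact serpentine and relaxed for 800 sweeps
under temporary harmonic restraints that bring the full hairpin (core
registry plus zipper extension) together (also for the lock-dead
mutants, which therefore *start* locked and relax open — the same
discard logic the source experiment applied to its predicted starting
structures).  The leading 20% of frames is excluded from every
ensemble average, mirroring the usual discard of the first fifth of a
sampling run.

## 3. Trajectory metrics

All conventions live in one `analysis_config()` object:

* side-chain contact: minimum distance between the residues'
  side-chain beads (or side-chain heavy atoms for all-atom input)
  below **0.6 nm**, with intramolecular pairs at sequence separation
  |i−j| ≤ **3** excluded ("ignored between three adjacent residues"
  read inclusively; the config exposes the alternative);
* hydrogen bond: acceptor–donor distance within **0.35 nm** and
  acceptor–donor–hydrogen angle (vertex at the donor) strictly below
  **30°**; each D–H…A triple counted once; for the coarse-grained
  model, intramolecular pseudo-site bonds additionally require
  sequence separation ≥ 3 (adjacent pseudo-sites are artifacts of the
  two-bead resolution);
* SASA: Shrake–Rupley with a 0.14 nm probe and 960 deterministic
  golden-spiral points per sphere (≈ 1% accuracy on an isolated
  sphere);
* β-strand: a residue is strand in a frame when it takes part in two
  consecutive inter-segment hydrogen bonds (a parallel or antiparallel
  ladder) *and* its local backbone is extended (backbone pseudo-angle
  ≥ 100°).  This ladder rule is the coarse-grained stand-in for a
  hydrogen-bond-pattern (DSSP-like) assignment, which is undefined
  without backbone carbonyls.  Because the core-ladder well minimum
  (0.34 nm) sits near the 0.35 nm detection cutoff, a bound pair is
  detected only part of the time; coarse-grained strand probabilities
  are therefore systematically lower than atomistic ones.

Ensemble aggregation (`ensemble_average()`, `metric_series()`)
discards the equilibration fraction and reports a block-bootstrap
standard error (10 contiguous blocks, 200 resamples) — chosen because
Monte Carlo series are autocorrelated and naive standard errors would
be anticonservative.

## 4. Thermo-switch inference

`delta_contact_profile()` is the per-residue summed contact-frequency
change between a low and a high rung; its confidence band is a frame
block bootstrap.  `detect_lock()` formalises the visual diagnosis of a
lock as three criteria: (1) runs of ≥ `min_run = 3` consecutive
residues losing contacts (`delta_threshold = 0`: any net loss) while
the chain-wide mean gains; (2) the candidate segment pair shows a
cross-segment residue pair in persistent contact at the low
temperature (peak cross-pair frequency ≥ `contact_floor`; the peak
rather than the block mean, because backbone-paired strands touch
through a few persistent side-chain pairs, not uniformly); (3) the
mean β-strand probability of both segments drops by ≥
`strand_drop = 0.05` on heating (small because coarse-grained strand
probabilities are compressed; see above).  The thresholds are
constants of the detector, tuned once against the synthetic generator
and stored in the call.

`rg_trend()` classifies the ladder trend of mean Rg by the Spearman
correlation with temperature and a block-bootstrap CI (decreasing /
increasing / flat).

## 5. Forward FRET model

With donor and acceptor fused to the termini, each frame's transfer
efficiency is `E = 1/(1 + (r/R0)^6)` from the terminus–terminus
distance; the predicted mean donor lifetime is `τ_D (1 − ⟨E⟩)` under a
static-frame assumption (each conformation contributes an independent
quenching environment; no photon simulation, no instrument-response
convolution — those are instrument-level concerns).  Defaults
R0 = 5.4 nm and τ_D = 2.6 ns are representative literature constants
for a GFP–mCherry pair; both are configurable.  Predictions are
validated by *ordering* across presets and temperatures only, never by
absolute nanoseconds: the zipped cold hairpin tethers the two termini
(short lifetime), while the lock-dead mutants leave them free when
cold (long lifetime) and collapse on heating (strongly reduced
lifetime, i.e. a much smaller — in fact negative — heating response
than any locked construct).  A caveat is discussed under
*Limitations*: in a single-chain model the heat-opened state is also
the LCST-collapsed state, so the wild type's own heating response sits
near zero and its sign is not reliably reproduced.

## 6. Proteomics enrichment statistics

`top3_protein_area()` implements top-3 label-free quantification: per
protein and *per replicate*, the mean of the three largest observed
peptide areas (all peptides when fewer than three).  The alternative
reading — top-3 selected on replicate-averaged peptide areas — is not
the default because replicate-wise selection is how the quantification
is described per replicate; the peptide-level input format keeps both
computable.  `impute_missing()` replaces every missing protein-level
cell with one constant, the mean of the per-replicate-column minima
(imputation at protein level, after quantification, before fold
change).  The proximity-labeling arm calls enrichment at
log2 fold change ≥ 1; the IP-MS arm runs an empirical-Bayes moderated
t-test on log2 areas (the transform is not stated in the source
protocol; log2 is the field convention) with the scaled
inverse-chi-square prior fitted by the method of moments on the log
sample variances, Benjamini–Hochberg adjustment, and the call rule
adjusted p < 0.05 *and* log2FC ≥ 1.  Proteins observed only in the
bait are retained (imputation guarantees a finite fold change).

`simulate_proteome()` plants truth: log-normal protein abundances
(log2 SD 1.5 across proteins), per-peptide response factors (log2 SD
1), replicate noise of log2 SD `sigma`, a planted enriched subset at a
fixed log2 effect, and missingness that is either intensity-dependent
(`MNAR-low`, a logistic in the abundance rank — the dominant mechanism
in label-free MS) or completely at random.  What it does *not*
emulate: shared/razor peptides, chimeric identifications,
batch/run-order drift, or correlated peptide noise — so passing
recovery tests demonstrates correctness of the statistics, not
robustness to every artefact of real MS data.

## 7. Numerical choices and degenerate inputs

* Minimum-image convention in every distance; coordinates are kept
  unwrapped so rigid-segment rotations remain exact.
* Energy bookkeeping is incremental per move but refreshed from a full
  recomputation at every recorded frame, so stored frame energies are
  exactly recomputable.
* Metropolis proposals with non-finite energy change are rejected.
* `ensemble_average()` refuses fewer retained frames than blocks;
  constant series give SE 0.
* In `moderated_test()`, proteins with zero pooled variance under a
  degenerate (constant) table fall back to t = 0 / p = 1 when the
  effect is zero; if no positive variances exist the prior scale
  degenerates gracefully.
* `trend_report()` maps an all-tied Spearman correlation to 0
  ("flat").
* Replicate columns that are entirely missing make imputation
  impossible and raise an error rather than guessing.

## 8. Problem sizes

The package's own test and acceptance runs use deliberately small
problems chosen to sample the phenomena adequately at desk scale: an
8-rung ladder over 280–316 K with 3,500–5,000 sweeps per replica for
trend checks; 280 K / 310 K single-temperature pairs of 2,000–4,000
sweeps for the seed batteries; two-chain boxes of 5,000–8,000 sweeps
(averaged over several independent runs in the reproduction script,
because the association of one chain pair is a rare, near-irreversible
event); and proteome simulations of 1,000–2,000 proteins with 4 + 4
replicates over 20 seeds.  These sizes are stated in
`scripts/acceptance.R` and the tests; all are configuration, not
constants of the methods.

## 9. Known limitations

* The simulator is a stand-in generator, not a force field: its
  constants are calibrated to reproduce the qualitative phenomenology
  (LCST compaction, breakable lock, sticker multivalency), and no
  quantitative claim about the real domain's energetics follows from
  it.
* Two coarse-graining compromises are documented rather than hidden.
  First, the contact count of a two-strand CG sheet saturates near
  three partners per residue, while a collapsed CG globule reaches a
  similar density; the per-residue contact *loss* of the lock segments
  on heating is therefore a weak, noisy signature, and
  `detect_lock()`'s recovery of the exact planted boundaries from
  simulated (as opposed to constructed) ensembles is unreliable even
  though the detector itself is exact on geometric fixtures.  Second,
  with donor and acceptor on the termini of a single chain, the
  heat-opened state is simultaneously the LCST-collapsed state, so
  the wild-type donor lifetime's heating response is near zero: the
  mutant-versus-wild-type orderings are robust, the wild type's own
  heating sign is not.
* Lock opening/closing is a rare event at the locked/open boundary;
  short runs rely on the prepared locked start plus the equilibration
  discard, and per-run occupancies are kinetically, not only
  thermodynamically, controlled — exactly as in the short all-atom
  sampling the design mirrors.
* The β-strand rule on coarse-grained input detects only the ladder
  geometry the model can express; it is not a secondary-structure
  assignment of atomic detail.
* XTC trajectories are not readable (no installed reader); multi-model
  PDB and DCD+PDB are supported.
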