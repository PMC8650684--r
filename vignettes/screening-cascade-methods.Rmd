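---
title: "The screening cascade: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The screening cascade: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vscascade)
```

Virtual screening trades accuracy for throughput in stages: a cheap
conformation-free classifier prunes a large library, docking and a
pose-aware classifier re-score the survivors, hard thresholds produce a
candidate list, and molecular-dynamics follow-up examines the shortlist.
This vignette documents how each stage is modelled here, which parameters
matter, what the synthetic generators do and do not emulate, and the
numerical choices a maintainer would want stated.

## Stage 1: substructure sentences and the pair-vector classifier

**Sentences.** A molecule is parsed (openbabel, after canonicalization,
so atom order is a property of the molecule rather than of its SMILES
spelling) and every heavy atom contributes one identifier per radius
0..R. The radius-0 identifier hashes (element, heavy degree, bond-order
sum); radius r hashes the radius-(r−1) identifier together with the
sorted (bond order, neighbour identifier) pairs — the usual circular
(Morgan) refinement. Identifiers are 32-bit FNV-1a hashes, so sentences
are deterministic across platforms. Default radius: 1 for embedding
sentences, 2 for the 2048-bit clustering fingerprints.

**Pocket sentences.** A binding pocket (all residues with any heavy atom
within 1.0 nm of the reference ligand, boundary inclusive, hydrogens
ignored) is treated as a set of disconnected residue fragments of one
molecular graph: bonds are inferred within a residue below 1.9 Å, never
between residues, and per-residue sentences are concatenated in residue
order. Atom-level fragments keep the representation independent of any
residue-type dictionary.

**Embedding.** A compact skip-gram with negative sampling, written in the
package (vectorised minibatch SGD, linearly decayed learning rate,
unigram^0.75 noise distribution), trains token vectors on the screening
corpus itself. Defaults: dim 100, window 10, min_count 1, 5 negatives,
5 epochs, all configurable. These are desk-scale settings — the classic
substructure-embedding setup used larger corpora and dimensions; nothing
downstream depends on more than distinct, stable directions per token.
Out-of-vocabulary tokens map to the zero vector so unknown substructures
contribute nothing rather than noise. Training is single-threaded and
seeded; the same corpus and seed reproduce the same vectors exactly.

**Pair vectors.** A pocket–ligand pair is `concat(sum of pocket token
vectors, sum of ligand token vectors)`, z-normalized per dimension with
the **training-set** mean and standard deviation (test data reuses the
training statistics; the deviation is floored at 1e-8 so constant
dimensions do not blow up).

**Classifier.** A dense fully connected network — default hidden widths
512/256/128/64, ReLU, sigmoid output, binary cross-entropy, Adam
(lr 1e-3, batch 128) — maps the pair vector to a binding probability.
Depth and widths are declared defaults, not inferred from anything;
training is deterministic given a seed. Negative pairs come from
cross-combination: pocket i with ligand j ≠ i, excluding any ligand
identical (by canonical key) to pocket i's cognate ligand, sampled
uniformly without replacement at a configurable negatives-per-positive
ratio.

## Stage 2: docking

The docking adapter writes and reads the standard config dialect
(receptor/ligand paths, box centre and size, exhaustiveness, num_modes,
energy_range) and parses the result table of a docking log. Defaults are
the common cascade settings: a cubic box of 2.5 nm per side centred on
the pocket mass centre (the unweighted mean of pocket heavy-atom
coordinates — no mass weighting, since nothing downstream is sensitive
to the few-percent difference), exhaustiveness 8, 20 modes, energy range
3 kcal/mol. Internally everything is Angstrom; pocket cutoffs and box
sizes are accepted in nm and converted (1 nm = 10 Å).

The **mock engine** is the test and demo default so no docking binary is
ever required. Its score is documented and seeded: best affinity
−(2 + 0.12 · n_heavy) kcal/mol plus a reproducible per-(receptor,
ligand, seed) jitter (σ = 0.5), with worse modes spread inside the energy
range; poses are rigid translations of the input ligand to uniform
points in the box, with the sampling range shrunk by the ligand's extent
so every atom stays inside. It reproduces the *shape* of docking output,
not its physics.

## Stage 3: interface maps and the pose classifier

A pose is encoded as a fixed-size matrix: one row per (protein heavy
atom, ligand heavy atom) pair within 10 Å, rows sorted ascending by
distance (ties broken by protein then ligand atom index), truncated to
the 256 closest contacts and zero-padded below. Each row is a one-hot
protein element over {C, N, O, S, P, halogens, other}, the same one-hot
for the ligand element, and distance/cutoff in [0, 1]. This layout is
versioned ("v1") and stored on trained models; it is a declared encoding,
chosen for being order-canonical and shape-stable.

The classifier is a residual dense network: an entry projection to a
32-wide trunk, four blocks of dense–ReLU–dense with an **identity skip
connection** (then ReLU), and a sigmoid head. Residual blocks rather
than convolutions: at desk scale the map's row ordering already encodes
the spatial structure a convolution would have to learn, and dense
blocks keep the numerical code small while preserving the
skip-connection design; depth and width are configurable.

Decoy poses for training come from cross-docking: each receptor docks
the ligands of other complexes (mock engine by default), the
best-scoring pose per pair is kept, and a receptor's own ligand — or an
identical ligand from another complex — is never its decoy.

## The threshold cascade and clustering

`apply_criteria()` keeps a record iff `deepbindbc > a` **and**
`docking <= b` **and** `dfcnn > c`, with optional name exclusions:
strict inequalities for the two probabilities, inclusive for docking, on
the values exactly as given (no rounding). The operator convention
matters at boundaries — a record docking exactly at the bound is kept —
and the packaged 24-compound table exercises exactly that case. Three
named presets ship: `list1` (0.99 / −10 / 0.99), `list2`
(0.99 / −8.5 / 0.998) and `tcm` (0.9 / −6 / 0.9). Ranking is a stable
sort (ties keep input order).

Candidates are clustered with 2048-bit hashed circular fingerprints
(radius 2), Tanimoto similarity and leader/Butina clustering at a 0.6
default threshold: the unassigned molecule with the most unassigned
neighbours becomes a centroid and claims them, ties broken by input
order, so the partition is deterministic. The number of clusters is an
outcome of the threshold, never a target. Cluster representatives follow
the highest interface score when a score table is supplied.

## Enrichment

For scores with activity labels, `Ratio_c = (N_c/N_total)/(NN_c/N_all)`
with strict `>` at the cutoff c (default 0.9). No pseudocounts: when
nothing scores above the cutoff the random rate is zero and the function
raises an error rather than smoothing, because the statistic defines
none. AUC is the rank-based (Mann–Whitney) form with ties counting one
half.

## MD and metadynamics post-analysis

**RMSD.** Each frame is least-squares superposed on the reference over a
fit selection (bio3d's Kabsch-style fit), then the RMSD is measured over
a second selection. The package convention for binding stability:
superpose on protein C-alphas, measure the ligand — this separates
ligand motion from global tumbling. The suite checks the result against
an independent quaternion (Horn) superposition oracle to 1e-9.

**Hydrogen bonds.** Geometric criterion, counted per frame over
(donor, hydrogen, acceptor) triples: D···A ≤ 3.5 Å and D–H···A ≥ 130°,
both configurable. The 3.5 Å / 130° default is a standard moderate
criterion chosen once for this package; published analyses vary between
120° and 150° cutoffs, and no attempt is made to match any particular
engine's default.

**Free-energy surfaces.** From a hills log (time, centre, width, height
per deposited Gaussian), `F(s) = −Σ h_k exp(−(s−s_k)²/2σ_k²)` on a grid
(default 512 points spanning the hill centres ± 3 σ_max), optionally
shifted so min F = 0. The reconstruction is CV-agnostic and 1D.
Well-tempered rescaling (ΔT/(ΔT+T)) is deliberately not applied by
default because the bias variant behind a given hills file is not
recoverable from the file itself; the negated-bias sum is the plain
metadynamics estimator.

**Stability ranking** orders candidates ascending by mean measured RMSD
and returns the top k.

## The synthetic generators

`generate_planted_library()` emulates a screening corpus with a knowable
answer. Each pocket carries a key token; a ligand binds iff it contains
the complementary key token; labels equal that rule flipped with
probability (1 − signal_strength)/2, so signal 1 is noiseless and signal
0 makes labels pure coin flips. Defaults: 20 pockets × 100 ligands
(2,000 pairs), signal 0.9, 8 key classes, 10-token ligand sentences over
a 60-token filler alphabet, and a **binder rate of 0.1**. The binder
rate is deliberately low: screening libraries contain few true actives,
and the enrichment ratio is only informative in that regime — with
abundant actives its ceiling (1/active-fraction) collapses toward 1.
Non-binders mostly carry the key of a *different* pocket class (70%) so
the classifier must learn the pocket–ligand match, not mere key-token
presence.

Recovery is evaluated **against the planted rule**, training on the
noisy labels. The label noise is a model of annotation error in training
data; measuring held-out AUC against those same noisy labels would cap
any classifier at the noise ceiling (≈ 0.84 at these settings) and test
the noise level, not the method. At the default conditions (seed 7) the
measured recovery is AUC ≈ 0.99 with Ratio_0.9 ≈ 7–12, and a
permuted-label control sits at AUC ≈ 0.5.

`generate_complex_set()` builds toy 3D complexes: a spherical shell of
pseudo-residues (radius ≈ 8 Å) around a compact interior ligand, so
native interfaces have many short contacts while mock-docked poses land
elsewhere in the 25 Å box and make sparse, long-range maps. The
interface classifier's job on this data — compact vs displaced — is the
geometric essence of native-vs-decoy discrimination, nothing more: no
chemistry, no induced fit, no near-native decoys. Passing it shows the
featurization and classifier machinery work, not that real decoy
discrimination is solved at this scale.

`generate_trajectory()` produces a near-rigid 22-atom pseudo-protein
(helix of 20 C-alphas plus an N–H donor) and a 5-atom ligand whose
acceptor oxygen starts in a formed, linear hydrogen bond (D···A 2.8 Å).
Stable trajectories jitter the ligand isotropically (default σ 0.3 Å,
protein at one sixth of that, so noise 0 reproduces the reference
exactly); drifting ones add a cumulative drift (default 0.1 Å/frame) in
a fixed random direction, giving a closed-form expected final
displacement of drift × (n_frames − 1). In the synthetic end-to-end
pipeline, binders keep their native pose (and receive a fixed −2
kcal/mol docking offset) while non-binders take the best mock-docked
pose — the generator's statement that true binders dock better and sit
still, which is the premise, not a finding, of the demo.

What the generators do **not** emulate: real chemistry of either side,
affinity scales, correlated pose ensembles, water, or any force-field
physics. Green tests on synthetic data validate the pipeline's
contracts and statistics, not screening performance on real targets.

## Numerical choices, in one place

- Distances: Angstrom internally; nm accepted where the field quotes nm
  (pocket cutoff, box size). Boundary comparisons inclusive (≤).
- Hashing: FNV-1a 32-bit in double arithmetic (exact on all platforms);
  fingerprint bit = hash mod 2048.
- Normalization: std floor 1e-8; training statistics only.
- Optimizers: Adam (β 0.9/0.999, ε 1e-8), full determinism from one
  seed, single-threaded; minibatch order is part of the seed contract.
- Tie-breaks: interface rows by (distance, protein index, ligand index);
  ranking by stable sort; Butina centroids by input order.
- Degenerate inputs raise errors rather than guessing: empty pockets,
  single-class training sets, fewer than 10 examples per class,
  zero-denominator enrichment, non-monotone residue numbering.
- Problem sizes used by the shipped checks: 2,000-pair libraries with a
  500-pair holdout for the pair-vector stage; 30–40 toy complexes with
  3 decoys each, 8 receptors held out entirely, for the interface stage;
  500-hill logs on 1,000-point grids; 10-atom superposition toys. These
  are the package's stated study conditions for its own validation.

## Known limitations

- The mock docking engine scores by ligand size plus noise; it validates
  plumbing and determinism, never binding physics.
- The interface encoding is a declared stand-in: element one-hots plus
  scaled distance, no pharmacophore typing, no angles.
- The skip-gram corpus is the screening library itself; transferring an
  embedding to a disjoint chemical space will mostly hit the unknown
  (zero) vector.
- FES reconstruction is 1D and assumes plain (non-well-tempered) bias
  unless rescaled upstream.
- Chemotype clustering with hashed fingerprints makes close homologs
  (e.g. chain-length series) identical at radius 2; that is expected
  fingerprint behaviour, and the clustering threshold should be chosen
  with it in mind.
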