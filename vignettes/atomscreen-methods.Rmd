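---
title: "atomscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{atomscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package does

`atomscreen` implements a structure-based virtual-screening workflow at
desk scale. The screening question is the one every hit-discovery campaign
faces: out of a large catalog of purchasable small molecules, which few
dozen should be bought and physically assayed against a protein target?
The package's answer follows the architecture of modern deep-learning
screening platforms:

1. **Library preparation** — drug-likeness windows and structural-alert
   (SMARTS) filters remove reactive, aggregation- and fluorescence-prone
   molecules; a *chemotype-novelty exclusion* then removes everything with
   Tanimoto similarity strictly above 0.5 (ECFP-style, 1024 bits) to any
   known binder of the target or of a sequence homolog at 70 % identity
   or more, so that any hit found later is a genuinely new scaffold.
2. **Featurization** — each receptor/ligand pose becomes a graph: atoms
   are vertices carrying a one-hot Sybyl atom type plus a ligand/receptor
   role bit; edges connect atom pairs within distance cutoffs and carry
   the interatomic distance. Receptor atoms farther than 7 Å from every
   ligand atom are excluded.
3. **Scoring** — a five-block multi-task graph-convolutional network
   predicts bioactivity probability, pose quality, and a docking-score
   surrogate; six networks trained with disjoint held-out
   sequence-identity folds form the production ensemble.
4. **Selection** — the top-ranked molecules are Butina-clustered at 0.35
   Tanimoto similarity and the highest-scoring exemplar of each cluster is
   carried to a blinded, scrambled 96-well plate. No step involves manual
   cherry-picking; the whole pipeline is a pure function of its inputs and
   seed.
5. **Analog expansion** — confirmed hits seed a follow-up round:
   fingerprint nearest neighbors plus Murcko-framework substructure
   matches, ranked by a regression-head variant of the same network
   trained on quantitative activities.
6. **Campaign analytics** — per-project hit rates, portfolio summaries,
   the hit-rate-versus-training-data regression, and scaffold-novelty
   distributions. The package ships a transcription of a 22-program
   internal-campaign results table as a plain-text fixture;
   `summarizePortfolio(internalPrograms())` reproduces its headline
   statistics (mean single-dose hit rate 8.8 %, mean dose–response hit
   rate 6.7 %, reconfirmation rate 91 %, analog-round means 29.8 %/26.0 %
   over the 13 programs reporting analog rates).

## The network and its declared operator

The scoring network has exactly five graph-convolution blocks. Blocks 1–2
use all ligand and receptor atoms with a 5 Å edge cutoff and 64 filters;
block 3 raises both to 7 Å and 128; blocks 4–5 keep those settings but
operate on ligand atoms (and ligand–ligand edges) only. The sum-pool over
ligand atoms of the last block feeds the task head — two sigmoid outputs
(bioactivity, pose quality) and one linear output (docking-score
surrogate), or a single linear output in the regression variant used for
analog ranking.

The literature describing this family of models specifies "pair-wise,
distance-dependent edges" but not a concrete convolution operator. The
package therefore *declares* its operator, chosen as the minimal form
honoring that description:

$$h'_v \;=\; \mathrm{ReLU}\Big(W_{\mathrm{self}}^\top h_v \;+\;
  \sum_{u \in N(v)} \phi(d_{uv})\, W_{\mathrm{nbr}}^\top h_u \;+\; b\Big),
  \qquad \phi(d) = \mathrm{rbf}(d)^\top w_g ,$$

where $\mathrm{rbf}(d)$ is a Gaussian radial basis expansion of the edge
distance (centers every 0.5 Å on (0, 7.5], width 0.5 Å) and $w_g$ is a
learned per-block weight vector, so each block learns a scalar
distance gate. Because node updates depend on distances only through
$\phi$ and the readout is a sum over ligand nodes, the outputs are
invariant to rigid rotation/translation of the complex and to atom
relabeling; the test suite asserts both at $10^{-6}$.

**Training.** Six models, one per held-out fold, 10 epochs each, ADAM at
learning rate 0.001. Folds are built by single-linkage clustering of
targets at 70 % global sequence identity (clusters are fold-atomic, so no
two targets at or above the threshold can land in different folds),
packed largest-active-count-first into the lightest fold. Within an
epoch, targets are drawn with replacement proportionally to their active
counts and each draw contributes one minibatch (default 32) of that
target's complexes.

### Numerical choices

* **Gate initialization.** Weight matrices are He-initialized; the gate
  vectors $w_g$ start near zero ($\sigma = 0.05$). With open gates the
  summed messages multiply activation variance by roughly the
  neighborhood size per block, which saturates the heads after five
  blocks; near-zero gates let the network start as a well-scaled
  per-node map and open the distance gates by gradient.
* **Regression-target standardization.** Docking-score surrogates (and
  potency targets in the regression variant) are z-scored inside
  `trainEnsemble`; the mean/sd are stored with each member and undone at
  prediction. Without this the MSE task dominates the shared trunk's
  gradients and the probability tasks train far more slowly.
* **Loss.** Binary cross-entropy for the two probability tasks (clipped
  at $10^{-7}$), mean squared error for the regression task, equal task
  weights by default, masked per example where a label is absent, mean
  over the batch.
* **Determinism.** Every stochastic step (initialization, target
  sampling, minibatch choice, plate scrambling, fixture generation) runs
  under its own seed derived from the master seed. `scoreLibrary`
  processes graphs in a canonical order so its output is bit-identical
  regardless of input order, and all ranking ties are broken by canonical
  SMILES (then id), which makes end-to-end runs byte-reproducible.

## Boundary conventions

Several published descriptions leave comparisons at the boundary open;
the package fixes them and tests them:

* Receptor truncation keeps an atom at exactly 7.0 Å ("more than 7 Å
  away are excluded" read literally); edge membership uses $d \le r$.
* Homolog inclusion uses identity $\ge$ 70 %; novelty exclusion removes
  similarity strictly $>$ 0.5 (a candidate at exactly 0.5 is retained).
* The Butina cutoff 0.35 is read as a *similarity* threshold (neighbors
  iff similarity $\ge$ 0.35), which yields broad chemotype clusters and
  maximizes the diversity of the exemplar set; the alternative distance
  reading is available via `cutoffIsDistance = TRUE`.
* Truncation is atom-wise, not residue-wise (the literal reading);
  hydrogens are dropped everywhere by default.
* Ties in Butina centroid choice go to the lower input index; exemplar
  and ranking ties go to the lexicographically smaller canonical SMILES.

## Open design points and how they were resolved

* **Fingerprint.** Bit-level ECFP portability across toolkits does not
  exist, so the package standard is declared: Open Babel's circular
  (Morgan-style) fingerprint, radius 2, folded from 4096 to 1024 bits by
  modular OR, computed on standardized structures (largest fragment,
  neutralized) by default — the standardization pass is exposed and can
  be disabled. Ten frozen bit vectors pin the implementation against
  regressions.
* **Descriptors** are Open Babel's (molecular weight, logP, topological
  polar surface area, N+O acceptor counting, donor counting); rotatable
  bonds are counted with the classic non-ring single-bond SMARTS (amide
  bonds counted). A 50-molecule frozen reference plus hand-summed atomic
  masses guard the implementation.
* **Sequence identity** is pairwise global Needleman–Wunsch (match +1,
  mismatch 0, gap −1, terminal gaps penalized), identity = matches /
  alignment columns. Profile-based homology search is out of scope.
* **Alert rules.** The published medicinal-chemistry filter collections
  run to hundreds of rules; the package ships a documented ~30-pattern
  representative subset (reactive groups, PAINS-style motifs,
  aggregator/fluorophore chemotypes) plus property windows in an editable
  YAML file, and an optional similarity pass (≥ 0.85) against a packaged
  aggregator reference list. Fidelity to any specific published rule set
  is a data question, not a code question.
* **Whole-kinome exclusion** is driven by a `kinase` class label on the
  user's binder database records.
* **Pose ensembles.** Multiple poses per ligand are aggregated by the
  maximum member probability per pose set (configurable to mean);
  clustering operates on the ensemble-mean score.
* **Analog search.** Proprietary feature-tree similarity searches are
  replaced by the Murcko-framework substructure route, with vertices
  matched on Sybyl types so aromatic queries do not match saturated
  rings; maximum-common-substructure and graph-edit augmentation are
  intentionally out of the core.
* **Control readout.** Planted-signal *recovery* is asserted per member
  (held-out AUC ≥ 0.8 for each of the six models); the shuffled-label
  *control* is summarized as the pooled cross-validated AUC (each ligand
  scored by the member that held out its fold), the natural single-number
  chance readout, asserted to lie in [0.4, 0.6].

## The synthetic study

All tests and the acceptance script run on synthetic fixtures generated
by the package itself:

* **Molecules** come from a fragment grammar (8 ring cores × 10 linkers ×
  16 decorations), canonicalized and deduplicated — every molecule is
  valid and the planted rule has chemical meaning. The default study uses
  1000 ligands.
* **Pockets** are 24 receptor atoms on a hemispherical shell of radius
  6 Å below the ligand plane (12 targets with target-specific element
  assignments); ligands sit at the pocket center with their generated 2D
  template coordinates plus 0.3 Å isotropic jitter. Each ligand also gets
  a decoy pose rigidly translated 4.5 Å out of the pocket, giving ~2000
  complexes.
* **Labels.** The planted activity rule is "contains an aromatic
  nitrogen and molecular weight ≤ 350 g/mol", XOR-ed with a 10 %
  Bernoulli label flip; pose quality is 1/0 for docked/decoy; the
  docking surrogate is the negative 4 Å ligand–receptor contact count
  plus unit Gaussian noise. Synthetic target sequences are random
  120-mers (mutually dissimilar, so 12 fold-atomic clusters exist).

Under these conditions the six-member ensemble reaches held-out AUC
≈ 1.0 per member and the shuffled-label control sits at ≈ 0.5. What this
does and does not show: the generator emulates the *structure* of the
learning problem (multi-target data, fold constraints, noisy labels,
pose decoys, multi-task supervision), but its planted signal is far
easier than real structure–activity relationships — poses are not
energy-minimized, pockets have no chemistry-specific shape
complementarity, and the activity rule is a function of ligand
composition alone. Passing tests therefore validate the machinery
(featurization, optimization, fold hygiene, determinism), not prospective
accuracy on real proteins.

Problem sizes were chosen so the whole suite runs comfortably on a
single CPU: the full study (1000 ligands / 12 targets / 2000 complexes)
for the recovery and control checks, 60–200 molecules for the per-module
oracle comparisons, and an 80-ligand end-to-end pipeline for the
byte-determinism check.

## Known limitations

* The production-scale components are intentionally absent: billions-of-
  compounds catalogs, physical docking and pose generation, pocket
  detection, homology-model construction, and any trained production
  weights. Binding sites and poses are inputs here.
* Butina clustering and novelty exclusion are dense $O(n^2)$
  implementations, fine for desk-scale libraries (up to a few tens of
  thousands of fingerprints), not for millions.
* Sybyl typing covers the common organic vocabulary; exotic elements and
  tautomer-sensitive cases fall back to a shared generic type with a
  warning.
* The 22-program campaign table was transcribed from a published table
  whose text extraction merged some cells; the transcription was
  validated against every aggregate statistic printed alongside it
  (column means, reconfirmation count, analog-round means), and the one
  remaining ambiguity (the tested-compound column mean, 435 vs a printed
  average of 440) is reported by `summarizePortfolio` rather than
  resolved silently.
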