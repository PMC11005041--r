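---
title: "Consensus toxicity classification with atom-level Shapley attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus toxicity classification with atom-level Shapley attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

ToxConsensus predicts a binary toxicity endpoint (mutagenicity, skin
irritation, acute oral toxicity, ...) for small molecules given only
their SMILES, and then explains each prediction at the level of
individual atoms. The pipeline has four stages.

**1. Encoding.** Each standardized molecule (largest covalent fragment,
canonical isomeric SMILES via RDKit) is encoded with three binary
fingerprint families:

* `MORGAN` — circular atom environments of radius 2, hashed to 1024
  bits;
* `PATH_TOPOLOGICAL` — the RDKit path-based topological fingerprint
  (bond subgraphs of 1–7 bonds, hashed to 2048 bits);
* `PUBCHEM` — an 881-bit substructure-key fingerprint following the
  classical PubChem layout: hierarchic element counts (bits 0–114), a
  ring-count block (bits 115–262), element-pair bond keys (bits
  263–326) and SMARTS functional-group/environment keys above that.

For every on-bit the package can also report *which atoms set it* (the
bit–atom map): the atoms of each hashed circular environment for
Morgan, the atoms of each hashed bond subgraph for the path
fingerprint, and the atoms of each distinct substructure match for the
PubChem keys. Each match or environment is one *occurrence*; hash
collisions keep all contributing occurrences. On-bits with no
heavy-atom correspondence (hydrogen-count keys) are recorded as
unmappable rather than silently dropped.

**2. Classification.** Four algorithm families are trained per
fingerprint family — random forest, SVM (RBF/linear kernel with a Platt
probability sigmoid), k-nearest neighbour (neighbour-vote fraction,
optionally distance-weighted) and a multilayer perceptron — giving
3 × 4 = 12 models per endpoint. Hyperparameters are tuned by exhaustive
grid search; each grid point is scored by the mean Matthews correlation
coefficient (MCC) over cross-validation folds, where a *fold* is an
independent random 80/20 resample of the training data (20 resamples
at full scale). Every model emits a probability score PS ∈ [0, 1];
a compound is toxic iff PS ≥ 0.5 (the 0.5 boundary is toxic).
y-randomization (retraining on shuffled labels) is available as a
negative control; on a balanced set it collapses MCC to ≈ 0 and
accuracy to ≈ 0.5.

**3. Consensus.** A consensus combination is any subset of ≥ 2 of the
12 models; its consensus score CS is the plain arithmetic mean of the
member PSs, thresholded at 0.5 exactly like PS. All
$\sum_{k=2}^{12}\binom{12}{k} = 2^{12}-13 = 4083$ combinations are
evaluated on the held-out test set (each model's PS vector is computed
once and reused, so the scan is 4083 mean-and-threshold passes) and
ranked by MCC. Ties prefer fewer members, then the lexicographically
smallest member tuple, so selection is deterministic.

**4. Explanation.** For each member of the selected consensus, Kernel
SHAP estimates a signed Shapley score per fingerprint bit (positive =
toward toxicity). Scores are retro-mapped onto atoms through the
bit–atom map with

$$fw(a) \;=\; \sum_{f \ni a} \frac{s_f}{n_{\mathrm{Atoms},f}\; n_{\mathrm{occ},f}},$$

i.e. each feature's score is divided by the number of atoms in the
occurrence containing $a$ and by the feature's occurrence count, and
summed over the features containing the atom. The final atom weight is
the arithmetic mean of $fw$ over the consensus members — the molecule's
atoms are the common denominator that makes mixed-family members
commensurable. Rendering draws the structure with a signed colour
scale (red toward toxicity, blue away from it).

## Tunable parameters

| parameter | default | why |
|---|---|---|
| Morgan radius / bits | 2 / 1024 | standard ECFP4-equivalent setting |
| path fingerprint bits / path sizes | 2048 / 1–7 bonds | common defaults for this family; recorded in the `FingerprintSet` params |
| PubChem-layout length | 881 (fixed) | layout contract of the family |
| CV folds (random 80/20 resamples) | 20 (`fastGrid` runs use 5) | repeated holdout estimates the CV MCC; 5 keeps desk runs in minutes |
| PS/CS decision threshold | 0.5, inclusive on toxic | fixed contract used consistently by models and consensus |
| SHAP background size | 50 seeded training compounds | bias/runtime compromise; the acceptance run uses 12 |
| SHAP coalition budget | `auto` = 2·M + 2048 | with ≤ budget coalitions the regression enumerates all of them and is exact |
| grid candidates | see `defaultGrid()` | RF: `max_features` ∈ {sqrt, log2, all} × 100/500 trees; KNN: k ∈ 1–15 × {uniform, distance}; MLP: 1–3 layers of {100, 200, 1000} × {lbfgs, adam, sgd} × 4 activations × 3 learning rates; SVM: {linear, rbf} × C ∈ {0.1, 1, 10, 100} |

The SVM candidate values (kernel and C) are conventional choices: only
the tuned *quantities* are fixed by the design, not their candidate
lists, so the grid uses the standard decades of C with both kernel
shapes, and the SVM decision values are passed through a Platt sigmoid
because the consensus averages probabilities, not margins. The MLP
layer layouts enumerate all 1–3 layer combinations of 100, 200 and
1000 neurons; deeper stacks add nothing a desk-scale dataset can
support.

## Design choices made where the design was open

* **Eye-irritation labeling** treats damage to *any* of conjunctiva,
  cornea or iris as toxic. The alternative (require all three) is
  grammatically defensible but toxicologically nonstandard; GHS-style
  classification triggers on any serious ocular lesion.
* **Conflicting duplicate labels** remove the structure entirely (both
  records). Keeping either side would silently adjudicate evidence the
  curation step cannot see.
* **Splits are plain random**, not stratified: nothing in the protocol
  requires stratification, and the class imbalance (≈ 70/30) is mild.
* **Stereochemistry is retained** during standardization. Dropping it
  merges genuinely different molecules; retaining it costs nothing for
  the fingerprint families used. No tautomer canonicalization is
  applied; the choice is recorded with the molecule set.
* **MCC ties in the consensus scan** prefer smaller combinations: a
  smaller ensemble predicts (and explains) cheaper at identical
  measured performance.
* **Ring-bit clustering** groups PubChem-layout bits 115–262 by (ring
  size, ring class), the granularity at which the block's bits differ
  only in occurrence count. Within each cluster only the
  highest-scoring on-bit keeps its score (ties: lowest bit index);
  dropped members are zeroed, not reassigned — the representative keeps
  its own atom mapping.
* **The 881-bit PubChem-layout table is a synthetic stand-in.** The
  official per-bit key table is not redistributable, so the package
  ships its own layout-faithful table: official thresholds for the
  first 49 element-count bits, the ring block at exactly 115–262, and
  authored pair/SMARTS keys above it, with the remaining high bits
  reserved (never set). Length, section structure, occurrence
  semantics and retro-mapping behaviour are preserved; per-bit
  semantics beyond bit 48 are the package's own. Models trained with
  this family are internally consistent but their bit indices are not
  comparable with other software's PubChem fingerprints.

## What the synthetic generator emulates — and what it does not

`generateDataset()` assembles molecules from ~16 drug-like aromatic
scaffolds × 30 substituents and plants a toxicophore (default: an
aromatic nitro group) in the toxic class. Labels are assigned by
actually substructure-matching the planted pattern on the assembled
molecule, then optionally flipped with probability `labelNoise`; the
default class balance is 70% nontoxic, emulating the imbalance typical
of curated binary endpoint tables, and generation is a pure function of
the seed.

The generator emulates the *mechanics* of an endpoint dataset: binary
labels correlated with a recoverable substructure, class imbalance,
near-duplicate structures, an 80/20 split. It does **not** emulate real
toxicological chemistry: activity cliffs, multi-mechanism endpoints,
assay noise structure and chemical-space breadth are all absent. A
green end-to-end test therefore establishes that the pipeline recovers
a planted signal through fingerprints, grid search, consensus selection
and SHAP retro-mapping — not that any particular real endpoint is
predicted well.

## Numerical choices

* **MCC with a zero denominator factor is defined as 0**;
  precision/recall/specificity with a zero denominator are reported as
  `NA` and excluded from ranking.
* **Kernel SHAP** excludes features identical to every background row
  (their Shapley value is exactly 0), enumerates all coalitions when
  `2^M` fits the budget (making the estimate exact), and otherwise
  enumerates complete coalition sizes smallest-first before sampling
  the remainder. The regression is solved with the local-accuracy
  constraint eliminated analytically, so scores + base = PS holds to
  numerical precision; a tiny ridge is added only if the normal matrix
  is singular.
* **SVM duals** get a 1e-8 ridge on the kernel matrix for positive
  definiteness; Platt scaling is fitted on the training decision
  values (not out-of-fold), which is slightly optimistic but stable at
  desk scale.
* **y-randomization checks need an adequately sized test set**: under
  the null, MCC is mean-zero but |MCC| is not — its expectation is
  roughly $0.8/\sqrt{n_{test}}$. The negative-control suite therefore
  evaluates on ≥ 80 test compounds so that "mean |MCC| near zero" is a
  property the experiment can actually exhibit.
* **Degenerate inputs**: single-class training data, empty SMILES,
  pentavalent carbons and family mismatches are rejected with errors;
  per-molecule failures in batch prediction drop the record and carry
  on.

## Known limitations

* Molecule handling requires a Python with RDKit on the PATH (the
  package shells out in batch; ~1 s per call). No pure-R fallback.
* Platt calibration on training decisions can saturate PS near 0/1 on
  separable data.
* The consensus scan is exhaustive only because the ensemble is small
  (4083 subsets of 12 models); it does not scale past ~20 models
  (2^20 subsets).
* Applicability-domain analysis is out of scope: predictions far from
  the training chemical space carry no warning.

## Reproducing the headline run

```{r}
library(ToxConsensus)
ds <- generateDataset(fixtureSpec(nCompounds = 300, seed = 1))
sp <- randomSplit(ds, seed = 1)
ens <- trainEnsemble(sp$train, folds = 5, seed = 1)
ranked <- exhaustiveScan(ens, sp$test)   # 4083 rows
best <- selectBest(ranked)
tox <- sp$test$smiles[sp$test$label == 1][1]
awm <- explainCompound(ens, best, tox, nBackground = 12, seed = 1)
renderAtomWeights(awm, svgPath = "tox.svg", jsonPath = "tox.json")
```

The same run, end to end, is what `scripts/acceptance.R` executes
against the installed package.
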