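---
title: "Feature-based drug–target interaction prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based drug-target interaction prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dtiforest` treats drug–target interaction (DTI) prediction as binary
classification of drug–protein pairs. This vignette explains the model and
the design decisions behind each stage, what the synthetic study emulates,
and where the method's limits are.

## The pair model

A pair `(d, p)` is represented by the concatenation of a protein feature
vector and the drug's 881-bit PubChem substructure fingerprint. Known
interactions are positives; a seeded uniform sample of unlisted pairs of
equal size (configurable via `neg_ratio`) supplies the negatives. Treating
unlisted pairs as negative is the standard — and imperfect — convention for
DTI gold standards: some "negatives" are merely untested. Candidate
negatives are enumerated in lexicographic `(drug, protein)` order before
sampling so the draw does not depend on input file order.

## Protein descriptors

Ten encoders cover composition, position, physicochemistry and evolution:

* **Positional encoders** (EAAC, EGAAC, NUM, BINA, flattened PSSM) need a
  fixed length; sequences are truncated to their first `L_fixed = 100`
  residues or right-padded with a dummy residue `O`. 100 is the value that
  makes the combined mode dimensions come out at 2125 (PSSM+EGAAC+EAAC) and
  4625 (+DDE+BINA). Padding positions count in window denominators but
  never in numerators, so a fully padded window encodes as zeros rather
  than as a fake composition.
* **Global encoders** (DDE, TF-IDF, 1/2-gram, PseAAC, PsePSSM) run on the
  original, unpadded input: padding would dilute compositions without
  adding information.
* **EAAC/EGAAC** use 5 equal non-overlapping windows (20 residues each at
  `L_fixed = 100`), giving dimensions 100 and 25. The EGAAC groups are
  aliphatic GAVLMI, aromatic FYW, positive KRH, negative DE, uncharged
  STCPNQ.
* **DDE** standardizes each of the 400 dipeptide frequencies against the
  expectation implied by sense-codon counts of the standard genetic code
  (`C_H = 61`): `DDE = (DC − TM) / sqrt(TM (1 − TM) / (H − 1))`. An absent
  dipeptide is therefore *negative* evidence, not zero.
* **PsePSSM** summarizes a variable-length PSSM as 20 column means plus
  `20 × ε` lagged mean squared differences, `ε = 1..10` (dimension 220).
  Raw integer scores are used; no sigmoid or min–max scaling is applied
  before the lag terms.
* **PseAAC** uses Chou's three property scales (hydrophobicity,
  hydrophilicity, side-chain mass), each standardized to zero mean and unit
  population variance over the 20 residues, with `λ = 8` correlation lags
  and weight `w = 0.05`; the 28 components are jointly normalized to sum
  to 1.
* **2-gram** is restricted to the 400 standard-residue dipeptides;
  `O`-containing pairs are skipped in the numerator only.

Combination mode A concatenates PSSM, EGAAC, EAAC; mode B adds DDE and
BINA; mode C concatenates all ten encoders (5414 protein features). The
pipeline defaults to mode C — the configuration in which the full encoder
set is pruned by the selection stage — since selection, not the encoder
list, is meant to control dimensionality.

## Feature selection

Symmetric uncertainty,
`SU(F, C) = 2 (H(F) − H(F|C)) / (H(F) + H(C))`,
is a normalized mutual information in `[0, 1]`. Features are discretized
by equal-width binning (5 bins; features with ≤ 5 distinct values pass
through) and ranked by descending SU, ties broken toward the smaller column
index. SU is defined as 0 when both variables are constant.

IWSSR then scans the ranking. The subset starts at the top-ranked feature;
for each next candidate `f`, level 1 tries replacing each selected feature
with `f`, and — if no replacement improves — level 2 tries the plain
addition. The best move is accepted only on *strict* improvement of the
evaluator score, which makes accepted scores strictly increasing and
prevents drift along ties.

The wrapper evaluator is an injectable contract (`function(subset) →
accuracy`). The default is the stratified 5-fold cross-validated accuracy
of a CART tree with `maxdepth = 5`: deep enough to register interactions
among a handful of selected features, shallow enough to stay fast and
stable. The fold assignment is drawn once per evaluator, so the evaluator
is a pure function of the subset and the whole search is deterministic
given its seed.

Two practical parameters:

* `max_rank` (default 100 in the pipeline) caps how deep into the SU
  ranking the wrapper scans. With thousands of assembled pair features a
  full scan costs tens of minutes while acceptances plateau long before;
  the cap bounds runtime at a measured, minimal cost to the outcome.
* `bins` (default 5) trades SU resolution against estimation noise.

## Rotation Forest

Each of the `n_trees = 35` trees sees the data through its own sparse
rotation. The feature indices are randomly partitioned into subsets of
`subset_size = 3`; per subset, `ceil(0.75 n)` training rows are sampled
*without* replacement and PCA is run on that sample restricted to the
subset. All principal axes (no truncation) are placed as one diagonal block
of the rotation matrix `R_i`; entries outside the blocks are exactly zero,
and each block is orthonormal. The tree is grown, fully (Gini, `cp = 0`,
`minsplit = 2`), on `X R_i`. A zero-variance subset receives an identity
block so `R_i` stays invertible, and a rank-deficient PCA block is
completed to an orthonormal basis.

Class confidences average the per-tree class distributions; per sample they
sum to 1. The predicted label is the arg-max (equivalently, thresholding
the positive confidence at 0.5 in the binary case), ties resolving to the
smaller class label.

## Evaluation protocol

Metrics follow the usual confusion-table identities (Acc, Sen, Sp, Pre,
MCC); a zero-denominator metric is reported as 0 with a `degenerate` flag
rather than raising, so a degenerate fold cannot abort a cross-validation
run. AUC is the tie-aware normalized Mann–Whitney statistic, checked in the
test suite against both a brute-force pairwise count and `pROC`.

Two protocols are provided:

* **Stratified k-fold cross-validation** (`kfold_cv`, default `k = 10`)
  with selection and model fitting nested inside each training fold —
  pooled predictions plus per-fold means and standard deviations.
  Nesting avoids selection leakage into the held-out folds.
* **Independent split** (`independent_split` + the default pipeline
  protocol): a stratified 90/10 split; selection and training see only the
  90%, the report measures the 10%. This is the pipeline default because
  one selection pass, not ten, fits interactive time budgets; note its
  AUC is estimated from the small independent set and is correspondingly
  noisy.

## The synthetic study

The generators emulate the four inputs at a desk scale chosen to run the
whole pipeline in minutes on one CPU: 40 proteins of 80–140 uniform random
residues, 30 drugs with i.i.d. fingerprint bits (density 0.1), synthetic
PSSMs (+5 at the observed residue over uniform noise in −2..2), and an
interaction network generated by a logistic model on 5 randomly chosen,
standardized feature columns of the assembled pair matrix (log-odds 2 per
unit each, no intercept, 5% label flips). The planted column names are
returned as ground truth, so selection and classification can be scored
against a known answer.

What the simulation does *not* emulate — and what passing tests therefore
do not show about real data: sequences carry no motif or family structure,
PSSMs carry no real evolutionary signal, fingerprint bits are independent
(real substructure bits are strongly correlated), and the interaction
network has none of the degree heterogeneity of curated DTI networks. One
property it does share with real pair data is worth emphasizing: because
features live at the protein or drug level while labels live at the pair
level, label information flows through entity *identity*. With only 40
proteins, many entity-level noise columns correlate with the per-protein
interaction rate by chance, so the SU filter ranks proxies of entity
identity alongside — often above — the truly generative columns, and the
selected subset tends to contain predictive proxies rather than the planted
columns themselves. This is a structural property of bipartite pair
learning at small entity counts, not an artifact of the implementation; it
is also why per-entity (cold-start) evaluation is harder than pair-level
evaluation on shared entities.

## Numerical and degenerate-input choices

* Entropies use base 2 with `0 log 0 ≡ 0`; SU is clamped to `[0, 1]`
  against floating-point drift.
* TF-IDF smooths `DF = 0` to 1 so unseen residues get the maximal, finite
  IDF; log base 10 (configurable).
* Orthonormality of rotation blocks is asserted to `1e-8`; off-block zeros
  are exact by construction.
* All randomness (generators, negative sampling, folds, row samples,
  partitions) is drawn under locally scoped seeds that restore the global
  RNG state, so library calls never perturb a caller's random stream.

## Known limitations

* Negative "examples" are unverified non-interactions by construction.
* The fixed-length convention (`L_fixed = 100`) discards C-terminal
  sequence beyond position 100 for positional encoders; global encoders
  see the full sequence.
* The wrapper's strict-improvement rule, combined with a single-tree
  evaluator, is conservative: selected subsets are small, and a plateauing
  evaluator ends acceptances early.
* TF-IDF document frequencies are fitted on the full protein corpus at
  build time; under cross-validation this is a (mild, 20-value) use of
  held-out sequence composition.
* PSSM inputs are read, never generated: producing real profiles requires
  an external PSI-BLAST run against a sequence database.
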