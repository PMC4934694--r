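---
title: "Methods: profile-based prediction of protein-RNA interface residues"
author: "RNAInterface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-based prediction of protein-RNA interface residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements,
the parameters that matter, the choices made where the method left room
for choice, and what the synthetic-data tests do and do not demonstrate.

## The labeling model

A residue of a protein chain in a solved protein–RNA complex is an
*interface residue* when at least one of its atoms lies within a
distance cutoff of any atom of any bound RNA chain. The cutoff defaults
to 5 Å, the mid-range of the 3.5–7 Å values used across the interface
prediction literature and the most common choice among sequence-based
predictors, which makes labels comparable across studies.

Three decisions around this definition are ours:

* **Boundary.** The distance test is inclusive (≤ 5 Å). "Within 5 Å"
  is ambiguous at the boundary; inclusiveness makes the rule
  deterministic, and a measure-zero boundary cannot affect statistics
  on real coordinates.
* **Atom set.** All recorded atoms participate, hydrogens and modified
  residues included. The field has no standard here; restricting to
  heavy atoms would change labels only for the minority of structures
  that record hydrogens, and an all-atoms rule is the simplest to state
  and reproduce.
* **Nonstandard residues.** Nonstandard amino acids (selenomethionine
  and relatives) are kept positionally and mapped to `X`, so sequence,
  profile and label arrays stay aligned with the structure; `X` rows of
  a pseudo-profile are neutral (all zeros, i.e. 0.5 after
  normalization). Alternate locations keep the first conformer;
  residues follow author chain order; outputs are 1-based per chain.

Benchmark admission (`filterDataset`) mirrors the criteria used to
build the structure-derived training sets: resolution strictly below
3.5 Å (complexes without resolution metadata are rejected and counted
separately), protein chain at least 40 residues, a bound RNA chain of
at least 5 nucleotides, and at least 3 interface residues in the chain.
Criteria are tested in that order and each rejected chain is counted
against the first criterion it fails, so the rejection counts sum to
the number of rejected chains.

`greedyIdentityFilter` is deliberately *not* a CD-HIT/KClust clone: it
is a longest-first greedy pass using global (Needleman–Wunsch)
alignments under BLOSUM62 (gap opening 10, extension 0.5), with
identity defined as identical aligned positions over alignment length,
gaps included. It reproduces the intent of the 30% non-redundancy
criterion on small benchmark sets; at database scale a dedicated
clustering tool should be used instead.

## Profiles and features

The per-residue evidence is a PSSM: an L×20 matrix of log-odds scores
from an iterative profile search (3 iterations, e-value 0.001, applied
as both the reporting and the profile-inclusion threshold — the search
tool distinguishes the two; using one value for both matches the
single-number configuration the method family reports). Raw scores are
mapped entrywise through the logistic function

$$f(x) = \frac{1}{1 + e^{-x}}$$

into (0, 1). A raw score of 0 ("no information") maps to 0.5. When a
search finds zero hits, modern BLAST+ writes no PSSM at all; the
wrapper then falls back to the query's BLOSUM62 rows
(`pseudoProfile`), which is also what the search tool itself uses as
the profile prior, with the hit count recorded as 0.

Each residue is encoded as the concatenation of the normalized profile
rows of a 25-residue window (the target plus 12 neighbours per side):
500 features. Two choices here are ours:

* **Terminus padding 0.5.** Window positions beyond the chain ends
  contribute 0.5 in all 20 slots — the logistic image of a raw score
  of 0, i.e. the normalization's own "no information" point. Zero
  padding would instead look like strong evidence *against* every
  residue type. The value is configurable (`windowConfig`).
* **No class rebalancing.** Interface residues are a minority
  (roughly one in five in structure-derived sets) and the encoder
  preserves that imbalance; the method family trains on the natural
  distribution.

## Profile distances

Two profiles of the *same* query generated against different reference
databases are compared entrywise:

$$\mathrm{NSSD}(P_1,P_2) = \frac{1}{20L}\sum_{i=1}^{L}\sum_{j=1}^{20}
\left(P_1(i,j)-P_2(i,j)\right)^2$$

$$\mathrm{NKL}(P_1,P_2) = \frac{1}{2\,(20L)}\sum_{i=1}^{L}\sum_{j=1}^{20}
\left[P_1(i,j)\log\frac{P_1(i,j)}{P_2(i,j)} +
      P_2(i,j)\log\frac{P_2(i,j)}{P_1(i,j)}\right]$$

Numerical decisions, all documented on the functions:

* Distances are computed on **logistic-normalized** values. NKL
  requires strictly positive entries, which raw log-odds do not
  provide; normalization guarantees the domain.
* NKL uses the **natural logarithm** (the base is a convention; it
  scales the metric by a constant and affects no comparison).
* Entries are treated as **pointwise values, not probability
  distributions** — no row renormalization. The symmetrized-KL form is
  applied verbatim, which keeps it a termwise non-negative, symmetric
  divergence that is zero exactly on identical matrices.
* The two prefactors differ (1/(20L) versus 1/(2·20L)) and are kept
  exactly as the metrics are defined.

## Classifiers

Four families, plus the consensus actually recommended for production
use:

| spec | implementation | defaults |
|---|---|---|
| `NB` | Gaussian naive Bayes (`e1071::naiveBayes`) | per-feature Gaussians — features are continuous in (0,1) |
| `RF100` | `randomForest`, exactly 100 trees | library defaults otherwise |
| `SVML` | `e1071::svm`, linear kernel | cost C = 1 |
| `SVMRBF` | `e1071::svm`, RBF kernel | C = 1, γ = 1/500 (1/feature width) |
| `CONSENSUS` | mean of SVMRBF and RF100 probabilities | members trained under the same seed |

The SVM hyperparameters are not part of the method's published
configuration; C = 1 and γ = 1/width are the standard library defaults
and are exposed through `modelSpec(...)`. SVM probabilities come from
the usual sigmoid (Platt) calibration fitted by the SVM library; the
original method family used WEKA-era implementations, so small
numerical differences in probabilities are expected and no attempt is
made to reproduce them bit-for-bit. No feature scaling is applied
beyond the logistic normalization — inputs are already in (0, 1).

Thresholding is `p ≥ t → interface` (ties positive), with t = 0.5 by
default. Training is fully seed-reproducible, and the seed handling
restores the caller's RNG state.

## Evaluation protocol

Confusion-based metrics follow the standard definitions (accuracy,
sensitivity, specificity, MCC). Degenerate cases: a zero denominator
in sensitivity or specificity yields `NA` (undefined, excluded from
averages); a zero factor in the MCC denominator yields MCC = 0, the
usual convention that keeps heavily imbalanced toy cases total. The
MCC denominator is computed in double precision — the four-factor
product overflows 32-bit integers at realistic dataset sizes.

AUC is the rank-sum (Mann–Whitney) statistic with midranks, i.e. the
probability that a random positive outranks a random negative with
ties counted half; this equals the trapezoidal area under the ROC
curve over all thresholds (`rocPoints` exports the curve itself).

Cross-validation is **chain-level**: folds partition chains, never
residues, so windows from one chain can never appear on both sides of
a split. Fold construction greedily balances *residue* counts (chains
sorted by decreasing length, each assigned to the lightest fold, ties
shuffled by seed), because chains vary in length and residue-balanced
folds give fold metrics comparable variance. Both per-fold reports and
a pooled report over the concatenated test predictions are returned;
the pooled report is the headline because it weighs every residue
equally and its confusion counts are exactly the sum of the per-fold
counts. Whether historical results pooled or averaged folds is not
always stated; providing both sidesteps the ambiguity.

## Database subsampling

Uniform random subsets of a reference FASTA database are drawn with
single-pass reservoir sampling (Algorithm R), then written in original
record order, byte-identical to the source records, with a manifest
(source checksum, seed, counts) beside the output. The sample size for
a k% fraction is `ceiling(n * k / 100)` — the unique simple rounding
rule consistent with all three published record counts of the
10%/5%/1% uniform samples of the 50,371,270-sequence UniRef100
release the method family used. Seeds fully determine samples, so
reduced databases are reproducible artifacts. Whether the original
sampling preserved record order is unstated; stable order is our
choice, chosen so diffs against the source database are meaningful.

## What the synthetic generators emulate — and what they do not

`synthComplex` builds minimal single-atom-per-residue geometries:
protein residues 10 Å apart on a line, one RNA nucleotide 3 Å from
each planted interface position, all other residues ≥ 8 Å from every
RNA atom, resolution 2.0 Å, and at least 5 RNA nucleotides so the
complex meets the admission criteria. The ≥ 4 Å margin between planted
and non-planted distances makes annotation robust to the 10⁻³ Å
round-off of the PDB coordinate format. These fixtures exercise the
all-atom distance scan and the admission filters, not real stereochemistry.

`synthProfileDataset` plants a learnable signal: per-residue labels are
Bernoulli(0.2) — close to the interface prevalence of structure-derived
benchmarks — raw scores are Normal(0, 1), and interface residues get a
mean shift of `effectSize` (default 3) on a fixed 5 of the 20 columns,
applied *before* the logistic map so the effect size has a stable
meaning on the raw-score scale. At effect 0 the construction is an
exact null.

Passing tests on these fixtures shows that the pipeline is wired
correctly end to end: geometry → labels → windows → classifier → CV,
with no leakage and chance-level behaviour under the null. It does
*not* show that real interface residues are predictable at any
particular accuracy — real profiles have column correlations, chain
composition biases and homology structure that the independent-Gaussian
generator deliberately omits. Claims about real-data accuracy require
real benchmarks and real PSI-BLAST profiles.

## Problem sizes and tolerances

The test and acceptance runs use 20 chains × 100 residues (2000
windows of 500 features) for the cross-validation checks, 200 random
geometries for annotation recovery, 100 random 5×20 profiles for the
distance oracles, and 2000 seeded repetitions for the
sampling-uniformity check (inclusion frequencies within 4 standard
errors of target/n) — sizes at which the expected behaviours
(pooled AUC ≥ 0.95 with the planted signal, AUC within [0.40, 0.60]
under the null) hold with large margins while a full run stays in the
minutes range on one CPU. Exact quantities (metric closed forms,
distance formulas, sampling counts) are checked to 10⁻¹² against
independent brute-force oracles.

## Known limitations

* The identity filter approximates, and will not exactly reproduce,
  CD-HIT/KClust clustering; do not use it to rebuild published
  benchmark memberships.
* PSI-BLAST is invoked as an external binary; checkpoint (binary PSSM)
  formats are not read, and a zero-hit search falls back to the
  substitution-matrix profile.
* mmCIF structures, biological-assembly expansion and missing-residue
  modeling are out of scope; inputs are PDB-format coordinate text.
* Modern SVM/NB implementations differ from WEKA-era ones, so
  historical AUC tables are comparable in protocol but not expected to
  reproduce to the second decimal on real data.
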