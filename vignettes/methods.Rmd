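---
title: "Scoring driver synonymous variants with a stacked sequence-representation ensemble"
author: "ssnvStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring driver synonymous variants with a stacked sequence-representation ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Synonymous single-nucleotide variants (sSNVs) change a codon without
changing the encoded amino acid. A small fraction of them nonetheless act
as cancer drivers — through splicing disruption, codon-usage effects, mRNA
structure, or miRNA binding — while the vast majority are selectively
neutral passengers. Because experimental validation of individual sSNVs is
slow, *in silico* prioritization is the standard first step. In the
recurrence-based framing used here, variants observed independently in
many tumour cases (recurrence level $r \ge 7$) are treated as putative
drivers and variants seen exactly once ($r = 1$) as putative passengers; a
classifier is then trained to separate the two classes from sequence-derived
features and precomputed annotation scores.

`ssnvStack` implements that full pipeline: window extraction and feature
encoding, labelled-dataset construction, feature-group screening,
importance-ranked forward feature selection, a five-learner stacking
ensemble, an evaluation suite, and a deterministic synthetic-data
generator that makes every stage testable with no external downloads.

## Feature representation

Each variant is represented by a 101-nt window centred on its position
(flank 50 on each side), extracted on the forward strand with a strict
reference-allele check. Two sequences exist per variant: the reference
window and the alternative window (centre base substituted). Seven feature
categories are computed; all "difference" categories are the signed
alternative-minus-reference encodings restricted to the coordinates whose
computation window covers the variant:

| category | groups | width (L = 101) |
|---|---|---|
| basic annotations (sequence, conservation, functional, splicing) | 4 | 39 |
| DNA shape, alternative allele | 14 | 1,364 |
| DNA shape, allele difference | 14 | 76 |
| physicochemical + one-hot, alternative allele | 4 | 1,616 |
| physicochemical + one-hot, allele difference | 4 | 16 |
| embedding-derived, alternative allele | 3 | 4,848 |
| embedding-derived, allele difference | 3 | 48 |

Total: 8,007 columns in 46 groups.

**DNA shape.** Shape descriptors are looked up per pentamer: the 8
per-base types (shear, stretch, stagger, buckle, ProT, opening, MGW, EP)
assign one value to the pentamer's centre base, giving $L-4$ values per
type; the 6 per-step types (shift, slide, rise, tilt, roll, HelT) assign a
pair of values to the two central base steps, and each step's value is the
mean of the contributions of the one or two pentamers whose central steps
cover it, giving $L-3$ values per type. This is the unique convention
consistent with the 1,364-dimensional total, i.e.
$8(L-4) + 6(L-3) = 1364$ at $L = 101$. The allele difference only touches
pentamers overlapping the variant: per-base positions centre $\pm 2$ (5
per type) and steps centre $-3$ to centre $+2$ (6 per type), hence
$8 \cdot 5 + 6 \cdot 6 = 76$ dimensions; the package asserts (and tests)
that the full-vector difference is identically zero outside those
coordinates.

**Physicochemical and one-hot.** Per nucleotide: a one-hot basis vector
(4), the 3-bit chemical-property code NCP, the electron-ion interaction
pseudopotential scalar EIIP, and 8 physical properties PCP, i.e. 16 values
per position and $16L = 1616$ per window. The PCP width of 8 is forced by
the dimension totals; the identity of the 8 properties is configuration,
with documented package defaults. The allele difference is the 16-dim
alt-row minus ref-row at the centre.

**Embedding-derived.** A pluggable adapter maps (model, sequence) to a
16-dim vector per position; the default is three models, so
$3 \times 16 \times 101 = 4848$ alternative-allele dimensions and
$3 \times 16 = 48$ centre-restricted difference dimensions. Real
chemical-language-model embeddings can be supplied as a per-nucleotide
TSV; the bundled adapter is a deterministic synthetic mock (seeded vectors
per model and nucleotide), which preserves the pipeline's geometry without
shipping model weights.

**Missing values.** Any value whose support contains a non-ACGT base
(an N in the pentamer, position, or embedding input) is missing.
Normalization is min–max to $[0,1]$ per column with statistics fitted on
training rows only; test values are clipped into $[0,1]$ and missing
entries are imputed with the training mean of the normalized column.
Constant training columns map to 0. Fitting the normalizer on all rows
would leak test information, so the normalizer is an explicit, separately
fitted object.

## Dataset construction

`label_by_recurrence()` applies the $r \ge 7$ / $r = 1$ rule (the gap
$1 < r < 7$ is excluded). `redundancy_filter()` removes near-duplicate
windows by greedy position-identity clustering at 80% identity — an
internal, dependency-free stand-in for external redundancy-removal suites
with the same threshold semantics, applied to nucleotide windows.
`pair_balance()` matches every driver to its nearest unused same-chromosome
passenger (greedy, position order), producing a balanced set;
`split_train_test()` splits 8:2 by *pair*, so both members of a pair land
in the same partition and near-duplicate leakage across the split is
impossible.

## Feature selection

Groups are screened individually: each group's columns alone are scored by
stratified 10-fold cross-validation under all five base learners, and a
group is retained when its aggregated AUC and accuracy both exceed 0.60.
Aggregation over the learners is the **mean** by default. The maximum over
five learners is also available (`aggregate = "best"`), but with 46 groups
× 5 learners a per-learner maximum performs ~230 comparisons against a
null whose pooled CV-AUC standard deviation is ≈ 0.03 at n = 400, and so
crosses 0.60 on label-independent data too often; the mean keeps
label-independent groups below threshold while, on the synthetic signal
fixture, retaining essentially the same informative groups.

Surviving columns are ranked four ways: impurity-decrease from a random
forest (RIS), gain from regularized extreme gradient boosting (XIS), gain
from a plain gradient-boosted ensemble (GIS), and a greedy mRMR ordering
(mRIS; mutual information with the label minus mean mutual information
with already-selected features, after equal-frequency 10-bin
discretization). For each base learner × ranking, a forward prefix search
evaluates 10-fold CV AUC on the top-$k$ features and keeps the
AUC-maximizing $k$ (smallest on ties); each learner then adopts its best
(ranking, prefix) pair. The default prefix grid is complete for up to 20
features and otherwise covers all $k \le 8$ plus a geometric ladder capped
at 150 features — the post-screen dimensionality this method targets is of
order $10^2$, and a complete scan is available via `ks = 1:D`.

## Stacking ensemble

Five tree-based base learners are used: a random forest (`rf`),
regularized extreme gradient boosting (`xgb`), a plain shallow-tree
gradient-boosting configuration (`gbdt`), discrete AdaBoost over decision
stumps (`ada`), and a stochastic gradient-boosting configuration with
row/column subsampling (`cat`) standing in for ordered boosting — the
learner ids are stable and the backends pluggable. Default
hyperparameters are deliberately modest (300 trees; 40–50 boosting rounds
at depth 3–4 with histogram splits; 40 stump rounds sampling up to 100
candidate features per round) so that the full pipeline runs in minutes on
one CPU; they are the package's own defaults, not tuned per dataset.

Each learner produces out-of-fold (OOF) probabilities under stratified
10-fold CV: a row's probability always comes from the fold model whose
training set excludes that row (the OOF fold structure is exposed and
asserted in tests). The five OOF columns feed a logistic-regression
meta-classifier; for inference the base learners are refit on the full
training data. Alternative combination rules are provided: majority
voting, simple averaging, and Bayesian model averaging with weights
$w_i \propto \max(\mathrm{AUC}_i - 0.5, \varepsilon)$ normalized to sum to
one — nonnegative, monotone in CV performance, and equal to simple
averaging when all AUCs agree. A super-ensemble comparator scores nine
candidate meta classifiers (LR, SVM, RF, decision tree, extremely
randomized trees, GBDT, AdaBoost, KNN, naive Bayes) by CV AUC on the OOF
matrix and keeps the best.

The pipeline's reported performance is the pooled 10-fold CV of the meta
classifier over the OOF matrix. If **no** group passes the screen, the
pipeline refuses to run subset optimization: an AUC-driven search over
thousands of null columns latches onto chance correlations and reports
clearly above-chance cross-validated performance even on shuffled
labels. Instead it stacks all learners on the full feature set — a
fixed, non-adaptive choice whose CV estimate remains honest — and warns.

## Evaluation

Threshold metrics (precision, sensitivity, specificity, balanced
accuracy, F1, accuracy, MCC) follow the standard confusion-matrix
definitions with the positive class = driver and classification strictly
above 0.5 (a score of exactly 0.5 is a passenger). Metrics with zero
denominators are reported as 0 and flagged. AUC uses the Mann–Whitney
rank statistic with averaged ties; AUPR uses step integration of the
precision–recall curve at distinct thresholds. The per-patient cumulative
effect risk (CER) is the sum of scores of predicted-driver variants
(score > 0.5 by default; summing all scores is available via
`mode = "all"`). Survival modelling on CER is intentionally out of scope —
the CER table is formatted for direct use with standard survival packages.

## The synthetic fixture and what it shows

`default_fixture_config()` fixes the study conditions: two 60-kb uniform
ACGT chromosomes; 200 drivers and 200 passengers; drivers placed where the
local 11-nt GC fraction is at least $0.5 + \delta/3$ and given C/G-biased
alternate alleles with probability $0.5 + \delta/2$ ($\delta = 0.6$);
passengers placed 120–500 bp away (far enough that windows never overlap)
with uniform alleles; annotation columns are class-shifted Gaussians
(effect 0.8 SD); recurrence is 1 for passengers and uniform on 7–20 for
drivers. The signal thus lives in sequence composition, in the mutation
spectrum *and* in the annotation block, so sequence-derived, difference
and annotation groups can all be screened meaningfully. With
$\delta = 0$ and zero annotation effect every feature is
class-independent.

Null diagnostics use `balanced_label_shuffle()`: a plain permutation has a
chance class-overlap correlation of order $1/\sqrt{n}$ with the true
labels, and strongly separable features amplify that into spurious
held-out signal well above the screen threshold; forcing exactly half of
each class to keep its label removes the confound while preserving class
counts.

What passing means — and does not mean: the fixture demonstrates that the
pipeline recovers planted signal (stack CV AUC ≥ 0.9) and stays at chance
with zero retained groups on shuffled labels. It does not emulate real
somatic mutation spectra, genuine shape/embedding physics, recurrence
distributions, or class imbalance, so measured AUCs say nothing about
performance on real tumour catalogues; retraining on real recurrence-
labelled variants with measured tables is the intended use.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive externally (VCF convention), 0-based
  inside windows. Windows that would overrun a contig end are an error —
  no padding — so silent truncation cannot corrupt the geometry.
* Difference direction is signed alt − ref (not absolute).
* Ties in importance rankings break by column order; prefix-search ties
  break toward the smallest subset; all CV folds are stratified and
  seeded, and every stage's seed derives deterministically from one root
  seed.
* The mRMR greedy order is computed exactly for the first 200 features and
  the remainder appended by relevance — prefix searches never look past
  the greedy depth.
* AdaBoost stump search is compiled (Rcpp) and samples at most 100
  candidate features per round, seeded, to bound cost on wide groups.
* Constant columns normalize to 0; all-missing columns impute to 0.
* Problem sizes used by the packaged tests and the acceptance script: 400
  variants × 8,007 features, 10-fold CV throughout; the end-to-end runs
  complete in a few minutes each on a single core.

## Known limitations

* The bundled shape/property/embedding tables are synthetic stand-ins;
  substitute measured tables (same TSV formats) for real analyses.
* The `cat` learner id is backed by a stochastic gradient-boosting
  configuration, not true ordered boosting.
* Only single-nucleotide substitutions are supported (no indels,
  multi-allelics, or liftover), and windows are taken on the forward
  strand only.
* The 39 basic-annotation scores are consumed from a table, never
  computed; absent variants are mean-imputed, which is conservative but
  can dilute annotation signal when coverage is poor.
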