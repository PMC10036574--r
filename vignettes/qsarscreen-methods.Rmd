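---
title: "Methods: ensemble QSAR classification and consensus screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble QSAR classification and consensus screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The modelling problem

The package addresses binary activity classification for virtual screening:
given compounds with measured IC50 against a target (the motivating case is
PIM-1, a serine/threonine kinase overexpressed in haematological and solid
cancers) and a numeric descriptor vector per compound, learn classifiers
that rank an external library so that experimental follow-up concentrates
on probable inhibitors. The central design commitments are (i) a *battery*
of four different learning algorithms combined by unanimity, on the view
that compounds passing every model are safer bets than the top of any
single ranking; and (ii) validation machinery — applicability domain and
y-randomization — treated as first-class outputs rather than afterthoughts.

## Curation

Activity is dichotomised at IC50 ≤ 1 μM (inclusive). A looser 10 μM cut
would declare far more compounds active than any screening campaign could
confirm, so the strict boundary deliberately trades recall for enrichment.
The boundary is a parameter (`boundary_um`); an optional `exclude_range`
drops an intermediate band (e.g. 1–10 μM) entirely for users who prefer a
buffer between classes. By default compounds above the boundary are kept as
inactives — discarding the 1–10 μM band shrinks the training set and, on
balanced synthetic data, did not change which descriptors are selected, so
the inclusive default is simpler.

Duplicate structures collapse to one record with the *median* IC50 of the
group. Aggregation beats deletion because discordant replicate assays are
common, and the median is robust to a single bad measurement;
`aggregate = "first"` restores plain deduplication. Structure
canonicalisation is a pluggable hook: the native path compares structure
strings verbatim, and a chemistry backend can be injected to canonicalise
SMILES or reject non-organic species. Records whose structures the hook
rejects are dropped and logged, never silently lost: every input id appears
in the output or in the removal log.

## Two-tier descriptor selection

**Tier 1 — correlation pruning.** Descriptor pairs with |r| > 0.85 carry
near-duplicate information; one member, chosen uniformly at random under a
caller-supplied seed, is dropped. Absolute correlation is used because
redundancy is sign-agnostic. The scan walks the upper triangle of the
correlation matrix in *sorted descriptor-name order*, resolving pairs
greedily; sorting makes the decision sequence, and hence the surviving
set, invariant to the column order of the input file. Zero-variance
descriptors (undefined correlation) are removed first with a warning.

**Tier 2 — Boruta.** The shadow-feature algorithm asks, per descriptor,
whether its importance is distinguishable from that of a provably
uninformative twin. Each iteration permutes every candidate column
(the *shadows*), fits a random forest on candidates + shadows, and
records a hit for candidates beating the *maximum* shadow importance.
After *n* iterations the hit count is referred to Binomial(*n*, ½)
two-sided at level α with Bonferroni correction across candidates:
significantly high counts are confirmed, significantly low counts
rejected, the rest tentative.

Implementation choices, in the package's own judgement where the
algorithm's published description leaves latitude:

* *Flat design*: all candidates stay in play for all iterations, with one
  test at the end, rather than progressively removing rejected features.
  This keeps hit counts exchangeable across descriptors, makes the whole
  run a pure function of (data, seed), and at the problem sizes the
  package targets (≤ a few hundred descriptors) costs little.
* *Importance*: impurity (Gini) by default — fast and adequate when the
  shadows provide the null reference; permutation importance is a flag.
* *Estimator*: `ranger` with 100 trees per iteration. Repeated fits
  dominate Boruta's cost; 100 trees already stabilise the max-shadow
  benchmark at n ≈ 400 compounds, and the iteration count (default 100,
  minimum 20) supplies the averaging.
* *Tentatives* are excluded from the `kept` set by default ("confirmed
  only"); `include_tentative` with the optional rough-fix (median
  importance vs median max-shadow) relaxes this.
* `alpha` shrinking provably never grows the confirmed set, which the test
  suite checks as a property.

## The four-model ensemble

Hyperparameters are fixed, deliberately un-tuned defaults: random forest
500 trees; XGBoost 300 rounds, depth 6, learning rate 0.1; SVM radial
kernel, cost 1, with Platt-style probability calibration (SVM margins are
not probabilities); kNN k = 5 with the inverse-distance-weighted active
vote fraction as the probability score. Descriptors are standardised with
training-set mean/SD inside the SVM and kNN paths, whose geometry is
scale-sensitive; tree models see raw values. A zero-distance neighbour in
kNN carries infinite weight, so an exact duplicate of a training compound
inherits that compound's label — in particular k = 1 reproduces the
training labels, which the tests use as a contract.

The probability rule is boundary-inclusive: p ≥ 0.5 ⇒ active, p < 0.5 ⇒
inactive. With an even k the kNN vote can land on exactly 0.5, and such
ties classify active by the rule. Consensus is hard-label unanimity —
active iff all four models call active — not probability averaging: the
screening funnel's first filter is defined in terms of "predicted active by
all models", and unanimity makes that filter exactly the intersection of
the four per-model active sets (a monotone, auditable criterion).

The train/test protocol is a stratified 80/20 split under a fixed seed.
The split ratio is a free parameter of the pipeline (`test_fraction`).

## Evaluation statistics

Precision TP/(TP+FP), recall TP/(TP+FN), accuracy (TP+TN)/n, and
F1 = 2PR/(P+R). Zero-denominator cases are reported as *undefined with a
reason* rather than coerced to 0, because a classifier that predicts no
actives has no precision, not zero precision. AUC uses the midrank
Mann–Whitney identity, which equals the trapezoidal area under the
empirical ROC curve and admits an exact all-pairs oracle; the test suite
checks agreement to 1e-12. The cumulative gain curve sorts by score
descending with a stable tie-break on input order, so `gain(1) = 1`
exactly. Outcome-stratified probability summaries (TP/TN/FP/FN means and
quartiles) diagnose *how confidently* a model is right or wrong.

## Applicability domain

The AD is fitted by PCA on the standardised training descriptors and
realised as an axis-aligned bounding box on the first `n_components`
(default 2) component scores, optionally expanded by `margin` × range per
side. A box rather than a convex hull or leverage criterion because it is
deterministic, cheap at any dimensionality, monotone in the margin (the
tests verify widening the margin never expels a compound), and matches the
way PC1/PC2 chemical-space overlap is argued visually. Its known
weakness is over-admission in the box's corners — regions inside every
univariate bound but far from any training point; users screening highly
clustered libraries should raise `n_components`.

## Y-randomization

Each of `n_runs` (default 500) runs draws ⌈fraction · n⌉ training
compounds without replacement (default fraction 0.5), permutes the labels
*within the drawn subset*, retrains with the identical configuration —
including the training seed, so the only difference from the reference
model is the scrambled data — and records accuracy and AUC on the
untouched held-out test set against true labels. Evaluating on the test
partition (rather than resubstitution on the scrambled training set) is
the stricter reading: it measures whether chance correlations generalise,
which is the question the test exists to answer; a cross-validated
train-set variant can be built from the exported pieces. Per-run seeds are
`master_seed + run_index`, so any individual run can be reproduced in
isolation. A drawn subset that is single-class is redrawn and counted in
`n_redraws` (labels of a single class cannot be meaningfully permuted).
Because the degenerate run — full resample, no permutation — is exactly the
reference protocol, the implementation reuses one train-and-score helper
for both, and the test suite asserts the equality.

For balanced classes the scrambled accuracy distribution is centred at
0.5; the package's acceptance checks require the 500-run mean to stay
below 0.58 and the reference model to beat every scrambled run.

## Fingerprint analysis

Fingerprints are 166-bit structural keys consumed as precomputed bit
tables (CSV of 0/1 columns or 42-character hex strings); generating keys
from structures is delegated to an optional chemistry backend so the
package itself needs no toolkit. Tanimoto similarity Tc = C/(A+B−C) is
computed vectorised via a bit-matrix cross product; the all-zero/all-zero
pair, formally 0/0, is defined as 0 with a warning — the conservative
choice for novelty annotation, where unknown similarity should not promote
a hit. Per-class bit frequency is the percentage of class members with the
bit on; differential bits are ranked by active-minus-inactive difference
with a default cutoff of 10 percentage points ("reasonable difference" is
inherently a judgement call; the cutoff is a parameter).

## Screening funnel

Filter 1 consensus-active; Filter 2 ensemble probability ≥
`probability_threshold`; Filter 3 inside the AD; final pass = conjunction.
The Filter 2 statistic is the mean of the four probabilities by default
(symmetric treatment of the models) with a per-model-minimum mode
(`filter2 = "min"`) for stricter campaigns; the default cutoff is 0.5, and
because reported screening hits in this domain typically carry per-model
probabilities ≥ 0.6, a stricter preset is reasonable and directly
configurable. Hits are ranked by mean ensemble probability, descending,
ties broken by compound id for a total, reproducible order. Novelty is the
maximum Tanimoto similarity to the training actives; ≤ 0.5 flags a
structurally novel scaffold. Missing library fingerprints degrade to `NA`
annotations with a log entry — novelty is an annotation, not a filter.

## The synthetic-data generator

The generator emulates the *statistical* structure a curated QSAR table
presents to the pipeline, with defaults fixed at the package's study
conditions: 200 active + 200 inactive compounds; 54 descriptors of which
5 are informative (standard normal shifted by Cohen's d = 2 in actives),
45 pure noise, and 2 pairs correlated at ρ = 0.9 via
x₂ = ρx₁ + √(1−ρ²)ε (so the >0.85 pruning filter always has work to do);
10 fingerprint bits enriched in actives (on-probability 0.8 vs 0.4) over a
0.3 background; IC50 drawn log-uniformly on the label-consistent side of
the 1 μM boundary. Structure strings are opaque unique identifiers.
All sampling is Mersenne-Twister, locally seeded: one seed reproduces a
dataset bit-for-bit without touching the caller's RNG state.

What it does **not** emulate — and therefore what passing tests do not
show about real data: descriptor distributions are Gaussian and
independent apart from the planted pairs (real descriptor blocks are
heavy-tailed, discrete, and massively collinear); fingerprint bits are
independent Bernoulli (real substructure keys are logically nested);
actives occupy no special region of descriptor space beyond the mean
shift (no activity cliffs, no scaffold clustering); and the screening
library's out-of-domain compounds are a uniform global shift rather than
chemically distinct series. The generator validates the machinery —
selection recovers planted signal, the AD excludes planted outliers, the
funnel composes correctly — not the chemistry.

## Problem sizes and numerical choices

The test and acceptance workloads run at the study conditions: 400
compounds × 54 descriptors for the 500-run y-randomization; 20 seeds ×
100 Boruta iterations (plus 20 permuted-label controls) for selection
recovery; exhaustive confusion-matrix enumeration to n = 30; 100-pair and
200-draw oracle comparisons for Tanimoto and AUC. Smaller fixtures
(120–300 compounds, ≤ 17 descriptors) back the unit tests. Other
numerical details: PCA rank is assessed at a 1e-8 relative singular-value
tolerance; probabilities returned by backends are clamped to [0, 1];
XGBoost runs single-threaded so results are bit-reproducible; all seeds
are plain 32-bit integers.

## Known limitations

* The box AD over-admits corner regions (see above) and, like any PCA
  domain, ignores descriptor directions beyond `n_components`.
* Platt calibration inside the SVM uses internal cross-validation; its
  probabilities are reproducible under a fixed seed but not smooth in the
  training data.
* Boruta's flat design can leave borderline descriptors tentative where
  the original iterative variant would re-test them against a shrunken
  shadow pool; raising `n_iterations` tightens the binomial test.
* Consensus unanimity is conservative by construction: a library compound
  missed by any single model is lost, which is the intended trade-off for
  screening precision, not a bug to tune away.
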