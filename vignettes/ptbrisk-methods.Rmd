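---
title: "Methods: entropy-based feature selection and preterm-birth risk classification"
author: "ptbrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based feature selection and preterm-birth risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbrisk)
```

## The problem and the model

`ptbrisk` classifies pregnancy records into term birth (label 0) and preterm
birth (PTB, label 1; delivery between the 28th and 37th week of gestation,
the positive and minority class). The pipeline has three stages: data
ingestion and validation; preprocessing (imputation, discretization, feature
selection); and model fitting with confusion-matrix evaluation.

The methodological core is a filter-method feature selector built on class
entropy. Writing $p_m$ for the proportion of instances of class $m$ in an
instance set $S$,

$$\mathrm{Entropy}(S) = -\sum_m p_m \log_2 p_m,$$

with $0 \log_2 0 \equiv 0$, and the information gain of a discrete feature
$A$ whose values $v_j$ partition $S$ into $S_{v_j}$ is

$$\mathrm{Gain}(S, A) = \mathrm{Entropy}(S)
  - \sum_j \frac{|S_{v_j}|}{|S|}\,\mathrm{Entropy}(S_{v_j}).$$

(The entropy is implemented with the conventional negative sign; the
sign-free variant sometimes seen in print would make entropy negative.)
The dataset is partitioned into three disjoint subsets; in each, every
candidate feature is scored and a *range threshold*

$$r = \frac{\max_i \mathrm{Gain}(S, A_i) - \min_i \mathrm{Gain}(S, A_i)}{n}$$

is formed, where $n$ counts the candidate features actually scored —
identifier and target columns are excluded by role, since a patient-id
column would otherwise contribute a maximal spurious gain to the numerator.
Features with gain strictly below $r$ are removed (a gain exactly equal to
$r$ is kept, matching the strict-inequality removal rule); the three
surviving sets are united, $F = F_1 \cup F_2 \cup F_3$. Because the cut is a
threshold on gain, every removed feature scores below every kept feature
within a subset (the monotone-cut invariant), and $F$ contains each $F_k$ by
construction. Scoring is a single pass over features, so the filter is
linear in the feature count.

Two properties of this design are worth keeping in mind. First, $r$ adapts
to the gain spread: one dominant feature (here, gestational age) raises $r$
and prunes aggressively, while a flat gain profile yields $r \approx 0$ and
keeps everything — including the degenerate all-tied case, where nothing is
below $r$ and $F = F_0$. Second, the union is deliberately inclusive: a
feature needs to clear the threshold in only one of the three subsets, so
the union retains strictly more noise than any single subset does. The tests
assert noise removal at the level this construction actually delivers.

## How the subsets are formed

How the three subsets arise is an open design point; the package uses a
seeded, stratified three-way split: within each class, row indices are
permuted and dealt round-robin, giving subset sizes equal within one row per
class and preserving the class ratio. This guarantees each subset sees both
classes (an all-one-class subset would score every feature 0) and makes the
partition a pure function of the seed. Gains are recomputed independently
per subset, never pooled.

## Preprocessing

Missing cells are imputed before discretization, in that fixed order.
Numeric features receive the mean of observed values — which leaves the
column mean unchanged — and ordinal/binary/categorical features, for which a
mean is undefined, receive the mode, ties broken toward the smallest value
for determinism. Observed cells are never altered; a fully missing feature
or a missing target is an error, not a guess.

Discretization maps each numeric feature to interval codes $0..k-1$ with
half-open intervals $[a, b)$ — a value equal to a boundary goes up — and
open outer intervals covering the whole line. The default method is a
supervised minimum-description-length search in the Fayyad–Irani style:
candidate cuts are midpoints between adjacent distinct values with differing
class labels, the entropy-minimising cut is accepted when its gain exceeds
$(\log_2(N-1) + \Delta)/N$, and the search recurses into both sides. A
feature that earns no cut collapses to a single bin, which downstream
scoring treats as zero-gain — harmless. Equal-width and equal-frequency
binning (default 5 bins, clamped to the number of distinct values with a
warning) are available where an unsupervised map is preferred. Applying a
map marks the feature ordinal, so re-application is the identity.

## Class balancing

The cohort is imbalanced (about 24% preterm), so the training signal is
dominated by term births. The balance stage oversamples the minority class
to a target fraction (default 0.5). The default mechanism is SMOTE: a
synthetic row interpolates between a random minority row and one of its
$k = 5$ nearest minority neighbours (Euclidean distance on the ordinal
codes), with integer-coded features rounded half-up back to valid codes —
so synthetic rows stay inside the minority's observed envelope. A
`duplicate` mode implements the literal-replication reading instead. Both
modes add only minority rows and never touch existing ones.

Where balancing happens matters. Balancing the full dataset *before* the
70/30 split (`balance_mode = "paper"`) leaks interpolated copies of
training-set neighbours into the test set and flatters accuracy; the package
defaults to `balance_mode = "train-only"`, which balances the training
partition after the split. Both modes are first-class and logged, because
the comparison between them is itself informative: across seeded synthetic
replicates, full-dataset balancing raises SVM accuracy relative to no
balancing in the majority of runs — the direction the balanced-versus-
original comparison is expected to show — and the acceptance suite asserts
exactly that direction, not any particular accuracy value.

## Classifiers and metrics

The 70/30 split is stratified (training size exactly
$\mathrm{round}(0.7 n)$, per-class counts within one row of proportional).
Three classifier families are exposed behind one surface: recursive
partitioning (`rpart`), binary logistic regression (`glm`, class 1 when the
fitted probability exceeds 0.5), and an RBF-kernel SVM (`e1071`).
Hyperparameters default to those implementations' documented defaults and
are echoed into the run manifest; the package pins no bespoke settings.

Evaluation fills the confusion matrix with PTB (label 1) as positive and
reports CCR (accuracy, percent scale), TPR/sensitivity, TNR/specificity,
FPR, FNR, precision, recall and F1. Recall is $TP/(TP+FN)$, identical to
TPR — the variant formula $TP/(TN+FN)$ occasionally seen in print is a
typographical error and is not implemented. A metric with a zero
denominator is reported as `NA` and flagged in `undefined`, never silently
as 0. Classifier accuracy is *not* asserted to beat the majority-class
baseline — that can legitimately fail — but the baseline is always logged
beside the reports.

## The synthetic cohort generator

No public cohort of this shape exists, so the generator is a first-class
module, not a test fixture. Its defaults emulate the study conditions the
pipeline targets: 1300 records, a 36-feature schema (patient id, 34
candidates, binary PTB target), minority prevalence 0.238 (309 preterm),
and class-conditional sampling for six planted features — GA (4 ordinal
gestational-age bands, population gain ≈ 0.44 bits; gestational age is
near-definitional for preterm birth, hence the dominant signal), BP, HB
(3-level ordinal, ≈ 0.13 and ≈ 0.12 bits), and the binary disorder
indicators PE, HT, PCS (≈ 0.13–0.15 bits). The remaining 28 candidates are
class-independent noise: mostly binary indicators at assorted base rates,
small ordinal scales, and three 12-level month codes (LMP/EDD/ADD) standing
in for date-derived fields — deliberate high-cardinality decoys whose
small-sample gain bias (roughly $(k-1)(c-1)/(2N\ln 2)$ bits) makes them the
features a gain filter most plausibly over-selects. Population gains were
fixed from the closed-form `expected_gain` (the mixture-entropy mutual
information) so that every planted feature clears 0.1 bits at the default
prevalence; sample gains converge to these values and the tests check that
convergence directly. All features are emitted as integer codes;
`raw = TRUE` adds sub-bin Gaussian jitter (sd 0.15) to numeric features so
the discretizer has real work. Missing cells are injected uniformly at a
configurable per-feature rate.

What the generator does *not* emulate: correlation between features within
a class (everything is class-conditionally independent), measurement error
structure, site or temporal effects, and any clinically calibrated marginal
distributions — the planted distributions are labelled fixtures. Passing
recovery tests therefore show that the filter finds well-separated
class-dependent signal among independent noise at this sample size; they do
not show robustness to collinear clinical features, which is a known
limitation of gain-based filters.

## Numerical and design choices

* Entropy and gain are plain double-precision sums; gains match an
  independent first-principles oracle to $10^{-12}$ over every 2-class,
  ≤ 3-value, ≤ 8-row contingency table.
* Boundary ties in discretization go to the upper bin; imputation mode ties
  go to the smallest value; threshold ties in selection are kept. All three
  are arbitrary but fixed, chosen for determinism.
* All randomness flows from one root seed, split per stage by fixed labels
  (`derive_seed`), so a single integer reproduces partitioning, splitting,
  balancing and generation; `withr::with_seed` keeps the global RNG state
  untouched.
* Feature selection runs on the full preprocessed dataset by default —
  matching the staged workflow in which Stage-II selection precedes the
  Stage-III split — with `select_on_train = TRUE` as the leakage-safe
  option. The default is faithful to the workflow being implemented; the
  flag exists because selecting on all rows lets test-set labels influence
  the selected set.
* Problem sizes in the test suite (cohorts of 300–1300 rows, 20-replicate
  studies, $10^4$ random property tables, one $10^5$-row convergence check)
  were chosen so the full suite completes in a few minutes on one CPU while
  keeping Monte-Carlo noise far from the asserted margins.

## Known limitations

The range threshold $r$ has no statistical calibration — it is a heuristic
of the gain spread, and with one dominant feature it can prune moderately
informative features; conversely it never removes anything when gains tie.
The union across subsets trades precision for recall of features.
Mean imputation distorts within-class distributions under informative
missingness. The SVM/LR treat ordinal codes as numeric scores. None of the
reported synthetic accuracies transfer to any real cohort; they
characterise the pipeline, not the epidemiology.
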