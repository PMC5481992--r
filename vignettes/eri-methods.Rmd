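---
title: "The Early Response Index: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Early Response Index: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eriselect)
```

## The problem

At the earliest stage of a disease process most truly involved molecules
have shifted only slightly — often well below what per-feature
differential-expression statistics flag at a controlled false-positive
rate. Such "early responder" proteins or genes are exactly the candidates
one wants for early diagnosis, and exactly the ones a t-statistic ranking
drowns in noise.

The Early Response Index (ERI) attacks this from the classification side.
For two features $F_i$, $F_j$, let $\mathrm{Acc}(F_i)$ and
$\mathrm{Acc}(F_i, F_j)$ be the cross-validated accuracies of a classifier
trained on the single feature and on the pair. The improvement score of
the pair is

$$\mathrm{IS}(F_i,F_j) \;=\; \mathrm{Acc}(F_i,F_j) \;-\;
  \max\!\left[\mathrm{Acc}(F_i),\,\mathrm{Acc}(F_j)\right],$$

the accuracy gained over the better single feature, and a feature's ERI is
its average improvement score over all $N-1$ partners:

$$\mathrm{ERI}(F_i) \;=\; \frac{\sum_{j \ne i}\mathrm{IS}(F_i,F_j)}{N-1}.$$

A feature scores highly not by being discriminative on its own but by
*consistently helping other features classify*. This is deliberately
different from synergistic subset-selection methods that hunt for the
single best-performing feature subset: ERI is an average over all
pairings, so weak-but-consistent contributors surface even when no single
pairing is spectacular. Negative improvement scores (pairings that hurt)
are kept in the average; flooring them at zero would bias every ERI
upward.

## Accuracy estimation

Accuracies are estimated by stratified 5-fold cross-validation repeated 5
times (defaults; both are configurable via `cv_config()`). One fold plan
is drawn per run and reused for every single feature and every pair, so
differences between $\mathrm{Acc}(F_i,F_j)$ and its component singles
reflect the features, not fold noise, and a run is reproducible from its
seed. Folds are stratified because unstratified splits of a 40-sample
design can produce single-class test folds on which accuracy is undefined.
Accuracy is plain fraction-correct: the designs this targets are
near-balanced, and fraction-correct keeps the estimate an unweighted mean
over samples.

The default classifier is a linear-kernel soft-margin SVM with $C = 1$,
each feature z-scored with training-fold mean and SD (the constants are
then applied to the held-out fold; the test fold never leaks into the
scaling). With one or two features and a few dozen samples this is about
as bias-free and reproducible as a classifier gets. An RBF kernel
(`svm_rbf`, default $\gamma = 1/p$) is available for non-additive pair
geometries, and naive Bayes and random forest plug-ins exist for
sensitivity analysis — the package's own checks show the XOR-style pair
geometry where the RBF pair succeeds while the linear kernel stays at
chance.

The SVM itself is solved by a compiled sequential-minimal-optimization
routine (most-violating-pair working-set selection, stopping tolerance
$10^{-3}$) with the whole repeated-CV loop batched in C++. A full pairwise
sweep is $N(N-1)/2$ pair evaluations of 25 fits each — at $N = 300$
(the default prefilter size) that is over a million SVM fits per run, and
permutation thresholding multiplies this by the trial count, so per-fit
overhead dominates wall time. The test suite cross-checks the solver's
decision values and predictions against an independent SVM implementation
(`e1071`, the libsvm binding) on randomized fixtures.

Degenerate inputs never abort a sweep: a training fold in which the
selected features are constant falls back to predicting the training-fold
majority class, with ties resolved to the class listed first in the label
file. On a balanced design a constant feature therefore scores exactly
0.5, reproducibly.

## Prefiltering

All-pairs evaluation is quadratic, so features are first ranked by the
absolute Welch two-sample $t$ statistic and the top $k$ (default 300)
kept. Welch rather than pooled-variance $t$ is the safer default for
expression data; with equal per-class sample sizes per feature the
ordering by $|t|$ is the practical equivalent of ordering by $p$-value.
Ties break lexicographically by feature id so runs are deterministic. The
$N$ in the ERI denominator is the post-prefilter feature count — ERI is
defined among the features that actually enter the pairwise sweep.

## Significance at 0% false-positive rate

The cutoff is estimated by label permutation: permute the class labels,
rerun the *entire* pipeline — including the prefilter, which must also see
permuted labels or the null maximum is understated — and record the
maximum ERI any feature achieves; repeat 10 times (default) and take the
overall maximum. Features at or above this value (the comparison is
inclusive) are called significant. Since no permuted feature reached the
cutoff, it is a 0%-FPR threshold in the permutation sense. By default the
cutoff is the exact observed maximum; `rounding = "ceil_3dp"` rounds it up
to the next 3-decimal value for reporting (a null maximum of 0.0258
becomes a cutoff of 0.026).

Each trial uses seed `base_seed + trial`, for the permutation and for that
trial's fold plan, so the 10-trial experiment is one reproducible object.
Whether the null trials should reuse the observed run's fold plan is
genuinely open; independent per-trial plans were chosen because the
permuted data are new datasets in every other respect.

If the observed labels are exchangeable with the permuted ones (i.e. no
real signal), the observed maximum is an 11th draw from the same
distribution as the 10 null maxima, so the chance that *any* feature is
falsely called is about $1/11$ per dataset. The acceptance suite measures
this directly: across 50 null replicates the fraction with at least one
call must stay at or below 20%.

## The synthetic generator

`simulate_expression()` encodes the early-disease regime as its defaults:
100 Gaussian features, 20 + 20 samples (two time points of ~20 animals),
10 responders shifted by 0.8 within-class SD — a shift weak enough that
single-feature accuracy sits near 0.6. Optional block correlation
(shared latent factors) mimics co-regulated panels. What the generator
does *not* emulate: heavy-tailed abundance distributions, feature-count
scales of real proteomes, batch structure, or correlated missingness —
passing tests show the machinery is correct under the stated model, not
that real data will behave as nicely.

`simulate_peptide_table()` emulates the reporter-channel design the
preprocessing chain targets: 6 channels per run, channels 1 and 6
measuring a pooled reference, peptide abundance = protein ratio ×
peptide response factor × channel bias × lognormal noise, with duplicate
identifications (a row split in two) and missing cells injected at stated
rates. One deliberate choice: by default (`channel_balanced = TRUE`) every
informative channel carries the same multiset of true ratio profiles
across runs, in channel-specific order. This is the exact finite-sample
counterpart of randomized channel assignment — the very argument that
justifies cross-channel quantile normalization — and it is what makes the
noiseless chain invert to the true ratios *exactly* rather than
approximately. Set `channel_balanced = FALSE` for independent ratios when
exact inversion is not the point.

## Preprocessing chain

The chain is: sum-merge repeated identifications of a peptide within a
run; divide each informative channel by the mean of the present reference
channels (rows with no present reference are dropped and counted — no
pseudo-counts are ever substituted); quantile-normalize the
informative-channel ratio columns, pooled across runs by default (channel
assignment is randomized across runs, so pooling matches the purpose of
removing channel effects; per-run normalization is available); take the
protein-level value as the median over the protein's unique peptide ratios
in each run/channel (even counts: mean of the central pair); drop proteins
observed fewer than `min_observed` times (default 12, chosen for 18-20
sample designs) and impute remaining gaps by sampling uniformly with
replacement from the same row's observed values under an explicit seed.
Ratios stay on the natural scale through rollup; `log2_transform` is
available downstream. Quantile normalization delegates to
`limma::normalizeQuantiles(ties = TRUE)`, whose rank-mean-with-
interpolation treatment of unequal column support is the standard
definition.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes a
single core handles in minutes, chosen as the package's own validation
scale: formula exactness on 6–10-feature stores; workload and invariance
at 30 features; FPR control on 50 null replicates of 100 features (20+20
samples) prefiltered to 30, 10 permutation trials each; sensitivity on 20
seeds of the 10-of-100 planted design; preprocessing inversion on
25–30-protein, 4–5-run tables.

## Known limitations

* **Power of the 0%-FPR cutoff under weak independent effects.** ERI
  ranks weak coordinated responders well ahead of nulls (the rank-sum
  check passes decisively), but the max-of-10-trials cutoff is a stringent
  order statistic: with 10 *independent* responders shifted by 0.8 SD in a
  20 + 20 design, a responder's ERI is an average of a few positive
  improvement scores diluted by many near-zero ones and typically sits
  below the null maximum, so few or no planted features are called
  significant. Raising the effect does not help — a strongly shifted
  feature classifies well alone, its pairings cannot improve on it, and
  its ERI *falls*. ERI calls are plentiful only in the regime it was
  designed for: many mid-strength, complementary features whose pairwise
  combinations beat their singles. The acceptance script reports the
  measured recovery percentage rather than hiding it.
* Two-class contrasts only; multi-class designs must be reduced to a
  binary contrast first.
* The pairwise sweep is quadratic in the post-prefilter feature count;
  $k$ much beyond a few hundred is costly, which is why the prefilter is
  part of the method.
* The permutation null reruns the full pipeline per trial, so thresholding
  costs `n_trials` times the observed run.

## Reproducibility

Every randomized stage (fold plans, permutations, imputation, simulation)
takes an explicit integer seed, and all derived seeds are deterministic
functions of it; a run is bit-reproducible from `(input, config, seed)`
regardless of the worker count used for the pairwise sweep. The
command-line layer writes a manifest (seeds, input hashes, stage counts)
sufficient to re-run any result identically.
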