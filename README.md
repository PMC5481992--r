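# eriselect

Early-stage biomarker prioritization for two-class omics data by the
**Early Response Index (ERI)** — a per-feature statistic measuring the
average cross-validated classification-accuracy improvement a feature
contributes when paired with every other feature — with a
label-permutation cutoff at 0% false-positive rate, plus the
peptide-to-protein preprocessing chain for isobaric (TMT-style)
reporter-channel quantification and a synthetic-data generator that makes
every stage testable without external data.

## Who this is for

Proteomics and transcriptomics analysts looking for molecules that respond
*early* in a disease course, when abundance shifts are still too small for
conventional differential-expression statistics (moderated t, SAM-style
permutation scores) to flag, but consistent enough to improve a
classifier when combined with other features.

## The statistic

For features $F_i$, $F_j$ with repeated-CV classification accuracies
$\mathrm{Acc}(F_i)$ (single) and $\mathrm{Acc}(F_i, F_j)$ (pair):

```
IS(Fi, Fj)  =  Acc(Fi, Fj) - max[Acc(Fi), Acc(Fj)]
ERI(Fi)     =  sum_{j != i} IS(Fi, Fj) / (N - 1)
```

Accuracies come from a linear-kernel SVM (C = 1, training-fold
standardization) under stratified 5-fold CV repeated 5 times on one shared
fold plan; features are prefiltered to the top *k* = 300 by |Welch t|
before the quadratic pair sweep. The significance cutoff is the maximum
ERI observed across 10 full-pipeline label-permutation trials; features
with `ERI >= cutoff` are called significant (inclusive comparison). The
inner SVM is a compiled SMO solver (cross-checked against `e1071` in the
tests), so a full sweep plus permutation thresholding runs in minutes.

## Worked example

```r
library(eriselect)

# 100 features, 20 + 20 samples, 10 weak responders (0.8 SD shift)
sim <- simulate_expression(n_features = 100, n_per_class = 20,
                           n_responders = 10, effect_size = 0.8, seed = 1)

sel <- eri_select(sim$expression, sim$labels,
                  cv_config(seed = 1), k = 30, n_trials = 10)
sel
#> <eri_select> 0 of 30 features significant at ERI >= 0.03052 (10 permutation trials)

head(tidy(sel), 3)
#> # A tibble: 3 x 4
#>   feature_id    eri  rank significant
#>   <chr>       <dbl> <int> <lgl>
#> 1 F0008      0.0295     1 FALSE
#> 2 F0003      0.0160     2 FALSE
#> 3 F0001      0.0129     3 FALSE

glance(sel)[c("n_features", "n_pair_evals", "cutoff", "n_significant")]
#> # A tibble: 1 x 4
#>   n_features n_pair_evals cutoff n_significant
#>        <int>        <int>  <dbl>         <int>
#> 1         30          435 0.0305             0
```

`eri_select()` scored the 30 prefiltered features (435 pair evaluations,
each 5x5-fold CV), set the cutoff to the largest ERI seen in 10
permutation trials, and — on this seed — called nothing significant: the
planted 0.8-SD shifts are real but sit below a 0%-FPR threshold, though
responders still dominate the top ranks (see the methods vignette on the
power of the max-null cutoff). `autoplot(sel)` draws the rank/score curve
with the cutoff; `autoplot(sel$null)` shows the permutation null.

For raw reporter-channel data, `preprocess_peptides()` runs
duplicate-peptide merging → reference-channel ratios → quantile
normalization → median protein rollup → missing-value filter/imputation,
returning the expression table the selector consumes. Both layers are
scriptable from a shell via `inst/scripts/eri-select`
(subcommands `simulate`, `preprocess`, `eri`, `threshold`, `select`).

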