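# consensusprio

Consensus disease-gene prioritization from case/control expression
matrices, with early-recognition evaluation metrics borrowed from
virtual screening.

## The problem

Transcriptome studies of complex disease produce thousands of candidate
genes, but downstream validation can afford only a handful. Individual
prioritization principles disagree: differential expression ranks genes
by mean shift, machine-learning classifiers find small discriminative
panels, and weighted gene co-expression networks (WGCN) find coherent
transcriptional modules. `consensusprio` implements a stringent
consensus of the three streams, plus the statistical and
early-recognition machinery to judge whether the resulting short list is
worth the follow-up cost.

## The method

A gene enters the consensus only if it is

1. **significantly differential** — moderated *t* with empirical-Bayes
   variance shrinkage (posterior variance
   (d₀s₀² + d·s²)/(d₀ + d), prior fit by method of moments on log
   variances) and Benjamini–Hochberg control, adjusted *p* < 0.05;
2. **selected by the ML stage** — greedy mRMR reduction on 3-state
   discretized expression, then a ranker ensemble mapped through the
   linear desirability d(R) = (R_max − R)/(R_max − 1) and a classifier
   panel with embedded feature selection, where a classifier is valid
   only if accuracy, sensitivity and specificity exceed 0.6 on
   training, LOO CV, 5-fold CV and a held-out test set; gene relevance
   is MLrel = (D(Rank) + d(Class))/2 with
   d(Class) = (N_rel − 1)/(N_class − 1);
3. **a member of a prioritized WGCN module** — unsigned |cor|^β
   adjacency (β = 6 by the scale-free criterion), average-linkage
   clustering of 1 − TOM, branch selection by height percentile, size
   and separation gap, and module prioritization by connectivity
   (⟨k⟩, ⟨k_intra⟩), expression shift ⟨log case − log control⟩ and
   merit = (n_in/n_sel)/(n_module/N) against the other two streams.

Survivors are ordered by **min/mean rank fusion**: ascending minimum of
the DE and ML ranks, then their mean, then gene id.

Validation: hypergeometric upper-tail tests, a bootstrap resampling
null (fold-enrichment = observed hits / mean null hits, TP rate),
Wilcoxon signed-rank comparisons of rankings, and early-recognition
metrics on randomized-tail evaluation rankings — AUAC, ROC area,
EF_χ, RIE and BEDROC at χ = 1/5/10/20 % (α = 160.9/32.2/16.1/8).

## Worked example

Everything below runs on a synthetic dataset with planted structure —
three co-expression modules (intra-module correlation 0.8), 60
differentially expressed genes inside them, and a flagged "known" set
of 40 planted genes plus 35 decoys:

```r
library(consensusprio)

d <- generate_dataset(synthetic_spec(), seed = 1)
fit <- consensus_pipeline(d$expr, d$labels, mrmr_k = 100,
                          known = d$known, seed = 1)
fit
#> consensus pipeline: 54 DE genes, 64 ML genes, 3 selected module(s), 32 consensus genes

head(fit$consensus, 5)
#> # A tibble: 5 × 6
#>    rank gene_id rank_de rank_ml key_min key_mean
#>   <int> <chr>     <int>   <int>   <int>    <dbl>
#> 1     1 g0200         2       1       1      1.5
#> 2     2 g0195         1       3       1      2
#> 3     3 g0017        24       2       2     13
#> 4     4 g0190         3      13       3      8
#> 5     5 g0192         4       5       4      4.5
```

The 32-gene consensus keeps 14 of the 75 flagged genes. The bootstrap
null says a random 32-gene draw would keep about 1.4:

```r
sig <- bootstrap_enrichment(d$expr$gene_id, d$known, n = 32,
                            observed_m = 14, reps = 100, seed = 1)
#>       N     K     n     m hypergeom_p boot_mean fold_enrichment tp_rate
#>    2000    75    32    14    8.71e-13      1.39            10.1   0.438
```

so the consensus is ~10-fold enriched (TP rate 44%) with a
hypergeometric p of 9 × 10⁻¹³. Early recognition on the full-background
evaluation ranking (consensus head, randomized tail):

```r
ev <- build_evaluation_ranking(fit$consensus, d$expr$gene_id,
                               d$known, seed = 1)
glance(metric_report(ev))
#>    auac   roc bedroc_0.01 bedroc_0.05 bedroc_0.1 bedroc_0.2
#>   0.588 0.592       0.263       0.233      0.231      0.274
```

AUAC/ROC sit near 0.5 because >95% of the list is randomized tail; the
BEDROC values, driven by the head, are what a label-permutation null
cannot reach (its 95th percentile is ≈ 0.09 at χ = 0.05).
`autoplot(ev)` draws the accumulation curve; `autoplot(fit$de)` the
volcano plot; `autoplot(fit$module_report)` the module connectivity
overview.

A command-line front end over the same functions is installed under
`inst/cli/consensusprio.R` with subcommands `simulate`, `de`, `ml`,
`wgcn`, `consensus`, `evaluate` and `significance`.

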