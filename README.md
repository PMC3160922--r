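# vaforest

Computer-coded verbal autopsy (CCVA) in R: cause-of-death assignment from
dichotomous sign/symptom interview items using pairwise random forests
combined through rank normalization, with the chance-corrected evaluation
framework used to validate such methods.

## The problem

In settings without medical death certification, a *verbal autopsy* (VA) —
a structured interview with the family of the deceased about the signs and
symptoms preceding death — is often the only source of cause-of-death
information. Each death is a vector of dichotomous items (endorsed / not
endorsed / missing) plus, in validation studies, a gold-standard cause.
The task is twofold: assign a cause to each death (individual level) and
estimate the cause-specific mortality fractions, CSMF_j, of a population
(population level).

## The method

For a cause list of length N, the classifier trains one random forest per
unordered cause pair (one-vs-one coupling): n = 100 randomized decision
trees per pair, each grown on a bootstrap resample of the pair's
class-balanced training records, branching on the item (out of m = 5 random
candidates per node) that best separates the two causes by Gini impurity
decrease, with each pair restricted to the union of its two causes'
top-40 items by absolute Tariff score
(tariff(i,j) = (x_ij − median_j x_i·)/IQR_j x_i·, where x_ij is the
endorsement rate of item i among cause-j deaths).

Scoring a death tallies, per cause, the number of trees voting for that
cause, giving a Score Matrix whose rows sum to n·N(N−1)/2. Because
different causes' forests hand out systematically different score levels,
raw scores are not comparable across causes; the assignment step therefore
rank-normalizes each test score against the corresponding cause column of
the **Train Score Matrix** (the model's scores on its own training
records): rank = 1 + #(train scores strictly greater). The predicted cause
is the best-ranked one, and the k best-ranked causes give a top-k
(partial-cause) prediction.

Evaluation follows the standard chance-corrected framework:

- CCC_j = (C_j − 1/N)/(1 − 1/N), cause-specific sensitivity corrected so
  random assignment scores 0;
- PCCC(k) = (C(k) − k/N)/(1 − k/N) for top-k lists;
- CSMF accuracy = 1 − Σ_j |true_j − est_j| / (2(1 − min_j true_j));

measured across repeated cause-stratified 75/25 train/test splits in which
each test set's cause composition is resampled to a Dirichlet(1,…,1) draw,
so results are not artifacts of one CSMF composition. Summaries are medians
with distribution-free 95% uncertainty intervals.

A seeded synthetic generator (`va_simulate()`) produces gold-standard
labeled datasets with controllable cause separability (signal items per
cause, endorsement probabilities, signal overlap, missingness, optional
HCE items), so the entire pipeline is testable without access to a real VA
study.

## Worked example

```r
library(vaforest)

ds <- va_simulate(n_causes = 5, deaths_per_cause = 100, seed = 42)
ds
#> Verbal autopsy dataset: 500 deaths, 60 items (0 HCE), 5 causes
#> Deaths per cause:
#> cause01 cause02 cause03 cause04 cause05
#>     100     100     100     100     100

fit <- va_forest(ds, ntree = 100, m = 5, top_n = 40, seed = 42)
fit
#> Pairwise random-forest VA model
#>   causes: 5 (cause01, cause02, cause03, cause04, cause05)
#>   coupling: one_vs_one, forests: 10, trees: 1000
#>   ntree = 100, m = 5, top_n = 40, seed = 42

v <- va_validate(ds, n_splits = 5, seed = 42)
summary(v)
#> Validation summary (median [95% UI] across splits)
#>         metric median  lower upper n_splits
#>        avg_ccc 0.9881 0.9722     1        5
#>  csmf_accuracy 0.9917 0.9833     1        5
#>    ccc_cause01 1.0000 1.0000     1        5
#>    ...
#>        pccc_k1 0.9900 0.9800     1        5
#>        pccc_k2 1.0000 1.0000     1        5
```

`avg_ccc` is the across-cause average chance-corrected concordance per
split (1 = every death assigned its true cause, 0 = chance);
`csmf_accuracy` measures population-level CSMF recovery on the
Dirichlet-perturbed test compositions; `pccc_k2` is the chance-corrected
rate at which the true cause appears in the top-2 list. The default
synthetic preset is deliberately separable (8 signal items per cause
endorsed at 0.8 against a 0.1 background), so near-perfect recovery is the
expected behaviour; see the methods vignette for what this does and does
not demonstrate about real VA data.

A thin command-line front-end over the same functions is installed at
`inst/cli/vaforest` (subcommands `synth`, `train`, `predict`, `validate`).

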