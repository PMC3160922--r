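---
title: "Pairwise random forests with rank-based cause assignment: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise random forests with rank-based cause assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaforest)
```

## The model

A verbal-autopsy record is a vector of K dichotomous sign/symptom items.
Given a training set with gold-standard causes over a cause list of length
N, `va_forest()` builds one binary random forest per unordered cause pair
— N(N−1)/2 forests of `ntree` randomized trees each. This one-vs-one
("pairwise coupling") decomposition is preferred over a single multiclass
forest because VA cause lists are long and per-cause sample sizes small:
each binary problem is far better conditioned, and the item-reduction step
can be specialized to the pair.

Each pairwise forest is built as follows:

1. **Item pool.** Tariff scores are computed on the training data:
   `tariff(i, j) = (x_ij − median_j(x_i·)) / IQR_j(x_i·)`, where `x_ij` is
   the endorsement rate of item i among cause-j deaths and the median/IQR
   are across causes. The pair's item pool is the union of the two causes'
   `top_n` items by absolute tariff.
2. **Class balance.** The smaller cause's records are upsampled with
   replacement to the larger cause's count, so neither class dominates the
   vote structure of the trees.
3. **Trees.** Each tree is grown on a fresh bootstrap resample of the
   balanced records. At each node, `m` candidate items are drawn uniformly
   without replacement from the items not yet tested on that path; the
   candidate with the largest Gini impurity decrease is taken (right
   branch = endorsed, left = not). A node terminates as a majority-class
   leaf when it is pure, its pool is exhausted, or no candidate splits its
   records.

**Scoring and rank assignment.** A death's score for cause j is the number
of trees, across all pairs involving j, that vote j; each pair contributes
exactly `ntree` votes, so row sums are `ntree·N(N−1)/2` by construction
(the package's vote-conservation invariant). Raw scores are not comparable
across causes — a cause whose pairwise problems are easy accumulates
systematically higher tallies — so the model stores its **Train Score
Matrix** (scores of the final model on its own training records) and
converts each test score to a rank within the corresponding cause column:
`rank = 1 + #(train scores strictly greater)`. This is a nonparametric
whitening: each cause's test score is judged against that cause's own
training score distribution. The predicted cause is the best-ranked one;
the k best-ranked causes form a partial (top-k) prediction. A test score
equal to a training score takes the better rank; ties between causes on
rank are broken by higher raw score, then cause-list order.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `ntree` | 100 | trees per pairwise forest; vote resolution is 1/`ntree`, and 100 makes pair votes stable without inflating the (N(N−1)/2)-forest model |
| `m` | 5 | candidate items per node; small relative to the ~80-item pair pools, giving decorrelated trees in the usual random-forest way |
| `top_n` | 40 | Tariff-selected items per cause; removes low-information items so that random candidate draws usually contain signal |
| `coupling` | one_vs_one | `one_vs_all` trains N forests of cause-vs-rest instead; retained for sensitivity comparisons |
| `feature_pool` | pair_union | per-pair union of the two causes' top-`top_n` sets; `global_union` gives every pair the union over all causes |
| `balance` | TRUE | upsample the smaller class; downsampling would discard records |
| `method` (predict) | rank | `score` assigns the argmax raw score, the comparison variant |

Defaults are the selected operating point of the method; the variants
behind `coupling`, `feature_pool` and `method` exist so that the
sensitivity of results to these choices can be measured rather than
assumed.

## Validation design

`va_validate()` repeats, per split: (1) a cause-stratified 75/25
train/test partition (`ceiling(0.75·n_c)` per cause to train, at least one
to test); (2) model fitting — including Tariff selection — on the training
records only, so no test information leaks into item selection or trees;
(3) resampling of the test set, with replacement within cause, to the
composition given by a Dirichlet(1,…,1) draw (largest-remainder rounding,
total size preserved), so every split evaluates a different CSMF
composition and population-level metrics are not artifacts of the data's
original mix; (4) rank assignment and metrics: per-cause and average CCC,
PCCC(k), CSMF accuracy, and the per-cause (true, estimated) CSMF pair.
Causes absent from a resampled test set have undefined CCC and are
excluded from that split's average; a Dirichlet target for a cause with no
test records is reallocated proportionally and recorded.

Across splits the package reports medians with distribution-free 95%
intervals from the binomial order statistics of the sorted per-split
values (`median_ui()`); `va_csmf_regression()` summarises per-cause CSMF
tracking as OLS slope/intercept/RMSE of estimated on true fractions.

Reproducibility is structural rather than procedural: every tree consumes
a substream seeded by a hash of (cause-pair identity, tree index, run
seed), and each validation split by (split index, run seed). Identical
inputs give byte-identical serialized models and result files; permuting
the cause list permutes — but does not change — scores, because
substreams are keyed by cause identifiers, not list positions.

## The synthetic generator

`va_simulate()` emulates the structure of dichotomized VA data: each cause
endorses its `signal_items` designated items with probability `p_signal`
(default 0.8) against a `p_background` (0.1) noise floor; an `overlap`
fraction of signal items is shared with the next cause cyclically to
create confusable pairs; cells are masked missing at `missing_rate`; an
optional `hce_frac` of signal items is flagged as health-care-experience
items with their own endorsement strength, supporting the
include/exclude-HCE analyses. The desk-scale preset (5 causes, 60 items,
8 signal items per cause, 100 deaths per cause) is sized so a 20-split
validation completes in about half a minute on one CPU; the same harness
scales to 500 splits when wanted.

What the generator does *not* emulate: items are independent within cause
(real VA items co-endorse in syndromic blocks), endorsement probabilities
are homogeneous within the signal/background dichotomy, and there is no
site, recall-quality or free-text structure. Passing the package's
recovery tests therefore demonstrates correctness of the machinery —
separable causes are recovered, chance-level problems score near zero
concordance — not expected performance on real VA interviews, which is an
empirical matter for gold-standard datasets.

## Numerical and degenerate-input choices

- **Missing responses** are stored as `NA` but treated as "not endorsed"
  at tree branching and endorsement-rate time (`va_symptom_matrix()` is
  the single conversion point). Trees branch on "was endorsed"/"otherwise",
  so this is the conservative reading of a missing answer; the storage
  keeps the policy revisable.
- **Tariff IQR floor.** IQR across causes uses type-7 (linear
  interpolation) quantiles and is floored at 0.001: with short cause lists
  the quartiles of an endorsement-rate profile can collapse to zero even
  for a maximally informative item (e.g. endorsed for one cause of five
  only), and flooring keeps such items while a genuinely constant item
  still scores 0 through its zero numerator. Importance is |tariff|:
  strong negative deviations discriminate as well as positive ones.
- **Tie-breaks** are all deterministic and documented: equal Gini
  decreases go to the earlier item; leaf majority ties to the
  lexicographically earlier cause of the pair; equal ranks to the higher
  raw score, then cause-list order. Lexicographic orders use C-locale
  (radix) sorting so results do not depend on the session locale.
- **Tree guards.** Depth is bounded by the test-each-item-once-per-path
  rule; minimum node size is 1; conflicting duplicate vectors terminate as
  a majority leaf.
- **Train Score Matrix** is computed in-sample (the final model scoring
  all its training records). An out-of-bag variant would shift every
  column's distribution downward; since ranks are computed within columns,
  the in-sample choice is internally consistent and keeps the matrix a
  deterministic function of the fitted model.

## Known limitations

- **Chance-level problems score slightly below zero at small pool sizes.**
  With indistinguishable causes, the held-out test records are the
  complement of the training records within each cause's finite record
  pool. Items chosen for splits precisely because the training subset's
  endorsement rate looked extreme are therefore mechanically anti-extreme
  among the held-out records (at a 75/25 split, the held-out deviation is
  −3× the training deviation around the pool mean). The resulting
  own-cause prediction deficit makes the chance anchor's median average
  CCC sit a little below 0 rather than at 0 — visible in the
  `chance_median_average_ccc` value that `scripts/acceptance.R` computes —
  and the effect shrinks as per-cause record counts grow. It is a property
  of complement-split validation of overfitting classifiers, not of the
  chance correction itself.
- The per-split average CCC weights all causes equally, so causes given
  tiny Dirichlet mass contribute high-variance terms; medians across
  splits absorb most of this, at the cost of a small skew at desk-scale
  test sizes.
- Trees are grown in pure R; the desk-scale presets run in seconds-to-
  minutes, but 40+-cause lists with thousands of records would warrant a
  compiled tree grower.
- No probability calibration is attempted: ranks are ordinal, and the
  partial-cause lists should be read as ordered candidates, not as a
  posterior over causes.
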