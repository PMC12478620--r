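---
title: "Testing MCAR by projected classification: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing MCAR by projected classification: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The testing problem

Rubin's taxonomy distinguishes missingness mechanisms by what they may
depend on: MCAR (nothing), MAR (observed values only), MNAR (unobserved
values too). Only a consequence of MCAR is testable from data: that the
distribution of the *observed* margins is identical across missingness
patterns. That is the hypothesis this package tests; rejecting it refutes
MCAR, while failing to reject is consistent with MCAR (and, as with any such
test, cannot confirm it — an MNAR mechanism can leave observed margins
untouched).

Comparing all pattern groups jointly is hopeless in general: groups can be
small, patterns many, and each group is observed on a different subset of
variables. The device that makes the comparison tractable is a random
projection pair `(A, B)`:

* `A` — the feature projection. Only rows fully observed on `A` (the set
  `O(A)`) enter, so the classifier sees a complete submatrix.
* `B` — a disjoint label projection. Each row of `O(A)` is labelled by its
  missingness pattern restricted to `B`, collapsed to at most
  `size_resp_set` classes.

Under MCAR the labels carry no information about `X[O(A), A]`, so any
classifier's out-of-bag performance is at chance; under a violation, some
projections pair an informative label set with informative features.

## Statistic

For one projection pair, a probability forest (bagged probability trees;
every column of `A` a candidate split, so the only feature subsampling is
the projection itself) yields out-of-bag class probabilities `p̂_g`. The
per-class statistic is the difference of mean log-odds

U(g) = mean over class-g rows of log(p̂_g/(1−p̂_g)) − mean over the
remaining rows of the same quantity.

The log-odds of the true posterior equals the log density ratio between
class g and the mixture of the rest, up to a class-prior constant that
cancels in the difference, so U(g) estimates the *symmetrized*
Kullback–Leibler divergence between class g and that mixture. The
symmetrized form uses every row of `O(A)`, not only class g's, which
matters because single patterns can be rare. Two testable consequences
anchor the implementation:

* for a two-class projection, U(1) = U(2) exactly (an algebraic identity of
  the log-odds), and
* plugging the *true* posterior of two equal-weight Gaussian classes N(0,1)
  vs N(δ,1) into the statistic recovers δ², the closed-form symmetrized KL
  divergence of that pair.

Both are asserted in the test suite, the second with 2×20,000 oracle draws.
The per-projection statistic averages U(g) over classes with equal weights
(class-size weighting is a conceivable alternative; equal weights match the
"mean over classes" reading and are what the implementation uses), and the
pooled statistic Û averages N projection draws.

## Permutation null and validity

Labels are a deterministic function of the missingness matrix `M`, so the
exchangeability argument must permute `M` itself: L uniform row
permutations, *shared across all projections*. Permuting labels
independently within each projection would ignore that the same rows are
relabelled coherently across projections and does not hold the level. For
each permutation, each projection's rows keep their fitted out-of-bag
probabilities — no refitting — and are relabelled by the permuted pattern
rows; patterns that did not occur among the projection's original classes
have no probability column, so those rows join the complement of every
class. `O(A)` is *not* recomputed: forest predictions only exist for rows
actually observed on `A`, and permuting `M` cannot create data.

The p-value is the add-one form Z = (1 + #{l : Û⁽ˡ⁾ ≥ Û})/(L+1), with ties
counted as exceedances; this is the standard finite-sample-valid
permutation form, and its validity is independent of how well the forests
classify. L only discretizes the attainable p-values (minimum 1/(L+1)), so
it can stay small (default 30) while the projection count N (default 100)
does the statistical work.

Degenerate cells — a (projection, permutation) pair whose permuted labels
empty a class — are skipped rather than scored zero, because a hard zero
would shift the permutation distribution asymmetrically. A permutation
degenerate on *every* projection is redrawn once from a pre-drawn reserve
(so reproducibility is unaffected) and scored as an exceedance if still
degenerate, erring conservative.

## Partial p-values

For variable k, re-pool Û and each Û⁽ˡ⁾ over only the pairs whose label set
`B` excludes k, and recompute Z on that subset. If the violation stems from
variable j's missingness alone, the subset for k = j never uses j's
patterns as labels and behaves like a null test, while every other subset
retains them — so a high partial p-value singles out the culprit. Whether k
should also be excluded from the feature set `A` is genuinely open: labels
are what variable k "induces", so the default filter is B-only, with an
`"AB"` switch for the stricter reading. When no pair qualifies the entry is
reported as undefined rather than silently reusing the global test.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `num_proj` (N) | 100 | projection draws; more = lower Monte-Carlo noise in Û |
| `nperm` (L) | 30 | permutations; only sets p-value resolution 1/(L+1) |
| `num_trees_per_proj` | 200 | trees per forest; more = less forest noise in OOB probabilities |
| `min_node_size` | 10 | leaf-size floor; mild regularization of leaf frequencies |
| `size_resp_set` | 2 | class cap; binary projections proved most reliable, larger values trade accuracy for pattern granularity |
| `eps` | 1/(2·num_trees) | log-odds clip; the resolution of an OOB frequency, bounding each term by ≈ log(2·num_trees) without moving interior values |
| `min_rows`, `min_class_size` | 10, 2 | minimum data for a projection to be accepted; the forest needs rows and both statistic means need members |
| `max_attempts` | 300 | rejection-sampling budget; exhaustion signals an untestable missingness structure (e.g. a single pattern) |

Apart from `size_resp_set`, these follow "higher is better, pay in
compute". One user seed drives three independent child streams (projection
sampling, forests, permutations), so changing L does not change which
projections were drawn; forests run single-threaded with fixed seeds, making
the whole result object bit-reproducible.

## Projection sampling

Sizes first, uniformly — |A| on {1,…,p−1}, then |B| on {1,…,p−|A|} — then
the sets uniformly without replacement; the class-count cap is enforced by
redrawing the whole pair rather than merging classes. Duplicate pairs across
the N draws are allowed (the draws are i.i.d.). With binary patterns a
single-column B yields at most two classes, so with `size_resp_set ≥ 2`
rejection terminates whenever any single column splits `O(A)` at all.

## The simulation suite

`generate_data()` implements eight complete-data distributions — independent
and correlated (constant off-diagonal ρ) multivariate normal, the analogous
multivariate t (Gaussian scaled by √(df/χ²_df)), independent and
Cholesky-mixed uniforms, componentwise powers of normals, and independent
Weibull marginals — spanning light and heavy tails, bounded support, and
skewness. Defaults (ρ = 0.7, df = 4, exponent 3, Weibull(1,1), MCAR cell
probability 0.1) are echoed into every report so results are
self-describing.

Three amputation mechanisms cover the study designs:

* **MCAR** — i.i.d. Bernoulli cells (fully missing rows redrawn, since a
  fully missing observation is never observed at all);
* **paired MAR** — column 1 stays observed and drives assignment: a
  still-MCAR mask with an expected `r_complete` complete rows is paired to
  data rows so that above-mean driver values are five times likelier to
  receive an incomplete mask row (probabilities 1/6 vs 5/6, falling back to
  the remaining group when one is exhausted);
* **single-variable MAR** — variable 1 missing exactly when the mean of the
  others exceeds a threshold, the rest MCAR; the localization setting for
  partial p-values.

What passing these simulations shows — and does not show. The generators
produce i.i.d. rows, modest p, and mechanisms either exactly MCAR or MAR
through one observed driver. Real data add dependence across rows,
structured/monotone missingness, measurement artifacts and MNAR mechanisms;
level is still guaranteed for any exchangeable-rows null (the permutation
argument needs only that), but the power figures from `run_experiment()` do
not transfer to arbitrary real mechanisms, and no test can distinguish MCAR
from an MNAR mechanism invisible on observed margins.

## Numerical and degenerate-input choices

* Patterns and labels are ordered by first occurrence: deterministic and
  seed-independent.
* Fully missing rows/columns are dropped at ingest with a warning; constant
  observed columns are kept (the forest ignores them) with a notice.
* Rows never out-of-bag are excluded from both means of the statistic with
  a logged count — no unbiased probability exists for them; with default
  tree counts the event is negligible (per-tree OOB probability ≈ e⁻¹).
* OOB frequencies can be exactly 0 or 1; the eps clip above keeps every
  log-odds finite.
* Completely observed data (a single missingness pattern) is an error, not
  a p-value of 1: the hypothesis is untestable, and saying so is more
  honest than manufacturing a number.

## Problem sizes used in the shipped studies

The package's own validation runs at deliberately economical sizes chosen to
keep a full replication on a laptop: level at n = 100, p = 4 with 200
replicate tests (N = 20, L = 30, 50 trees); power at n = 200 on ρ = 0.7 data
with 100 replicates; partial-p-value localization at n = 500 with 20
replicates (N = 100, 200 trees). At these sizes the type-I error stays below
its binomial band around 0.05, MAR power is ≈ 0.9, and the localization
rates exceed 0.8 — all recomputed, not quoted, by
`scripts/acceptance.R` and the test suite.

## Known limitations

* Power depends on the classifier seeing the violation through some sampled
  projection; pathological mechanisms visible only through high-order
  variable interactions may need larger N.
* Mixed-type support encodes categorical features for splitting; extremely
  high-cardinality factors will dilute the forest.
* The permutation guarantee assumes exchangeable rows under the null;
  time-ordered or clustered rows violate that.
* Partial p-values are reported raw, without multiplicity correction, as
  localization diagnostics rather than confirmatory tests.
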