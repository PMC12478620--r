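# pklm

Is your data missing completely at random? Most downstream choices in an
incomplete-data analysis — complete-case analysis, simple imputation, how to
validate an imputation method — lean on the MCAR assumption, i.e. that the
missingness mechanism is independent of the data. `pklm` implements a
nonparametric, permutation-based test of MCAR for rectangular datasets with
mixed numeric and categorical columns, aimed at applied statisticians and
epidemiologists who want a level-guaranteed diagnostic before choosing a
missing-data strategy.

## The method

Write `M` for the binary n×p missingness matrix (`m_ij = 1` iff cell (i, j)
is missing). The distinct rows of `M` split the observations into pattern
groups; MCAR implies the observed data distribution is the same in every
group. The test makes that comparison feasible and powerful by random
projections:

1. Sample a pair of disjoint column sets `(A, B)`: `A` is the feature
   projection, `B` the label projection. Keep the rows `O(A)` fully observed
   on `A`, and label each by its missingness pattern restricted to `B`
   (collapsed classes, capped at `size_resp_set`).
2. Fit a probability random forest on `X[O(A), A]` against those labels
   (all features candidate splits; bootstrap per tree) and take out-of-bag
   class probabilities `p̂_g(x)`.
3. For each class g, compute the symmetrized log-odds statistic

       U(g) = mean_{i in I_g} log( p̂_g(x_i) / (1 − p̂_g(x_i)) )
            − mean_{i in I_-g} log( p̂_g(x_i) / (1 − p̂_g(x_i)) ),

   which estimates the symmetrized Kullback–Leibler divergence between
   class g and the mixture of the others (class-prior terms cancel). Average
   over classes, then over N projection pairs, giving the pooled statistic Û.
4. Permutation null: draw L global row permutations of `M`, shared across
   all projections; relabel (no refitting) and re-pool, giving Û⁽¹⁾…Û⁽ᴸ⁾.
   The p-value is the add-one form Z = (1 + #{l : Û⁽ˡ⁾ ≥ Û}) / (L + 1),
   finite-sample valid for any classifier quality.

Per-variable **partial p-values** re-pool over only the projections whose
label set `B` excludes variable k; if a single variable's missingness drives
the MCAR violation, its partial p-value stays high while the others drop —
the test localizes the culprit.

## Worked example

```r
library(pklm)

set.seed(1)
x   <- generate_data(case = 2, n = 200, p = 4, rho = 0.7)  # correlated normal
dat <- ampute_mar_liyu(x, r_complete = 130)                # MAR: above-mean rows
                                                           # of column 1 are 5x
                                                           # likelier incomplete
res <- pklm_test(dat$x,
                 pklm_config(num_proj = 50, nperm = 30,
                             num_trees_per_proj = 100, partial = TRUE),
                 seed = 1)
res
```

```
Projected KL test of MCAR
  pooled statistic U = 0.9899
  p-value = 0.0323  (N = 50 projections, L = 30 permutations)
  partial p-values:
 variable     u_hat     pvalue n_pairs_used
        1 1.3609065 0.03225806           37
        2 1.0211268 0.03225806           38
        3 0.8530132 0.03225806           27
        4 1.0616252 0.03225806           35
```

The pooled statistic Û = 0.99 is a KL-divergence estimate: clearly above
zero, so observed distributions differ across missingness patterns. The
p-value 0.032 is the smallest attainable with L = 30 permutations
(1/31) — the MAR mechanism is detected. On MCAR data the same call gives
p-values spread over the grid (see the simulation suite: `run_experiment()`
reproduces level and power studies for eight data distributions).

A command-line front end ships in `inst/cli/pklm.R`:

```sh
Rscript inst/cli/pklm.R test data.csv --num-proj 100 --partial --seed 1 --out report.json
Rscript inst/cli/pklm.R simulate --case 2 --n 200 --p 4 --mechanism mar-liyu --r 130 --reps 100 --seed 1
```

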