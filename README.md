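# rsinet

Regularized partial-correlation network analysis for bounded 0–100
questionnaire items, built around the 12-item ACL Return to Sport
after Injury (ACL-RSI) scale. The package is for researchers studying
psychological readiness to return to sport after ACL reconstruction —
and, more generally, for anyone who wants a fully reproducible
Gaussian-graphical-model pipeline for short questionnaires with two
participant groups.

## What it computes

Items are nodes; an edge is the regularized partial correlation
between two items given all the others,

```
w_ij = -θ_ij / sqrt(θ_ii θ_jj),
```

where Θ is a sparse precision matrix estimated by graphical lasso —
the ℓ1-penalized Gaussian maximum-likelihood estimator

```
max over Θ ≻ 0 of  log det Θ − tr(SΘ) − λ Σ_{i≠j} |θ_ij|,
```

with the penalty λ selected by minimizing the Extended BIC
(EBIC_γ = −2L + E log n + 4 E γ log p, γ = 0.5). Before estimation,
each item is rank-Gaussianized with a truncated-ECDF nonparanormal
transform, so skew and ceiling effects in 0–100 scores do not distort
the correlations. On top of the fitted networks the package provides:

- node centrality (Strength = Σ|w|, plus shortest-path Closeness and
  Betweenness with edge length 1/|w|),
- bootstrap 95% confidence intervals for every edge weight,
- the case-dropping subset bootstrap and CS-coefficient for centrality
  stability,
- a two-group permutation network comparison test (NCT) for edge and
  Strength differences,
- a synthetic two-group cohort generator with a known sparse
  partial-correlation structure, so the whole chain can be validated
  against ground truth.

## Worked example

```r
library(rsinet)

cohort <- simulate_cohort(default_sim_spec(seed = 2024))  # 441 participants
net <- fit_network(cohort)
net
#> <rsi_network> 12 nodes, 27 edges | lambda = 0.1155 (EBIC gamma = 0.5), n = 441

head(dplyr::arrange(tidy(net), dplyr::desc(abs(weight))), 3)
#> # A tibble: 3 × 3
#>   from  to    weight
#> 1 Q7    Q9     0.397
#> 2 Q4    Q8     0.307
#> 3 Q1    Q11    0.174

head(dplyr::arrange(centrality_table(net, "whole"),
                    dplyr::desc(strength)), 3)[, 1:4]
#> # A tibble: 3 × 4
#>   network_id node  strength closeness
#> 1 whole      Q7       0.934   0.00594
#> 2 whole      Q9       0.493   0.00524
#> 3 whole      Q4       0.448   0.00427

bt <- bootstrap_edges(cohort, B = 200, seed = 2024)
dplyr::filter(tidy(bt), from == "Q7", to == "Q9")
#> # A tibble: 1 × 6
#>   from  to    estimate boot_mean ci_low ci_high
#> 1 Q7    Q9       0.397     0.403  0.328   0.478
```

The generator plants Q7–Q9 at partial correlation 0.48 and Q4–Q8 at
0.37; the fitted weights (0.397, 0.307) show the shrinkage the lasso
penalty applies at n = 441 — the interval above is the uncertainty
around the *regularized* estimate, and the estimate converges to the
planted value as n grows (the tests check recovery within ±0.03 at
n = 10⁵). Q7 and Q9 carry the largest Strength because the strongest
edge is incident to both.

Group comparison and stability:

```r
ret <- dplyr::filter(cohort, returned)
not <- dplyr::filter(cohort, !returned)
cmp <- nct(ret, not, n_permutations = 1000, seed = 1)
report_significant(cmp)          # unadjusted p < 0.05, exploratory

cd <- case_drop_bootstrap(cohort, seed = 1)
cs_coefficient(cd)               # e.g. 0.75 = very stable Strength ordering
```

`run_full_analysis(run_config(input = ..., seed = ...))` chains every
stage (three networks: whole / returned / not-returned, centralities,
bootstraps, NCT) and can write all artifacts as CSV/JSON. Figures:
`autoplot(net)`, `autoplot(bt)`, `autoplot(cd)`,
`plot_centrality(...)`.

See `vignettes/network-methods.Rmd` for the model, the estimator's
shrinkage and support-recovery behaviour, all defaults, and known
limitations.

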