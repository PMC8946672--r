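---
title: "Estimating and comparing readiness-item networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing readiness-item networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsinet)
```

## The model

rsinet analyses questionnaire data — in the first place the 12-item
ACL Return to Sport after Injury (ACL-RSI) scale, each item scored
0–100 — as a **Gaussian graphical model** (GGM). Items are nodes; an
edge between two items is their *partial correlation*, the association
that remains after conditioning on all other items. In a multivariate
normal model the partial correlations are read off the precision
(inverse covariance) matrix $\Theta$:

$$ w_{ij} = -\frac{\theta_{ij}}{\sqrt{\theta_{ii}\,\theta_{jj}}}, $$

and $\theta_{ij} = 0$ means items $i$ and $j$ are conditionally
independent given the rest. Because bounded 0–100 scores are skewed and
often pile up at the ceiling, the items are first rank-Gaussianized;
because $\binom{12}{2} = 66$ free edges estimated from a few hundred
participants would overfit, the precision matrix is estimated with an
$\ell_1$ penalty that sets small edges exactly to zero.

The pipeline is: nonparanormal transform → Pearson correlation →
graphical lasso along a penalty path → EBIC model selection →
centrality indices → bootstrap accuracy/stability → two-group
permutation comparison. Each stage is exported on its own; `run_full_analysis()`
chains them.

## Marginal Gaussianization

`npn_transform()` implements the truncated-ECDF ("shrunken ECDF")
nonparanormal estimator. Column $j$ with $n$ observations is mapped
through

$$ z_{ij} = \Phi^{-1}\!\Big(\mathrm{clip}\big(\tfrac{r_{ij}}{n+1},\;
\delta_n,\; 1-\delta_n\big)\Big), \qquad
\delta_n = \frac{1}{4 n^{1/4} \sqrt{\pi \log n}}, $$

where $r_{ij}$ is the average rank (ties share a rank, so tied raw
scores map to one identical transformed value — important for
ceiling-heavy items where many participants score 100). The truncation
constant $\delta_n$ keeps extreme quantiles finite. Each column is then
standardized to unit sample variance. The map is monotone within a
column, so all rank-based structure (Spearman correlations) is exactly
preserved, and applying the transform twice is a no-op. A constant
column is an error: the transform is undefined, and an item without
variance cannot sit in a correlation network.

We compute Pearson correlations of the transformed scores. Rank-based
dialects (polychoric or auto-detected correlations) exist and can move
edge weights in the second decimal; this choice is fixed here and is
the main reason numerically published edge weights from other toolchains
may differ slightly.

## Penalized network estimation

`glasso_fit()` maximizes the penalized Gaussian log-likelihood

$$ \log\det\Theta - \operatorname{tr}(S\Theta)
   - \lambda \sum_{i \ne j} |\theta_{ij}| $$

over positive-definite $\Theta$ by block coordinate descent on the
covariance (implemented in C++; the diagonal is unpenalized).
Convergence is declared when the working covariance changes by less
than $10^{-6}$ in a sweep, with a cap of $10^4$ sweeps; non-convergence
is an error that reports the KKT residual rather than a silent
approximate answer. The tests verify the solver against an independent
proximal-gradient maximizer and against the KKT optimality conditions
at every fitted model.

`ebic_glasso()` fits a path of 100 penalties, log-spaced from
$\lambda_{\max} = \max_{i \ne j} |S_{ij}|$ (the smallest penalty that
kills every edge) down to $0.01\,\lambda_{\max}$, and selects the model
minimizing the Extended Bayesian Information Criterion

$$ \mathrm{EBIC}_\gamma = -2L + E \log n + 4 E \gamma \log p, $$

with $E$ the number of nonzero upper-triangle entries. Defaults:
$\gamma = 0.5$ (the conventional value for questionnaire networks;
$\gamma = 0$ recovers the BIC and denser models), ties broken towards
the larger penalty (sparser model), and entries below $10^{-10}$
treated as zero to absorb solver noise. The full
$(\lambda, \mathrm{EBIC}, E)$ path is kept in the fitted object for
audit.

Two properties of this estimator are worth knowing. First, edge weights
are shrunken towards zero at realistic sample sizes: a planted partial
correlation of 0.48 is estimated near 0.37 at $n = 441$ and only
approaches 0.48 as $n$ grows to $10^5$. That is the price of the
variance reduction the penalty buys and it affects published analyses
with this estimator equally. Second, support recovery is good but not
exact: at large $n$ every genuine edge is found, while a few weak false
positive edges typically survive selection (the $\ell_1$ analogue of
the irrepresentable condition). The tests assert sensitivity and
specificity of at least 0.9 rather than exact support recovery.

## Centrality

`centrality_table()` reports three node-importance indices. Strength
is $\sum_j |w_{ij}|$, the primary index: a high-Strength item has many
strong direct conditional associations. Closeness and Betweenness are
shortest-path indices where an edge of weight $w$ has length $1/|w|$
(the standard convention in network psychometrics): Closeness is the
inverse of a node's total distance to all others, Betweenness counts
geodesics passing through a node, splitting ties equally (Brandes
convention). A node disconnected from any other has Closeness 0 by
convention; isolated nodes score 0 on all three. Raw values are
reported alongside a min–max rescaling to $[0, 1]$ used for plotting
(1 = most important); all inferential comparisons operate on the raw
values.

## Accuracy and stability

`bootstrap_edges()` assesses edge accuracy with a nonparametric
bootstrap: resample $n$ participants with replacement, rerun the
*entire* pipeline (the penalty is re-selected inside every replicate),
record all 66 edge weights, and report percentile 2.5/97.5 intervals.
No bias correction is applied. The default is $B = 1000$ iterations.

`case_drop_bootstrap()` assesses whether the centrality ordering would
survive with fewer participants: for each drop proportion
$\pi \in \{0.05, 0.10, \ldots, 0.75\}$ it repeatedly subsamples
$\lfloor (1-\pi) n \rfloor$ participants without replacement,
re-estimates the network, and correlates the replicate's Strength
vector with the full-sample one. `cs_coefficient()` condenses this into
the CS-coefficient: the largest $\pi$ such that at it — and at every
smaller grid value, so one unstable intermediate proportion caps the
result — at least 95% of replicates correlate $\ge 0.7$ with the
original. CS below 0.25 flags an unstable ordering; above 0.5 is
considered good. The grid tops out at 0.75, so 0.75 is the best
attainable value. A replicate whose Strength vector is constant
(typically an empty network) has no defined correlation and counts as
non-qualifying.

Every resampling routine pre-draws per-replicate seeds from one master
seed, so results are bit-reproducible and independent of how many
failed replicates were redrawn (failures are redrawn up to a cap of
twice the requested count).

## Two-group comparison

`nct()` is a two-tailed permutation network comparison test. Both
groups' networks are estimated with the full pipeline; the observed
statistics are the absolute differences in each edge weight and in each
node's Strength. Pooled participants are then repeatedly reassigned at
random to pseudo-groups of the original sizes, both networks
re-estimated (again with their own penalty selection — the null
distribution must reflect the whole estimation procedure), and the
statistics recomputed. P-values are $(1 + \#\{\text{permuted} \ge
\text{observed}\})/(1 + M)$, which can never be exactly zero. The
pooled rows are put in a canonical sort order before permuting so that
swapping the group labels gives identical p-values. Transformation
happens inside each pseudo-group, keeping every replicate
pipeline-consistent; transforming once on the pooled data would be the
main alternative and matters little at these sample sizes.

P-values are reported unadjusted and flagged as exploratory;
`report_significant()` lists those below $\alpha = 0.05$. With 66 edge
and 12 Strength tests, a handful of sub-0.05 results is expected under
the global null. Omnibus statistics (global strength difference,
maximum edge difference) are computed as extras.

For sparse networks the permutation null is discrete at zero: if an
edge is absent in both groups in most replicates, observed and permuted
differences tie at 0 and the p-value is 1. The test is therefore
conservative for never-selected edges and calibrated for edges that are
actually estimated — the tests verify a 5% false-positive rate on
planted (nonzero, group-equal) edges.

## The synthetic cohort

`default_sim_spec()` + `simulate_cohort()` generate data with known
ground truth under the reference study's conditions: 12 items, 115
returned / 326 not-returned participants, and per-item, per-group
marginal means/SDs taken from the reference cohort's descriptive
table (e.g. item 12: mean 80.07, SD 22.08 among returners, 55.06 and
27.81 among non-returners). Whole-cohort descriptives of the synthetic
data are the size-weighted mixture of the two groups. The planted dependence
structure is sparse: partial correlations 0.48 (Q7–Q9) and 0.37
(Q4–Q8) in both groups, ten weaker common edges in $[0.05, 0.2]$, and
three edges (Q2–Q7, Q5–Q8, Q3–Q12) planted stronger in the returned
group so the comparison test has a true alternative. The implied
precision matrices (unit diagonal, off-diagonal $-w_{ij}$) are checked
for positive definiteness; an invalid user-supplied structure is
repaired by uniform off-diagonal shrinkage with the factor recorded.

Generation draws a latent multivariate normal with the implied
correlation structure, maps it to the 0–100 scale with the group/item
mean and SD, clips to $[0, 100]$ and rounds to integers. Clipping and
rounding reproduce the ceiling effects and discreteness of real item
scores, and they slightly attenuate the planted correlations — the
recovery tests allow $\pm 0.03$ at $n = 10^5$ for this reason. What the
generator does *not* emulate: item-level measurement models (no
item-response-theory structure), non-normal latent dependence, ordinal
response styles, or longitudinal drift. A passing test suite therefore
shows the estimator chain is correct and stable under realistic
marginals and sparse partial-correlation truth, not that any particular
clinical dataset satisfies the GGM assumptions.

## Orchestration, determinism, problem sizes

`run_config()` collects every tunable; `run_full_analysis()` runs the
stages that are toggled on and, given `output_dir`, writes each
stage's CSV/JSON artifacts. Per-stage seeds are derived
deterministically from the master seed and the stage name, so toggling
one stage never changes another stage's draws; re-running a config
reproduces every output exactly. Network figures (`autoplot()`,
`plot_centrality()`) use a fixed circle layout precisely so that plots
are reproducible too.

Default replicate counts follow the reference analysis ($B = 1000$
bootstrap iterations, 1000 permutations, case-dropping grid up to
0.75). The bundled reproduction script uses 250 case-dropping
replicates per grid point per network — the CS-coefficient is a 95th
percentile over replicates, already stable at that count — and the test
suite uses smaller cohorts ($p$ of 3–6, $n$ of a few hundred) for the
properties that do not need the full design, with the full 12-item,
441-participant configuration exercised in the end-to-end checks.

## Known limitations

- Edge weights inherit lasso shrinkage; compare weights only across
  models fitted with the same procedure and sample size regime.
- Pearson-on-transformed correlations are one of several dialects for
  ordinal-ish 0–100 items; polychoric variants can shift weights by a
  few hundredths.
- The NCT is conservative for edges the estimator never selects, and
  its per-edge p-values are unadjusted by design.
- EBIC selection at $\gamma = 0.5$ is strict at small $n$: with ~115
  participants and a weakly interconnected truth (a few strong edges,
  many near-zero ones, as the synthetic generator plants), the
  selected subgroup network can be empty, taking its CS-coefficient to
  0 with it. Real questionnaire data, whose items share a strong
  latent factor and are densely intercorrelated, give the likelihood
  far more to gain per edge at the same $n$.
- A GGM is an undirected conditional-association model: it cannot
  distinguish a common cause from a mediator from a common effect, and
  a cross-sectional network says nothing about within-person dynamics.
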