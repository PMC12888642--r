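---
title: "Methods: federated probability averaging for random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated probability averaging for random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedforest)
```

This vignette is the package's account of its model, its tunable
parameters, the synthetic data it tests itself on, and the design choices
made where more than one reasonable option existed.

## The aggregation model

In the horizontal federated setting every site holds its own patients but
the same feature space. Site $i$ trains a *probability forest* of $m_i$
trees; for a query its prediction is

$$x_i = \frac{1}{m_i}\sum_{j=1}^{m_i} p_{i,j},$$

the mean over trees of the terminal node's positive-class relative
frequency. This is the estimator `ranger` produces with
`probability = TRUE`, and `per_tree_probability()` exposes the $p_{i,j}$ so
the decomposition is testable exactly. The federated prediction is the
convex combination $P = \sum_i w_i x_i$ with $w_i = v_i / \sum_k v_k$; the
five choices of the raw value $v_i$ (1, $n_i$, positives, minority count,
and $E_i\,n_i$ with $E_i$ the Shannon evenness of the site's class
proportions) trade off three facts about a site: how much data it has, how
much signal about the positive class it has, and how badly one class
dominates it.

Two modelling points deserve emphasis:

* **Averaging probabilities equals pooling trees.** A single forest built
  from the union of all sites' trees, with each tree of site $i$ carrying
  weight $1/(N m_i)$, predicts identically to the unweighted mean of
  per-site probabilities. `pooled_forest_predict()` implements the pooled
  form and the test suite holds the identity to $10^{-12}$ on randomized
  ensembles. This is why sharing predictions loses nothing relative to
  physically merging forests.
* **The sum form vs. the mean.** Written as a plain sum over sites of
  per-forest means, the aggregate could exceed 1; the package implements
  the mean over forests (equal weights $1/N$), which is the construction
  the schemes generalize with non-uniform $w_i$. All aggregation operates
  on probabilities — never on votes or logits.

Edge conventions: $0\ln 0 = 0$ in the diversity index, so a single-class
site has $v = 0$ under `mpd` (and under `minority`, and possibly
`positives`) while still counting under `samples` and `unweighted`;
`normalize_weights()` raises an explicit error, not `NaN`, when *every*
site has value zero. A site balanced at exactly $n/2$ needs no tie-break:
the minority count is $n/2$.

## The benchmark protocol

`run_benchmark()` mirrors a multi-site evaluation campaign:

* One shared stratified $k$-fold plan (default $k = 5$) per site, built so
  per-fold class counts are within one sample of proportional; the general
  model's fold-$i$ test set is the union over sites of each site's fold
  $i$. Sites with fewer than $k$ members of a class fall back to
  non-stratified folds with a warning.
* Per fold: one forest per site plus a general model (GM) on the pooled
  training partitions; scheme weights recomputed from *training-partition*
  class counts only, so nothing about a test fold can leak into training or
  weighting. (Weights published for a whole cohort — the `weights` CLI
  path — use whole-site counts; the benchmark deliberately does not.)
* Metrics: rank-based AUROC with midrank tie handling, summarized across
  folds as mean $\pm 1.96\,\mathrm{sd}/\sqrt{k}$ clipped to $[0,1]$ (a
  normal approximation chosen for its symmetry; a pooled-prediction
  alternative was considered and rejected to keep fold-to-fold variance
  visible), and the operating point at the maximum Youden index
  $J = \mathrm{sens} + \mathrm{spec} - 1$, computed per fold, with ties in
  $J$ (within $10^{-12}$, which absorbs floating-point coincidences of
  rationally equal $J$) broken to the lowest threshold.
* AUROC is fold-averaged, not pooled over all test predictions: the
  fold-wise spread is itself a quantity of interest (model consistency),
  and pooling would hide it.

## Hyper-parameter tuning

`tune_hyperparameters()` grid-searches `ntree` × `mtry` by repeated
stratified inner CV confined to the training data, scoring each cell by
mean accuracy at the 0.5 probability cutoff (the cutoff is a package
choice; accuracy needs one and 0.5 is the probability-forest analogue of
majority vote). The full campaign grid — `ntree` 100–1000 by 100, `mtry`
1–30, five repeats of ten folds — is available via
`default_grid(d, full = TRUE)`, but the package's defaults are desk-scale:
`ntree` {100, 300, 500}, `mtry` in a ±2 band around $\lfloor\sqrt d\rfloor$,
two repeats of five folds. Trees are standard CART with Gini impurity,
bootstrap resampling and no depth limit; class weighting and resampling
(SMOTE et al.) are deliberately absent — imbalance is handled at
aggregation time, which is the point of the weighting schemes.

## The synthetic cohort generator

No public dataset has the multi-site structure this package targets, so
`generate_federated_cohort()` draws one. Its defaults emulate the
eleven-hospital delirium cohort profile shipped as
`delirium_site_profile()`: eleven sites, 29,479 samples, per-site sizes
552–6,624 and incidences 11.4%–63.4%.

The mechanism is the simplest one that produces a shared learnable signal
with between-site heterogeneity:

* Features: 30 binary (Bernoulli, rates drawn once from $U(0.05, 0.5)$ and
  shared across sites — sparse indicator-style covariates) and 10
  continuous (standard normal). Dimension is configurable; 40 is a
  desk-scale stand-in for a six-hundred-feature EMR space.
* Labels: $P(y=1\mid x) = \sigma(\beta^\top x + b_\text{site} +
  \varepsilon)$, $\varepsilon \sim N(0, 0.5)$, with $\beta$ shared by all
  sites (ten binary and four continuous features carry signal,
  $|\beta| \in [0.25, 0.9]$, mixed signs) so that every site is learning
  the same function.
* Incidence: $b_\text{site}$ is found by bisection so the mean predicted
  probability over the site's realized linear predictors equals the target
  incidence; over 20 replicate draws at $n = 5{,}000$ the mean empirical
  incidence lands within ±0.01 of target (tested). Incidence exactly 0 or
  1 is allowed as an explicit degenerate case (single-class site, warned).
* Heterogeneity: a per-site scalar `site_shift` moves every binary
  feature's rate on the logit scale and every continuous feature's mean.
  A constant *intercept* shift would be absorbed exactly by the incidence
  calibration, so heterogeneity must enter through the covariates to
  survive; this is the package's resolution of that interaction, and it is
  what makes site models genuinely differ.
* Determinism: one master seed; consumers get sub-seeds from a fixed-size
  block drawn once, so identical configurations give bit-identical
  cohorts.

What the generator does *not* emulate: department/case-mix structure,
feature correlation blocks (ICD hierarchies, repeated labs), missingness,
temporal drift, and label noise from imperfect coding. Passing tests on
this generator therefore show the machinery is correct and the weighting
schemes behave as designed under size/imbalance heterogeneity — they do not
certify performance on real EMR data.

## Problem sizes used in the shipped tests

The test suite exercises the benchmark at a reduced scale chosen to keep a
full run deskside: the eleven-site profile scaled to ~6,000 total rows
(each site's size and incidence kept proportional), 40 features, fixed
`ntree = 100`, `mtry = 6` (a one-cell grid), $k = 5$, five replicate
cohorts. At that scale the qualitative ordering of the full-size campaign
reproduces: GM ≥ best weighted scheme ≥ unweighted mean, with the weighted
schemes' margin over the unweighted mean around 0.01 AUROC and every
federated scheme ahead of the best single-site model. Generator calibration
uses 20 replicates at $n = 5{,}000$.

## Known limitations

* Binary outcomes only end-to-end. The diversity/evenness formulas accept
  any number of classes, but no multi-class pipeline is built.
* The per-site models must share one feature schema; no vertical or
  transfer setting.
* The "central server" is simulated in-process: no communication layer,
  encryption, or differential privacy.
* Probability calibration (Platt/isotonic) is out of scope; forests are
  used with their native terminal-node frequencies.
* Missing data handling is minimal by design: reject on read, or
  mode/mean imputation on request.

```{r}
# the weight table the schemes produce on the shipped profile
head(site_weights(delirium_site_profile(), "all"), 12)
```
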