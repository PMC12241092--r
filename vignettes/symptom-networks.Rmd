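---
title: "Estimating and stress-testing symptom networks with symptomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and stress-testing symptom networks with symptomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model and its assumptions

`symptomnet` treats a table of clinical scores — here 13 negative-symptom
items rated 0–6, four cognitive-domain scores, and one social-function
total on a 0–48 scale — as draws from a Gaussian graphical model. An edge
between two variables is their *partial correlation*: the association that
remains after conditioning on every other variable in the network. Sparse
estimation uses the graphical lasso, the L1-penalized maximum-likelihood
estimator of the precision matrix $\Theta$,

$$\hat\Theta_\lambda = \arg\max_{\Theta \succ 0}\;
  \log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\neq j}|\theta_{ij}|,$$

with edge weights $w_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$.
Only off-diagonal entries are penalized, so the implied covariance keeps
the observed diagonal and the weights remain proper partial correlations.

Assumptions worth keeping in mind: the scores are treated as continuous
and jointly Gaussian (product-moment correlations by default — 7-point
clinical ratings are conventionally treated this way; a rank-correlation
option exists but polychoric estimation is out of scope); both clinical
groups are assumed to share one conditional-dependence structure, which is
what pooling them into a single network presumes; and no missing data are
tolerated anywhere — validation errors name the offending cell rather
than imputing.

## Tuning parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.5 | EBIC model-space penalty; 0 recovers plain BIC, larger values give sparser networks (the selected edge count is provably non-increasing in `gamma`). |
| `n_lambda` | 100 | Penalty-path length, log-spaced from $\lambda_{\max} = \max_{i\ne j}|S_{ij}|$ downward. |
| `lambda_min_ratio` | 0.01 | Bottom of the path as a fraction of $\lambda_{\max}$. |
| convergence | `1e-7`, 10,000 sweeps | Tolerance on the maximum parameter change per block-coordinate sweep; desk-scale problems converge in far fewer sweeps. |
| edge-length | $1/|w_{ij}|$ | Distance convention for closeness/betweenness; absolute values keep lengths non-negative when negative edges are present. |
| CS thresholds | 0.7 / 0.95 | A drop proportion "passes" when at least 95% of subsample correlations with the full-sample values are at least 0.7. |
| drop grid | 0.05–0.75 by 0.05 | Case-dropping proportions; the retained subsample must keep at least $p+1$ subjects. |

Bridge strength sums *absolute* cross-domain weights by default: a signed
sum can cancel between positive and negative edges, which contradicts the
"capacity to connect domains" reading. A `signed = TRUE` variant is
available. Domains are always user-declared metadata, never detected.

## The synthetic generator

The generator (`default_spec()`, `sample_dataset()`) emulates the study
conditions the pipeline was built around: two groups of 70
(deficit-syndrome-like) and 91 (non-deficit-like) male inpatients measured
on 18 variables. Its ground truth is a sparse partial-correlation matrix
with five within-domain blocks — strongly coupled pairs (Y1, Y2),
(B12, B13), (B5, B6), (B7, B8) at 0.3; anhedonia (B1–B3) and expressivity
(B9–B11) triads at 0.25 — plus 0.15 bridges from the social-function total
to B1, B2, Y1 and Y3. Within-cluster magnitudes were chosen once to match
the *order* of the published strongest edges (0.533, 0.371, 0.355, 0.295),
not their exact values, which depend on unpublished data. Group means and
per-variable dispersions come from the published two-group summary table;
for the 13 item rows the published "±" figure is a standard error (SE ×
√n reconciles the item-level t magnitudes), elsewhere a standard
deviation, and the generator uses the group-averaged SD.

Sampling draws latent multivariate-normal deviates with the correlation
structure implied by the ground truth, shifts each group's mean on the
latent scale, and only then discretizes (0–6 ratings and the 0–48 total by
rounding and clamping; cognitive scores floored at zero). Discretizing a
latent liability mirrors how ordinal clinical ratings arise and costs a
mild, realistic attenuation of item correlations; shifting means before
discretization keeps the covariance structure identical in both groups.

What the generator does *not* emulate: antipsychotic-dose effects, rater
error, missing data, floor/ceiling pile-ups beyond what clamping induces,
or any distributional feature of the real data beyond published means and
dispersions — the latent-Gaussian form is a modeling stand-in, not an
inference. Passing tests therefore demonstrate that the pipeline recovers
known structure under these idealized conditions, not that the published
network is correct.

### Recovery conditions

Structure-recovery checks (both in the test suite and in
`scripts/acceptance.R`) draw a pooled continuous sample of n = 2,000 from
the default structure *with the two group means equalized*. With the full
group shifts in place, the pooled covariance acquires a rank-one
between-group component that induces genuine pooled partial correlations
of about 0.05 on conditionally independent pairs — a property of pooling
shifted groups, not an estimator defect — so recovery of the planted
structure is only well-posed against the shared within-group model. Under
those conditions every planted edge with $|\rho| \ge 0.2$ is detected
with the correct sign and the mean absolute weight over true-zero pairs
stays below 0.03.

## Numerical choices

* The penalty path descends with warm starts; EBIC ties resolve to the
  larger penalty (sparser model).
* Entries zeroed by the soft threshold are exact zeros, so edge counts
  are well defined; converted weights below 1e-10 are snapped to zero.
* $\lambda = 0$ is solved by direct inversion (the unpenalized MLE),
  which the coordinate-descent solution matches to 1e-6 on
  well-conditioned inputs.
* Glasso active sets are *not* strictly nested along the path: edge
  counts can dip locally as $\lambda$ decreases. This is a real property
  of the estimator (an independent solver reproduces the same counts),
  so sparsity checks assert the overall trend, not strict monotonicity.
* Isolated nodes get closeness 0; disconnected pairs have infinite
  distance; tied geodesics share betweenness credit fractionally.
* Case-dropping correlations are undefined when an index is constant
  (e.g. an empty subsample network makes every strength 0); these are
  recorded as missing, excluded, and counted — at heavy drop proportions
  on n = 161 this is common, and the CS walk simply stops where defined
  correlations run out.
* The CS coefficient requires *every* proportion up to the reported one
  to pass, preventing non-monotone flukes from inflating stability.
* All writers format numbers stably (and the spec serializer round-trips
  doubles exactly via `%.17g`), so a rerun with the same seed is
  byte-identical.

## Design decisions

**Welch, not pooled-variance, t-tests.** Recomputing the published table
rows whose dispersions are standard deviations matches the printed t
under Welch to within 0.05 (e.g. scale total: 13.50 Welch vs 13.99
pooled against printed 13.495). The published table prints |t|; the
package keeps the sign convention $\mathrm{sign}(t) =
\mathrm{sign}(\bar x_1 - \bar x_2)$.

**18 nodes.** The node roster is the 13 items, four cognitive domains and
one social-function total — consistent with the published pair count
(153 = C(18, 2)) and figure legends. A conflicting in-text enumeration
("25 nodes") is treated as a textual inconsistency.

**Bootstrap edge intervals are accuracy envelopes, not coverage
intervals.** Quantile intervals from re-estimated resamples are centered
on the regularized (shrunk) estimate; for a strong edge they may sit
entirely below the generating value. Tests therefore check that the
interval never sits *above* the truth and that it separates a strong edge
from zero, rather than asserting nominal coverage.

**One seed.** Every stage derives its own seed from the single top-level
seed, so stages are individually reproducible and the whole pipeline is
deterministic end to end.

## Problem sizes used in the checks

The shipped checks run at deliberately desk-scale sizes chosen once:
consistency draws at n = 50,000; recovery at pooled n = 2,000; stability
at the study's own n = 161 with B = 250 subsamples per drop proportion;
interval behavior on a 4-node planted-edge model with 200 replicates of
B = 100. Reported-analysis defaults (B = 1,000 bootstraps) are larger
than what the tests exercise.

## Known limitations

Cross-sectional networks describe conditional associations, not causal
pathways. Polychoric/copula correlation options, mixed graphical models,
directed networks, separate per-group networks and bootstrapped
difference tests are deliberately out of scope. CS coefficients on
n = 161 with 18 nodes are themselves noisy; treat grid-resolution
differences (0.05) as meaningless.
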