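# symptomnet

Regularized partial-correlation network analysis for clinical rating-scale
data: negative-symptom items, cognitive-domain scores and a social-function
total, as collected in schizophrenia research. The package is aimed at
psychiatric and psychometric researchers who want a scripted, reproducible
version of the now-standard symptom-network workflow — Gaussian graphical
model estimation with the graphical lasso, centrality and bridge-centrality
analysis, and bootstrap stability assessment — together with a synthetic
two-group data generator so every stage can be exercised and tested without
access to patient data.

## The model

Given an *n* × *p* score matrix with correlation matrix **S**, the network
is the Gaussian graphical model obtained by maximizing the penalized
log-likelihood

```
log det(Θ) − tr(SΘ) − λ Σ_{i≠j} |θ_ij|        (graphical lasso)
```

over positive-definite precision matrices Θ; the penalty λ is chosen on a
descending log-spaced path by the extended Bayesian information criterion

```
EBIC(λ) = −2ℓ(Θ̂λ) + E log n + 4 E γ log p,
```

where E is the number of nonzero off-diagonal entries and γ (default 0.5)
trades sensitivity for parsimony. Edge weights are the regularized partial
correlations `w_ij = −θ_ij / √(θ_ii θ_jj)`.

On the estimated network the package computes, per node: **strength**
Σ|w_ij|, **expected influence** Σw_ij, **closeness** (inverse total
shortest-path length, edge length 1/|w|), **betweenness** (fractional
geodesic counts), and **bridge strength** (Σ|w_ij| over edges to other
declared clinical domains, equivalently node strength on the network with
all within-domain edges removed). Uncertainty is quantified by a
nonparametric bootstrap of edge weights and by a case-dropping bootstrap
summarized by the correlation-stability (CS) coefficient: the largest
fraction of subjects that can be dropped while the correlation between
subsample and full-sample index values stays ≥ 0.7 in at least 95% of
subsamples. Two-group (deficit vs non-deficit) comparisons use Welch's
unequal-variance t-test with Welch–Satterthwaite degrees of freedom.

## Worked example

```r
library(symptomnet)

# Welch t from published group summaries (scale total, n = 70 vs 91)
welch_t(44.93, 13.03, 70, 19.70, 9.85, 91)
#> $t 13.50217   $df 124.9186   $p 3.78e-26

# Simulate the default 18-node two-group dataset and estimate its network
ds <- sample_dataset(default_spec(), seed = 42)
ds
#> item_dataset: 161 subjects x 18 nodes
#>   domains: cognition (4), negative_symptoms (13), social_function (1)
#>   groups: DS (n=70), NDS (n=91)

m <- estimate_network(ds, gamma = 0.5)
m
#> network_model: 18 nodes, 105/153 nonzero edges (95 positive)
#>   lambda = 0.05635 (EBIC gamma = 0.5), n = 161

ct <- centrality_table(m)
head(ct[order(-ct$strength), ], 4)
#>    node_id            domain strength expected_influence closeness betweenness
#> 14      Y1         cognition     1.07              1.072   0.00496          15
#> 1       B1 negative_symptoms     1.04              1.036   0.00449           5
#> 6       B6 negative_symptoms     1.01              0.899   0.00405          16
#> 13     B13 negative_symptoms     1.00              1.000   0.00492          15

bs <- bridge_strength(m)
head(bs[order(-bs$bridge_strength), ], 4)
#>      node_id          domain bridge_strength
#> SSPI    SSPI social_function           0.783
#> Y4        Y4       cognition           0.782
#> Y3        Y3       cognition           0.757
#> Y1        Y1       cognition           0.641

st <- case_dropping(ds, indices = "strength", B = 50, seed = 7)
st
#> stability_analysis: B = 50 per proportion, n = 161
#>   CS(strength) = 0.25  (cor >= 0.70 with prob >= 0.95)
```

The simulated data reproduce the qualitative findings the generator was
built to emulate: the sustained-attention and anhedonia nodes carry the
highest strength, and the social-function total is the strongest bridge
between domains. `run_pipeline(pipeline_config(...))` chains every stage
and writes all tables to an output directory; a thin command-line driver
with `simulate` / `compare` / `network` / `centrality` / `bridge` /
`stability` / `all` subcommands is installed at
`system.file("cli", "symptomnet.R", package = "symptomnet")`.

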