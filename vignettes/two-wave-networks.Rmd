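---
title: "Two-wave psychometric network analysis with panelnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-wave psychometric network analysis with panelnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelnet)
```

panelnet estimates how a set of psychological constructs measured at two
waves relate to each other concurrently and over time. Its motivating use
case is a dyadic panel in which mothers report five parenting practices
(warmth, monitoring, hostility, inductive reasoning, harshness) and
adolescents report four mental-health problems (anxiety, depression,
aggression, conduct problems), eighteen months apart. This vignette is the
package's own account of the models it fits, the defaults it chooses and
why, what the synthetic-data generator does and does not emulate, and the
numerical behavior a user should know about.

## From items to residualized scores

Scale scores are means of keyed Likert items (reverse-keyed items recoded
as `lo + hi − x`). The mean rather than the sum keeps scores on the
response metric and comparable across scales with different item counts; a
score is computed when at least 75% of a scale's items are answered,
otherwise missing. Both choices are configuration options
(`score_scales(min_prop = )`), because instrument manuals differ and
neither convention is universal.

Reliability is screened with Cronbach's alpha, computed on
listwise-complete item rows. A scale is excluded only when alpha falls
below 0.60 at *both* waves: a scale that scrapes under at one wave but is
adequate at the other (harshness-type scales, with three items, often sit
near 0.6) carries usable signal, while a scale weak at both waves
(consistent-discipline-type scales) does not. Skewness and excess kurtosis
are reported with the small-sample-adjusted conventions of common
commercial statistics software (`e1071` type 2), since that is what
readers of Table-1-style descriptives will compare against.

Before any network is estimated, every score is replaced by its OLS
residual after regressing on the covariates (adolescent gender as a 0/1
indicator, age in years, maternal education and family income as ordinal
integer codes). Rows with any missing score or covariate are dropped
listwise — the simplest policy that keeps all nine nodes on identical
cases, which the network estimators require. Constant or collinear
covariate columns are dropped with a warning rather than failing, because
real panels routinely contain degenerate encodings.

## The contemporaneous networks

Each wave's network is a Gaussian graphical model: edge weights are
partial correlations, obtained from a sparse precision matrix `Theta`
maximizing the penalized log-likelihood
`log det(Theta) − tr(S Theta) − lambda * sum_{i≠j} |Theta_ij|`.
The solver is the standard block coordinate descent over rows with lasso
subproblems (solved by Gram-matrix coordinate descent), with the diagonal
unpenalized; convergence is declared when the implied covariance's
off-diagonals move less than 1e-5, with a 500-iteration cap. A zero
penalty short-circuits to the exact inverse, so the unpenalized model
agrees with textbook partial correlations to machine precision. Zeros are
stored exactly: an edge absent from the model is 0, never 1e-9.

The penalty is chosen by EBIC, `−2l + E log n + 4 E γ log p`, over 100
log-spaced penalties from the smallest all-empty value down to 1% of it,
with γ = 0.5 — the conventional default of EBIC-based network estimation,
erring toward sparsity. Ties resolve toward the larger penalty. Both γ and
the grid are exposed (`select_network(gamma =, nlambda =,
lambda_min_ratio =)`) and echoed into every run manifest, so results are
self-describing.

One behavior deserves emphasis: because a single λ controls both which
edges exist and how much the strong edges are shrunk, the EBIC minimum on
a path with strong true edges tolerates a few near-zero spurious edges —
the likelihood gained by debiasing strong edges outweighs the per-edge
penalty. In chain-graph simulations (true partial correlations 0.4,
n = 2000) every true edge is recovered in every replicate, while a handful
of false edges an order of magnitude smaller (|w| ≤ 0.03) survive. Users
should read tiny edges with the bootstrap CIs, not as discoveries.

The two waves are reported jointly: `average_edges()` averages each pair's
weights, rounds half-away-from-zero to two decimals (so 0.445 prints as
0.45, matching how such tables are typeset), and displays pairs whose
weight exceeds 0.01 in absolute value at either wave; the unrounded full
table rides along as an attribute.

## The temporal network

The cross-lagged panel network regresses each T2 residualized score on all
nine T1 scores with the LASSO, objective
`(1/2n) ||y − b0 − X b||² + λ ||b||₁`, predictors standardized internally
and coefficients reported on the original scale (the "unstandardized"
reporting convention). Each node's λ is tuned by 10-fold cross-validation
with seeded fold assignment, using the minimum-CV rule rather than the
one-standard-error rule: published cross-lagged tables report edges down
to ±0.01, which a 1-SE rule would erase. The cost of that choice is a
known false-positive appetite — on a design with one true cross path among
72, minimum-CV keeps spurious small coefficients at a rate around 15%
(the field-standard `cv.glmnet` lambda.min runs near 23% on the same
design). The per-node CV seed is derived from a hash of the node's label,
not its column position, so reordering columns cannot change any node's
fit; `fit_clpn` is therefore exactly invariant to column permutations of
either wave.

Centralities follow the two readings in circulation. The default
in-/out-prediction is the signed sum of permitted edge weights — what
temporal-network bar charts display — with the cross-lagged variant
excluding only the autoregressive path and the cross-construct variant
also excluding same-construct paths. The variance reading ("proportion of
variance at a T2 node accounted for by T1 nodes") is implemented
separately as `variance_explained_prediction()`: R² of the fitted linear
predictor with non-permitted coefficients zeroed. Neither is silently
preferred; the `measure` column labels every exported row. Expected
influence for contemporaneous networks is the one-step signed edge sum;
two-step variants are out of scope.

## Bootstrap machinery

Edge accuracy uses the nonparametric bootstrap (resampling rows with
replacement, 1000 replicates by default) with percentile 95% intervals —
the convention of the bootstrap routines this field uses; BCa is not
offered. Difference tests declare two estimands distinct when the
percentile interval of their paired replicate-wise differences excludes
zero (α = 0.05 two-sided; the convention is stated in output metadata
since published reports rarely say).

Centrality stability uses case-drop bootstrapping on the 10-point drop
grid from 5% to 75%: CS is the largest drop proportion at which the
subsample centralities correlate at least 0.7 with the full-sample
centralities with estimated probability at least 0.95 (250 subsamples per
proportion by default). The search walks the grid upward and stops at the
first failure, enforcing a monotone decision. The 0.7/0.95 thresholds and
the grid follow the established stability methodology; the usual reading
applies — CS below 0.25 means the ordering should not be interpreted,
above 0.50 is strong.

A structural property of case-drop CS worth knowing: when all true
centralities are *equal but nonzero*, the subsample estimate correlates
with the full-sample estimate at about `sqrt(1 − q)` purely because the
subsample's rows are a subset of the full sample's — independent of n. CS
then lands near 0.36–0.51 no matter how much data there is. Only when the
true network is empty (all centralities equal at zero, the independence
null) does the ordering become genuinely unstable and CS collapse to 0.
The stability tests use the independence null for exactly this reason.

Everything stochastic — bootstrap resamples, fold assignments, replicate
CLPN refits — draws its seed deterministically from one master seed via
`derive_seed()`, so serial and parallel execution, reruns, and
`replay_run()` agree bit for bit.

## The synthetic-data generator

`default_spec()` encodes a two-wave, nine-node panel shaped like the
motivating study: n = 591 dyads; positive partial-correlation blocks
within positive parenting, within negative parenting, and within the
mental-health problems, with weak negative cross-construct edges
(monitoring–conduct the strongest); an autoregressive diagonal of 0.5 with
cross-lagged paths led by hostility → depression (0.23),
harshness → hostility (0.20) and anxiety → depression (0.19); item counts
and response formats matching the instruments (e.g. 8 warmth items on 1–5,
27 depression items on 0–2); per-scale alpha targets from 0.59 to 0.87;
and covariate effects (gender on externalizing, age on internalizing,
education on positive parenting, income on hostility) large enough that
skipping residualization visibly distorts the networks.

Two generator choices are worth explaining. First, T2 innovations default
to the covariance `Sigma1 − B' Sigma1 B` ("stationary" structure), which
makes the T2 contemporaneous covariance equal the T1 covariance: both
waves share one true network, the situation two-wave studies describe and
the reason averaging the waves' edge tables is meaningful. A diagonal
option exists for pure-VAR experiments. Second, the measurement model is
an exact-reliability construction: each item is the latent score plus
unique noise that sums to zero within the scale, with per-item noise
variance `(1 − α)(k − 1)`. The scale *mean* then equals the latent score
exactly while realized alpha equals its target in expectation — so
continuous-mode data recover the true partial correlations without
attenuation, and reliability calibration is testable to ±0.03 at large n.
Likert discretization (equiprobable normal thresholds per item, skewed
thresholds available) then produces the attenuation real data show;
discretized edges are systematically smaller than their continuous-mode
counterparts on matched seeds.

What the generator does not emulate: item-level multidimensionality,
differential item functioning, missingness mechanisms beyond MCAR
deletion, floor effects beyond threshold skew, and attrition between
waves. Passing recovery tests therefore demonstrates estimator
correctness under a faithful-but-idealized measurement model, not
robustness to every pathology of real questionnaire data.

## What recovery tests can and cannot show

With the full published edge set as ground truth, the acceptance-grade
recovery runs (25 replicates at n = 5000) find the three largest
cross-lagged paths, with correct signs, in every replicate. Rank recovery
of cross-construct out-prediction is a different matter: seven of the nine
true values lie within 0.05 of zero and differ from each other by at most
0.02, while the sampling noise of an estimated coefficient sum at
n = 5000 is itself about 0.02–0.03. The median Spearman correlation
between true and estimated rankings consequently plateaus near 0.78–0.79 —
and replications with perfectly reliable (continuous) measurement land in
the same place, confirming the ceiling is the near-tied ground truth, not
attenuation. The practical lesson transfers to real data: out-prediction
*extremes* are interpretable at these sample sizes; fine distinctions
among near-zero centralities are not, which is precisely what the
bootstrap difference tests are there to flag.

Problem sizes in the test suite are chosen to make each property visible
at comfortable margins: closed-form and convex-solver oracle comparisons
at p ∈ {2, 4}; selection behavior at n = 2000; recovery at n = 5000 over
20–50 seeded replicates; calibration of alpha at n = 100 000 and of
bootstrap coverage over 200 outer simulations with 200 replicates each;
pipeline reproducibility on a 120-row run with reduced bootstrap sizes.

## Degenerate inputs and numerical conventions

Out-of-range or unparseable item responses become missing and are
counted, never silently altered. Zero-variance columns abort correlation
estimation with the column named. Constant predictors are excluded from
lasso fits (coefficient exactly 0) with a warning. Bootstrap replicates
whose refit fails are skipped and logged, with a hard error past 5%.
Cronbach's alpha on a zero-variance total is an error, not NaN. All
reported roundings are half-away-from-zero; all internal computation is
double precision with zeros stored exactly where estimators produce them.

## Limitations

Two waves only — no continuous-time or multi-wave dynamics; no latent
variables (scores enter as observed); no moderated or mixed graphical
models; listwise deletion is the only missing-data policy wired into the
pipeline; and figures are deliberately out of scope — the canonical
outputs are the CSV/GraphML tables behind them, which render anywhere.
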