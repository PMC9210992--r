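---
title: "Models and methods: SRM decomposition and ARRMA estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SRM decomposition and ARRMA estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrma)
```

## The componential model

A directed measurement in a multi-interaction dyadic design — person *i*'s
response to person *j* in group *k* — is decomposed by the Social Relations
Model (SRM) into four components:

$$X_{ijk} = \mu_k + \alpha_{ik} + \beta_{jk} + \gamma_{ijk} + \varepsilon_{ijk}$$

where $\mu_k$ is the group mean, $\alpha_{ik}$ is *i*'s actor effect (a
consistent response tendency toward all partners), $\beta_{jk}$ is *j*'s
partner effect (the response *j* consistently elicits), and $\gamma_{ijk}$
is the relationship effect, *i*'s unique adjustment to *j*.  With a single
indicator per construct, the relationship effect and the measurement error
are confounded; multiple indicators separate them.

For a round robin (every member rates every other member, no self-ratings)
the least-squares estimates accommodate the missing diagonal through the
weighted marginal means

$$\hat\alpha_i = \frac{(n-1)^2}{n(n-2)} M_{i.} + \frac{n-1}{n(n-2)} M_{.i}
  - \frac{n-1}{n-2} M_{..}$$

(and symmetrically for $\hat\beta_j$), with
$\hat\gamma_{ij} = X_{ij} - \hat\alpha_i - \hat\beta_j - M_{..}$.  These
closed forms are the exact solution of the constrained least-squares
problem minimizing $\sum (X_{ij} - \mu - \alpha_i - \beta_j)^2$ over the
defined cells subject to $\sum\alpha = \sum\beta = 0$; the test suite
verifies this equivalence against an explicit design-matrix oracle.  In
blocks (two categories rating each other) the effects are the plain row and
column mean deviations within each block.

Consequences used throughout: actor and partner effect estimates sum to
zero within each group, relationship effect estimates have zero row and
column sums over the defined cells, and
$\hat\mu + \hat\alpha_i + \hat\beta_j + \hat\gamma_{ij}$ reproduces every
defined cell exactly.

## ARRMA

ARRMA models three phenomena simultaneously.  At the individual level, the
actor effect of the metaperception (one's generalized prediction of others'
responses to oneself) is regressed on the actor and partner effects of the
interpersonal response:

$$\alpha_{mp} = b\,\alpha_r + c\,\beta_r + e$$

Path **B** (*assumed reciprocity*) asks whether people believe others
respond to them as they respond to others; path **C** (*metaperception
accuracy*) asks whether others' actual responses predict the
metaperception; parameter **A** (*reciprocity*) is the free covariance of
$\alpha_r$ and $\beta_r$.  The standardized solutions follow from the
correlation algebra of the two-predictor system:

$$b^* = \frac{\rho_{\alpha_r\alpha_{mp}} -
  \rho_{\alpha_r\beta_r}\rho_{\beta_r\alpha_{mp}}}{1-\rho^2_{\alpha_r\beta_r}},
  \qquad
  c^* = \frac{\rho_{\beta_r\alpha_{mp}} -
  \rho_{\alpha_r\beta_r}\rho_{\alpha_r\alpha_{mp}}}{1-\rho^2_{\alpha_r\beta_r}}$$

and identically at the dyadic level with relationship effects
($\gamma_{imp,ji} = b\,\gamma_{ij} + c\,\gamma_{ji} + e$).  Perfect
reciprocity ($|\rho| = 1$) leaves the system unidentified and is an error.

The *full dyadic* model uses both members' metaperception relationship
effects as joint outcomes: two assumed-reciprocity paths (B, B'), two
accuracy paths (C, C'), one reciprocity covariance (A), and a covariance of
the two disturbances (D, the reciprocity of metaperceptions).  With one row
per dyad the model is just identified and reproduces the sample covariance
matrix exactly.

### Indistinguishable dyads

When nothing orders the two members of a dyad, the designation of "member
1" is arbitrary and estimation must respect it.  Two devices are used
together:

* **Pairwise double entry** — each dyad contributes two rows with the roles
  swapped, which forces exchange-symmetric sample moments.
* **Olsen–Kenny equality constraints** — equal predictor means, equal
  predictor variances, equal outcome intercepts, equal disturbance
  variances (disturbance loadings fixed at 1), and equal structural paths
  (B = B', C = C').

The **I-SAT** (indistinguishable-saturated) model imposes only the equality
constraints on an otherwise saturated four-variable model: 8 free
parameters against 14 sample moments (10 covariances + 4 means), hence 6
df.  On pairwise double-entered data the doubled moments satisfy the
equalities exactly and the I-SAT chi-square is identically zero; on
dyad-format data its chi-square reflects only the arbitrary designation and
is subtracted (chi-square and df alike) from any substantive constrained
model's fit.  Constrained path estimates come out within rounding error of
the average of the corresponding unconstrained pair; the test suite checks
this on simulated data, along with full invariance of the constrained
estimates under member relabeling.

## The estimation engine

All non-closed-form fits run through a small maximum-likelihood
covariance-and-mean-structure engine (`ml_fit()`).  Models are declared as
recursive path structures over observed and latent variables (RAM
parameterization); equality constraints are encoded by sharing a parameter
label.  The normal-theory discrepancy

$$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}(\theta)) - \log|S| - p
  + (\bar x - \mu(\theta))'\Sigma^{-1}(\theta)(\bar x - \mu(\theta))$$

is minimized by a quasi-Newton method (`nlminb`, relative tolerance
1e-10, at most 1000 iterations, with a BFGS polish if the first-order
condition is not met).  Start values for covariance and mean labels are
seeded from the sample moments, so saturated blocks start at their optimum;
just-identified models converge to machine-level zero discrepancy.
Convergence is judged by the gradient norm, not the optimizer's return
code.  Identification is checked numerically: a relative eigenvalue of the
observed information below 1e-6 flags a flat direction and raises an
error.  Standard errors come from the observed information; the chi-square
multiplier is $(N-1)$ by default (the convention of mainstream SEM
software), configurable to $N$; the covariance divisor is likewise $N-1$ by
default.  Near-singular sample matrices receive a small ridge
(`1e-8 * trace/p`) with a prominent warning.  Negative variance estimates
are reported with a warning, never silently bounded at zero — transparency
over smoothing.

The Bentler–Bonett NFI is reported against the independence baseline (free
variances and means, zero covariances), whose discrepancy has the closed
form $-\log|R|$ with $R$ the sample correlation matrix.

## Degrees of freedom for pooled effect estimates

SRM effect estimates sum to zero within every group, so a pooled dataset of
$K$ groups of size $n$ carries $K(n-1)$ independent rows of information
rather than $Kn$.  Individual-level fits therefore use residual degrees of
freedom $N - K - 2$ when the records carry group identifiers: path
p-values use the matching t reference, and the restricted model's p-value
uses the exact F reference (the ML discrepancy of the accuracy restriction
equals $\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ of the nested regressions, so
$(e^{F}-1)\cdot\mathrm{df}$ is an F statistic).  Simulation shows the
conventional $(N-1)$ chi-square reference over-rejects a true zero-accuracy
restriction at roughly 13% in 25 groups of 4, while the within-group-df F
reference holds the nominal 5% level.  The chi-square *value* is still
reported with the conventional multiplier so that published results remain
comparable.  Dyadic double-entry fits deliberately report the conventional
doubled-table standard errors (matching how such tables are published);
the rows of a doubled table are not independent, and a dyad-cluster robust
option is available (`robust = "dyad"`).

## The synthetic-data generator

`simulate_srm_arrma()` generates the reference study conditions used in
validation: `K = 25` groups of `n = 4`, grand mean 4 (the midpoint of a
7-point scale), unit actor/partner/relationship variances, generalized and
dyadic reciprocity covariance 0.4, individual paths `b_ind = 0.8`,
`c_ind = 0.1` with disturbance variance 0.3 (so the individual model
explains about 90% of metaperception variance), dyadic paths
`b_dyad = 0.6`, `c_dyad = 0.15` with disturbance variance 0.5 and
disturbance covariance `cov_d = -0.2`.  These magnitudes mirror the
qualitative pattern reported for family similarity judgments: assumed
reciprocity dominant, reciprocity moderate, accuracy weak, metaperception
disturbances negatively related.

One design decision matters for interpretation.  Least-squares relationship
estimates are a linear projection (zero row/column sums) of any underlying
effects, so if raw effects were drawn independently per dyad, the
*estimated* effects would not carry the configured variances at small *n*.
The generator therefore produces effects directly on the estimate scale:

* actor/partner pairs are drawn bivariate normal with covariance inflated
  by $n/(n-1)$ and then centered within the group, so the realized effects
  carry exactly the configured variances and reciprocity covariance;
* relationship-effect pairs are drawn with a covariance pre-inflated by the
  inverse of the exact 2×2 moment map of the round-robin residual
  projection (computed once per group size from the projector itself) and
  then projected, so every realized cell has exactly `var_rel` and every
  yoked pair exactly `cov_rel_dyadic`;
* metaperception effects are built from these by the ARRMA paths, with
  disturbances treated the same way (centered at the individual level,
  projected at the dyadic level, covariance `cov_d` across the two members
  of a dyad — bivariate normality is the package's choice of distributional
  form).

With `var_noise = 0` and a single indicator the decomposition then
recovers the generated effects *exactly*, every fit's estimand coincides
with the configured truth, and the 200-replicate recovery experiment is an
unbiasedness check rather than a check of projection artifacts.  Per-cell
indicator noise (`var_noise`) attenuates dyadic paths, as it must — the
relationship effect absorbs measurement error when only one indicator
exists; averaging `m` indicators recovers most of the attenuation, and the
test suite asserts the direction of both effects.  An optional
`var_shared_noise` adds a noise component shared between the response and
metaperception cells of the same indicator, reproducing the positively
correlated indicator errors seen when one person produces both
measurements; it is off by default.

Seeding is split per group (one sub-seed per group drawn from the global
seed), so enlarging `K` never perturbs earlier groups, and regeneration is
bit-identical.

What the generator does *not* emulate: discrete rating scales (cells are
Gaussian, not 1–7 integers), non-normal or heavy-tailed effects, missing
cells, group-level effect heterogeneity, and person-level covariates.
Passing recovery tests therefore demonstrate correctness of the estimation
pipeline under the componential model, not robustness to violations of it.

## Numerical choices and limitations

* Zero-sum and reconstruction invariants are checked at an absolute
  tolerance of 1e-9 (configurable).
* The minimum round-robin size is 4; `allow_triads = TRUE` admits n = 3
  with a warning (the closed-form weights remain defined, the estimates are
  very unstable).
* Missing off-diagonal cells are a hard error — the closed forms assume
  complete off-diagonal data and no imputation is attempted.  Self-ratings
  found in input files are dropped with a notice.
* Group means are computed and removed per group (per block in block
  designs); no additional cross-group centering is applied before pooling —
  with per-group centering the pooled components are already mean-zero, so
  a second centering would be a no-op on the effects and would only obscure
  the group means.
* Member designation in dyad files is canonicalized lexicographically
  (`i < j`) on ingest, so dyad-format results cannot depend on row order in
  the file.
* Latent (SEM) variants share the engine: three constructs measured by `m`
  indicators each, first loading fixed at 1.00 as the marker, error
  covariances between corresponding response and metaperception
  indicators.  The spec builder intentionally frees `m - 1` loadings per
  construct — three free loadings with `m = 2` — and refuses `m = 1`,
  directing users to the composite path model.  The R² convention for SEM
  fits is 1 − (disturbance variance / model-implied outcome variance).
* Variance-component estimation (with its jackknife significance
  machinery), between-group effects, APIM-style single-interaction designs,
  FIML for missing data, and robust (Satorra–Bentler) corrections are out
  of scope.

## Problem sizes used in validation

The shipped validation uses 50 random round robins for the decomposition
oracle, 200 Monte-Carlo replicates at K = 25, n = 4 for parameter recovery
and for the size of the zero-accuracy test, 20 replicates for the I-SAT
and constraint-averaging properties, and K = 2000–3000 single draws for
generator moment checks — sizes at which Monte-Carlo error is small enough
for three-standard-error assertions while the whole suite runs in a few
minutes on one core.
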