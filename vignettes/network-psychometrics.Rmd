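---
title: "Methods: mixed graphical model networks for psychometric cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed graphical model networks for psychometric cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psychnet)
```

psychnet implements the complete analysis pipeline of a network
psychometrics study of insomnia in major depressive disorder: estimation
of a regularized conditional-dependence network over mixed questionnaire
variables, centrality and bridge analytics over questionnaire
communities, shortest pathways, and bootstrap stability — together with a
synthetic cohort generator that makes every stage testable against known
ground truth. This vignette records the model, its assumptions, the
tunable parameters, and the design decisions taken where the methodology
left genuine choices open.

## The statistical model

The network is a Markov random field over p variables of mixed type. It
is estimated by nodewise penalized regression: each node is regressed on
all others (linear least squares for continuous targets, multinomial
logistic for categorical targets) with an L1 penalty, and the penalty is
chosen per node by the extended Bayesian information criterion

$$\mathrm{EBIC}(\lambda) = -2\hat\ell + k\log n + 2\gamma k \log p_{\mathrm{cand}},$$

where $k$ counts nonzero coefficients and $p_{\mathrm{cand}}$ counts
candidate predictor columns after dummy expansion. Two neighborhood
estimates exist for every pair; the AND rule keeps an edge only when both
select it. Under correct model specification and sparsity, this
neighborhood-selection strategy consistently recovers the conditional
independence graph; for all-continuous data the edge weights are
monotonically related to partial correlations.

Assumptions worth keeping in mind:

* conditional dependencies are pairwise (no three-way interaction
  terms);
* continuous variables are jointly Gaussian *after* the nonparanormal
  transformation — ordinal Likert items and subscale totals are treated
  as continuous, which is the convention of this literature but is an
  approximation for 5-point items;
* observations are i.i.d. complete cases.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.25 | EBIC sparsity pressure, on [0, 0.5]; 0 is plain BIC |
| `rule` | `"AND"` | neighborhood combination; `"OR"` available |
| `nlambda` | 100 | penalty path length, log-spaced from the per-node $\lambda_{\max}$ down to $10^{-3}\lambda_{\max}$ |
| `standardize` | `TRUE` | z-score continuous variables within each nodewise fit so weights are comparable across edges |
| `npn` rule | `"skewed"` | transform continuous columns with moment-ratio skewness over 1 |
| `n_boot` | 1000 | bootstrap replicates for stability/CIs |
| `drop_proportions` | 0.05–0.75 by 0.05 | case-dropping grid |
| `cor_threshold`, `prob_level`, `cs_pass` | 0.7, 0.95, 0.25 | CS-coefficient rule |

γ = 0.25 is the conventional compromise between sensitivity and
false-edge control in this literature and is the default here. The AND
rule is the conservative default of the mixed-graphical-model packages
this workflow descends from; OR is offered because individual studies
occasionally prefer it.

## The nonparanormal transformation

Skewed continuous variables are Gaussianized as
$x \mapsto s\,\Phi^{-1}(T_\delta(\hat F(x)))$, where $\hat F$ uses
average ranks divided by $n$, $T_\delta$ winsorizes into
$[\delta_n, 1-\delta_n]$ with
$\delta_n = 1/(4 n^{1/4}\sqrt{\pi \log n})$, and $s$ rescales to unit
sample SD. This is the truncated-ECDF variant, chosen as the de-facto
standard; shrinkage-ECDF alternatives differ only at the extreme ranks.
Which columns to transform is a genuinely open choice: published
analyses rarely enumerate them. The package's rule — transform when
|skewness| > 1 — is deterministic and reported in the transform object;
`rule = "all"` and `"none"` override it. Ties share average ranks, so
tied observations map to identical transformed values; the transform is
invariant under strictly increasing maps and idempotent up to
floating-point noise.

## Edge weights, signs, and categorical nodes

Per-neighbor coefficients are aggregated as the mean of absolute values
over the dummy/class coefficients linking target and neighbor; the edge
weight is the mean of the two nodewise aggregates. A sign exists only
for continuous–continuous edges; when the two regressions disagree in
sign (rare, and only possible near zero) the edge is zeroed with a
warning rather than given an arbitrary sign. Edges with a categorical
endpoint are magnitude-only, and the per-edge `sign_defined` flag
records this — these are the edges drawn in gray in the field's network
figures.

This has one consequence the user should know: in expected influence and
bridge expected influence, unsigned edges contribute their magnitude.
Implementations that silently treat unsigned magnitudes as positive
signed weights produce the same numbers, but the convention is stated
here because it is a divergence risk against sign-assuming code.

## Centrality, bridges, and pathways

Strength, expected influence (1-step), bridge strength and bridge
expected influence (1-step) are plain sums over the weight matrix, with
each questionnaire declared as one community. Exact identities — the
strength decomposition $s_i = s_i^{\text{within}} + bs_i$ and the
equality of strength and EI on all-positive networks — are enforced in
the test suite against a brute-force summation oracle.

"Shortest pathways" are computed over edge distances $1/|w|$, the
convention of the network-pathways literature (strong edges are short);
`metric = "hops"` provides the literal minimum-step reading. Among
equal-distance paths the lexicographically smallest node-name sequence
is returned. This tie-break is why the search is implemented as
label-correcting relaxation in the package rather than delegated to a
graph library: determinism of reported pathways matters more than
asymptotic speed on networks of a few dozen nodes. Distance ties are
detected with a relative tolerance of 1e-9.

Domain screening mirrors the study design: a psychosocial domain enters
the integrated network only if its symptom-plus-domain network contains
at least one nonzero domain–symptom edge.

## Stability and accuracy

The case-dropping bootstrap subsamples without replacement at each grid
proportion, re-estimates the network, and correlates each centrality
index with its full-sample counterpart. The CS coefficient is the
largest grid proportion $p$ such that at *every* proportion $q \le p$
the empirical 5th percentile of replicate correlations is at least 0.7
("with 95% probability" is operationalized as the empirical 5th
percentile, R's default quantile type 7). The monotone guard prevents a
non-contiguous pass region from inflating the coefficient. Replicates
with failed estimation or constant index vectors have undefined
correlations; these are conservatively recorded as 0 and counted in the
report. Per-replicate seeds are derived from the master seed up front,
so results are independent of execution order and bit-reproducible.

Edge-weight accuracy uses the nonparametric bootstrap: full-size
with-replacement resamples, percentile 2.5/97.5 bounds, zeros included
when an edge is unselected in a resample. These intervals describe
sampling variability of the *regularized* estimate; because the LASSO
shrinks, they should not be read as significance tests — the acceptance
suite nevertheless verifies ≈95% coverage of the true latent weights in
the regime it simulates (3-node chains, partial correlation 0.3,
n = 500), where selection variability widens the intervals enough to
absorb shrinkage bias.

## The synthetic cohort generator

The generator exists because the patient data underlying this design are
not public. It draws a latent multivariate normal whose precision matrix
encodes a known sparse partial-correlation graph, then maps each column
through a monotone discretization (Gaussian copula): clamped rounding
$x = \mathrm{clamp}(\mathrm{round}(\mu + \sigma z))$, with $(\mu,
\sigma)$ solved per variable so the discretized mean and SD hit their
targets (Nelder–Mead on exact category probabilities; the solver warns
beyond 0.05 absolute mean error, and the test suite checks all achieved
means within 0.05 and SDs within 0.08). Boundary censoring is what
produces the strongly right-skewed trauma marginals from a normal
latent.

The `paper_like` preset fixes the marginal targets at the published
cohort descriptives (n = 791; ISI items, EPQ/IRCDS/CTQ/SSRS subscales,
HAMD-14/17, age, 75.9% female, medication-group frequencies) and plants
a structure that echoes the study's qualitative findings: a dense
insomnia block whose strongest links are maintenance–early-awakening and
worry–daytime edges, a neuroticism bridge into the insomnia community,
weak interpersonal and social-support links, and a childhood-trauma
block with no edges to any other community. Two calibration details:

* the shared inter-item latent partial of the insomnia block (0.136) was
  calibrated once, by simulation, so that the prevalence of ISI ≥ 8
  reproduces the reported 67%; the ISI-total SD and kurtosis then emerge
  untuned in the vicinity of the published 6.49 and 2.278;
* the medication covariate shifts the severity latents (untreated
  highest, antidepressant-only lowest), making the severity latent a
  normal mixture — the threshold solver uses that mixture CDF, not the
  standard normal, or the severity marginals would drift by about a
  tenth of a point.

Categorical covariates are drawn independently of the latent field
(except for the severity link); the generator is *not* a model of the
real joint distribution of demographics and symptoms. What passing
tests show is that the pipeline recovers known structure from data with
realistic marginals and copula dependence; they cannot show robustness
to features the generator omits — item-level measurement error,
informative missingness, floor effects beyond those implied by
censoring, or non-Gaussian copulas.

`chain` and `independent` presets provide raw-Gaussian fixtures for
parameter recovery and false-positive checks, with the generating
adjacency returned as ground truth.

## Numerical choices and degenerate inputs

* Per-node λ paths come from glmnet (100 values, min ratio $10^{-3}$);
  EBIC ties resolve to the larger (sparser) penalty.
* $p_{\mathrm{cand}}$ counts dummy-expanded predictor columns, since the
  EBIC reference count is not standardized in this setting.
* Constant columns are fatal at estimation time (and at dataset
  construction unless explicitly allowed, as bootstrap resampling
  requires); missing data are handled by listwise deletion with a logged
  count, matching the complete-case design — no imputation is offered.
* Dummy coding uses the first declared level as reference; multinomial
  class coefficients are aggregated by mean absolute value.
* The validation suite runs at reduced problem sizes chosen to keep the
  full run in minutes on one core: recovery at n = 2000 over 20 seeds,
  stability at n_boot = 100 on a 15-point drop grid with a 30-value λ
  path, CI coverage over 50 datasets at n_boot = 200, calibration over
  40 cohorts of n = 791 (the acceptance script reports over 20). The
  shipped defaults (n_boot = 1000, 100-value paths) are the
  study-scale settings.

## Known limitations

* Ordinal items enter as continuous (after rank-Gaussianization);
  no dedicated ordinal or Poisson node families.
* No moderated (three-way) interactions; no network comparison tests or
  centrality difference tests.
* Bridge indices are 1-step only.
* The generator produces subscale totals directly rather than item by
  item (except the seven insomnia items), so item-level psychometrics
  of the factor scales cannot be simulated.
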