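---
title: "Sex-stratified copula graphical models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified copula graphical models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

`rankggm` estimates and compares conditional-association networks in aging
cohorts where the variables are a deliberately mixed bag: inflammatory
biomarkers (IL-6, IL-8, IL-10, IL-12, CRP) that are continuous but
non-normal and zero inflated (assay floors produce a point mass at zero), a
bounded integer depression score (0–15), a continuous global cognition
z-score, ordinal education (1–5) and alcohol-frequency (1–6) scales, a
continuous cardiovascular risk score, and a binary APOE-ε4 carrier flag.
The scientific questions are (i) which pairs of variables are conditionally
associated given all the others, separately in males and females; (ii)
which of those associations differ between the sexes; and (iii) whether
differences flagged in a first measurement wave survive confirmatory
testing on a second wave two years later.

## Model

### Gaussian copula with extended rank likelihood

For each sex stratum we posit latent variables $z_{i1}, \dots, z_{ip}$ per
subject $i$, jointly Gaussian with precision matrix $K$, and assume each
observed variable is a non-decreasing transform of its latent column. Only
the *ordering* of the observations is used: the likelihood is the
probability that the latent matrix falls in the set $D$ of matrices whose
within-column ranks match the observed ranks (ties impose no constraint
among themselves). This extended rank likelihood sidesteps estimating the
margins entirely, which is what makes zero-inflated biomarkers, counts,
ordinal scales, and a binary indicator all digestible by one model. A
binary variable simply enters as a two-level, tie-heavy ordinal column; no
separate probit branch is needed.

The estimand is the matrix of partial correlations

$$\rho_{jk} = -\frac{K_{jk}}{\sqrt{K_{jj} K_{kk}}},$$

which is invariant to the scale of the latent columns, so no explicit
latent standardization step is required (or used).

### Gibbs sampler

The sampler alternates:

1. **Latent update.** Each cell $z_{ij}$ is redrawn from its univariate
   conditional normal, truncated to the interval
   $(\max\{z_{i'j}: y_{i'j} < y_{ij}\},\ \min\{z_{i'j}: y_{i'j} > y_{ij}\})$
   defined by the *current* latents of cells at strictly lower / strictly
   higher observed levels. The sweep is column-major (variable, then
   subject), in a fixed order, so a run is reproducible from its seed.
   Within a column the per-level bounds are maintained incrementally
   (suffix minima computed at column start, a running maximum as levels are
   ascended), making the sweep $O(np)$ per iteration rather than
   $O(n^2 p)$. Missing cells are redrawn from the *untruncated*
   conditional: this is posterior-predictive imputation happening inside
   the sampler, so missing data never require a separate imputation pass.
2. **Precision update.** Given the latent matrix $Z$, the full conditional
   of $K$ under a Wishart$(\nu_0, V_0)$ prior is
   Wishart$(\nu_0 + n, (V_0^{-1} + Z^\top Z)^{-1})$, sampled by Bartlett
   decomposition.

Truncated-normal draws use the inverse-CDF method; when a truncation
window's probability mass underflows (possible transiently early in a
chain), the draw falls back to the window midpoint and still consumes one
uniform so the RNG stream stays aligned. All randomness comes from R's RNG:
a run is bit-reproducible from `set.seed`, and because only level codes
enter the C++ core, the entire posterior is invariant — bit for bit at a
fixed seed — under strictly monotone transforms of any margin.

### Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| prior df $\nu_0$ | $p + 2$ | smallest integer df giving a proper, weakly informative Wishart with finite prior mean |
| prior scale $V_0$ | $I_p$ | diffuse conjugate default; posterior dominated by data at the cohort sizes in view |
| retained draws | 5000 | matches the convention of summarizing each edge with 5000 posterior estimates |
| burn-in | 500 | the chain mixes fast (conjugate precision step); split-chain $\hat R$ is monitored per edge and warned about above 1.1, not treated as an error |
| thinning | 1 | autocorrelation is modest; draws are cheap to store at $p = 11$ |
| credible level | 0.95 | the field's selection rule: an edge is kept iff its 95% equal-tailed CI excludes zero |
| PP threshold | 0.95 | one-directional posterior probability above 0.95 counts as confirmation |

Equal-tailed (quantile) intervals are used rather than HPD: they are
order-statistic exact, invariant to monotone reparameterization per edge,
and match common practice for reported partial-correlation intervals.

## Group comparison and the two-wave design

Differences are formed by pairing posterior draws index-by-index across
the two strata's independent chains (female minus male, fixed and labelled
in all outputs): the difference sample has exactly the retained draw count,
whereas cross-pairing all draws would change its Monte-Carlo properties.
Each edge gets a mean difference and a 95% equal-tailed CI; significant
edges become directional hypotheses (direction = sign of the mean
difference). On wave 2, a hypothesis's posterior probability is the
fraction of paired draws satisfying the inequality strictly, with exact
ties counting one half — which makes pp(direction) + pp(opposite) = 1
exactly. No multiplicity correction is applied across the 55 edges; the
exploratory-to-confirmatory design is the error-control device, and
reports flag this.

Hypotheses are serialized to YAML between waves, and the confirmatory
report records the MD5 of the hypothesis file it tested.

## The synthetic cohort generator

Because the motivating cohort data are restricted-access, the package
ships a generator that emulates the *structure* of such data, not any real
cohort's numbers: per sex, latent Gaussian rows with the correlation
matrix implied by a configured true partial-correlation network, pushed
through per-variable monotone margins (probability integral transform).
Zero inflation is implemented as left-censoring of the latent at the
inflation quantile, which keeps the copula's latent-Gaussian assumption
literally true — recovery tests therefore have a well-defined target.
Missingness is MCAR by default (5% per variable) since the motivating
study does not characterize its missingness mechanism.

Wave 2 redraws time-varying variables with latent autocorrelation 0.7 to
the subject's wave-1 latents; education and APOE-ε4 are frozen as stable
traits. Dropout follows a logistic model on age, depression and cognition;
the bundled scenario uses intercept logit(0.12) with coefficients 0.06 per
year of age, 0.12 per depression point and −0.35 per cognition SD, giving
roughly 15% attrition in which dropouts are older, more depressed and
lower-scoring — the qualitative completer/dropout profile such cohorts
report.

The bundled 11-node scenario has 450 subjects per sex and nine edges per
sex with magnitudes 0.25–0.35: a shared biomarker backbone (IL-6 connected
to every other biomarker), shared education–cognition and APOE-ε4–CRP
edges, female-only depression–cognition (−0.3) and IL-8–alcohol edges, and
male-only IL-8–cognition and CRP–risk edges. Magnitudes sit in the upper
half of the plausible band *by design*: an a-priori power analysis using a
frequentist fit on the true latent Gaussian data (an oracle independent of
this package's estimator) shows truth–estimate correlations of about 0.94
at n = 450, leaving headroom for the 0.9 recovery target the scenario
exists to exercise; weaker networks make that target unattainable for any
estimator at this sample size.

### What a green test does and does not establish

The generator satisfies the copula model exactly (monotone margins of
truly Gaussian latents, MCAR missingness). Green recovery and calibration
tests therefore establish correctness of the machinery, not robustness to
model violations real cohorts can exhibit: margins that are not monotone
transforms of anything Gaussian, informative missingness, measurement
error correlated across variables, or confounding by variables outside
the node set.

Two behaviours of the *stated world* are worth knowing when reading test
output:

* **Waves are not independent.** With latent autocorrelation 0.7 and
  shared subjects, wave-1 sampling noise partially persists into wave 2, so
  a spurious exploratory difference has a better-than-nominal chance of
  being "confirmed". This mirrors the real design's limitation (a
  follow-up wave of the same people is not an independent replication) and
  is left in deliberately.
* **Informative attrition biases paired tests.** When dropout depends on
  cognition, completers are selected on their wave-1 values and regression
  to the mean makes paired wave differences genuinely nonzero even with no
  generating shift. Null-calibration checks of the paired t-test therefore
  use flat (non-informative) attrition.

## Numerical choices and degenerate inputs

* Constant variables are rejected at rank-bound computation with the
  variable named; every variable needs at least two distinct observed
  values per stratum.
* A paired t-test whose difference vector has zero variance is reported
  with a `degenerate` flag (p forced to 0 when the mean is nonzero; t = 0,
  p = 1 when all differences are zero) rather than erroring, so synthetic
  edge cases cannot crash a robustness sweep.
* Welch comparisons of constant groups report t = 0, p = 1, d = 0.
* Force-directed layouts are averaged only after Procrustes alignment
  (rotation/reflection/scaling to the first network's layout); averaging
  independently rotated layouts would be meaningless. With identical
  inputs the average equals the single-network layout exactly.
* Figures are emitted as hand-generated SVG so rendering needs no graphics
  device; the drawn edge count is recorded in the SVG root's `data-edges`
  attribute for structural audit.

## Known limitations

* One estimation path (sampling + CI selection) is used for both waves;
  Bayes-factor exploration machinery is intentionally out of scope.
* The sampler's single-site latent updates mix slowly for extremely
  tie-heavy columns at very large n; at the cohort sizes in view (hundreds
  per stratum) split-chain $\hat R$ stays near 1 with the defaults.
* Whether imputation should pool sexes before stratifying is unknowable
  from the motivating description; this implementation imputes within each
  stratum fit, consistent with fitting strata independently.
* The cardiovascular risk score is consumed as a generic continuous
  variable; no transformation is applied or assumed.
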