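---
title: "Modelling individual grain-weight distributions as Gaussian mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individual grain-weight distributions as Gaussian mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainmix)
```

## The model

Each treatment group — one cultivar at one seeding rate sampled at one
number of weeks after heading (WAH) — contributes a sample of individual
grain weights $x_1, \dots, x_n$ in milligrams. We model the sample as a
k-component univariate normal mixture

$$p(x) = \sum_{i=1}^{k} \pi_i\, \mathcal{N}(x \mid \mu_i, \sigma_i^2),$$

with mixing weights $\pi_i > 0$ summing to one. The scientific question
is about $k$: a single normal ($k = 1$) says the grains form one
homogeneous population; $k = 2$ says two populations (in Triticeae, the
natural candidates are grains from different floret positions within the
spikelet). The model's assumptions are those of any finite normal
mixture: within-component normality, independent grains, and a common
component family across the sample. Grains from the same head are *not*
modelled hierarchically — the head enters only through the sampling
design (which heads are weighed at all), not the likelihood.

Fitting is by expectation–maximisation. The E-step computes
responsibilities $r_{ij} = \pi_j \mathcal{N}(x_i \mid \mu_j, \sigma_j) /
\sum_l \pi_l \mathcal{N}(x_i \mid \mu_l, \sigma_l)$ in log space with
log-sum-exp stabilisation; the M-step uses the standard
responsibility-weighted updates with MLE ($1/n$-type) variances, matching
the likelihood being maximised. Sample-sd ($n-1$) conventions appear only
in descriptive summaries, never inside EM. For $k = 1$ no iteration is
needed: the fit is the closed-form normal MLE.

## Choosing k

Candidates $k = 1 \dots k_{\max}$ (default 3) are compared by AICc and
BIC with $K = 3k - 1$ free parameters. Both criteria are computed with
exact natural logarithms — e.g. the BIC penalty at $n = 300$, $K = 2$ is
$2\ln 300 = 11.40756\ldots$, not a pre-rounded $2 \times 5.703 = 11.406$.
AICc is preferred over raw AIC because per-group sample sizes (a few
hundred grains from five heads) are small relative to the 8 parameters of
a 3-component mixture. Ties are broken toward smaller $k$ (parsimony; the
records are ordered by $k$ so the first argmin wins). The sample size $n$
entering AICc and BIC is the post-filter group size — the criteria are
computed on exactly the sample that was fitted.

AICc and BIC deliberately answer different questions, and on grain-weight
shaped data they disagree in a characteristic way: BIC's heavier penalty
($K \ln n$ vs $2K$ once $n \ge 8$) makes it conservative about extra
components, while AICc will reward a third component whenever the
log-likelihood gain exceeds roughly 3 nats. Our simulation suite (see
"What the tests show" below) reproduces this: on two-component truth BIC
almost always stops at $k = 2$, whereas AICc selects a third component in
a non-trivial minority of replicates. This is not an optimiser defect —
the extra-component optima are genuine, verified against an independent
direct-summation likelihood oracle — but the known tendency of
AIC-family criteria to overfit mixture order. Conclusions about
bimodality should therefore rest on the two criteria jointly, as the
pipeline reports them.

## Numerical design

**Standardisation.** For $k \ge 2$ the sample is internally z-scored, EM
runs on the standardised scale, and parameters are mapped back
($\mu = m + s\mu_z$, $\sigma = s\sigma_z$, $\ln L = \ln L_z - n \ln s$).
This makes the whole fit exactly translation/scale equivariant (fitting
$ax + b$ gives $a\mu + b$, $a\sigma$, identical weights, and
$\ln L - n\ln a$) and puts tolerances and floors on a scale-free footing.

**Initialisation and restarts.** Restart 0 is deterministic: component
$j$ starts at the $(j - 0.5)/k$ sample quantile with unit (global) sd and
equal weights. Restarts $1..R-1$ perturb those means with seeded Gaussian
noise (sd 0.5 on the standardised scale). Default $R = 10$;
reproducibility comes first, basin escape second, and every restart's
seed derives from the single user-facing seed.

**Convergence.** Relative log-likelihood change below `tol` (default
1e-8) or 1000 iterations. The winning restart is the highest
log-likelihood among non-degenerate runs.

**Degeneracy.** Component sds are floored at $10^{-4}$ times the data
range; a restart whose floored component also has weight below $10^{-3}$
is discarded (the unbounded-likelihood point-mass pathology). If every
restart degenerates, the fit errors out with per-restart diagnostics
rather than returning something silently wrong. Zero-range samples and
$n < 3k$ are rejected up front.

**Labelling.** Components are always reported sorted by mean ascending.
Mixture likelihoods are label-symmetric, so any consistent order is
valid; mean-ascending makes "the lighter component" a stable, comparable
notion across groups and seeds, and the $k = 2$ report's mean difference
is then non-negative by construction.

## Preprocessing decisions

The pipeline fixes the stage order as: select heaviest heads, then filter
outliers, then fit. "Heaviest head" means largest *sum of threshed grain
weights* — chaff is not in the data model, so head weight with chaff is
not computable; grain-sum is the deterministic, order-invariant proxy
(ties break by head identifier). The IQR filter removes values outside
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ with quartiles from
linear interpolation of order statistics (`stats::quantile` type 7); both
the multiplier and the quantile type are configurable because published
analyses rarely state them and the fences depend on the estimator. The
filter is applied exactly once per group, after head selection — filtering
before selection would let a single gross outlier decide which heads are
"heaviest". Min–max scaling, used only for shape-comparison densities, is
per group, so each panel spans $[0, 1]$.

## The synthetic-data generator

`simulate_group()` draws, per head, a grain count uniform on a configured
range (default 47–82, the span of per-spike grain counts in field data
for these cultivars), then grain weights from the group's two-component
mixture. Three deliberate choices:

- **Negative draws are redrawn, not clipped.** Clipping would create a
  point mass at zero that corrupts mixture-recovery tests.
- **A head-level lognormal multiplier** (sdlog 0.05, i.e. ±5% per head)
  makes "heaviest heads" a meaningful selection. Field data surely has
  between-head variance; its magnitude is not separately identifiable
  from published tables, so the default is kept small enough that
  mixture recovery stays within test tolerances, and it is recorded in
  every manifest.
- **Gross outliers** (default rate 1%) are injected as uniform extremes
  5–8 mixture-sds from the mixture mean, giving the IQR filter something
  real to do.

`default_scenarios()` provides a 36-group study (3 cultivars × 3 seeding
rates × 2/3/4/5 WAH). The 4- and 5-WAH cells use explicit two-component
parameters spanning component separations from 6.2 to 27.1 mg and
proportions from 0.03 to 0.97 — the realistic range for near-harvest
triticale-type distributions. For 2- and 3-WAH cells only overall
mean/sd targets are available from descriptive tables, so components are
placed at mean ± 0.8 sd with sds 0.6 sd and equal weights: this
reproduces the target mean exactly, the target sd to within 1%, and
gives the mildly non-normal, narrow early-filling shape. Across WAH the
presets drift right and broaden, emulating grain filling.

What the generator does *not* emulate: measurement discretisation (a
1-mg balance), floret-position biology as an explicit mechanism (the
mixture *is* the model), within-head covariance beyond the scalar
multiplier, and year/site environmental effects. Passing tests therefore
certify the statistical machinery on data satisfying the model's
assumptions — they do not certify that any particular field dataset has
two components.

## What the tests show

The suite checks, among other things: exact closed-form behaviour of the
$k = 1$ fit; per-iteration log-likelihood monotonicity; responsibility
and weight normalisation; exact scale equivariance; agreement of the
log-likelihood with a naive direct-summation oracle; recovery of a
moderately overlapping two-component truth (means within ±1.5 mg,
weights within ±0.08, at $n = 2000$, in at least 18 of 20 seeded
replicates); and the selection operating characteristics of both
criteria over 200 seeded datasets per condition at $n = 300$. For that
last simulation the EM settings are scaled to the problem
($R = 4$ restarts, `tol` 1e-7, 500-iteration cap) so the 400-dataset
sweep completes in minutes; selection outcomes are insensitive to the
tighter defaults. End-to-end, the pipeline run on a fixed synthetic
study is asserted byte-identical across reruns.

## Known limitations

- Mixture order selection is hard at small separations: components
  closer than about one pooled sd are effectively unidentifiable at
  $n \approx 300$, and the criteria will (correctly) prefer $k = 1$.
- AICc's appetite for a third component (above) means per-group AICc
  selections of $k = 3$ on two-component truth are expected at a rate of
  roughly one in five; report both criteria.
- The EM fits a *global* maximum only as well as its restart policy
  explores; pathological multimodal likelihoods can in principle defeat
  any finite restart scheme.
- Weights are treated as exact; a 1-mg balance quantises early-WAH
  grains (3–17 mg) fairly coarsely, which slightly inflates component
  sds relative to the underlying continuous weights.
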