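# grainmix

Gaussian mixture modelling of individual grain-weight distributions.

## The problem

Grain weight in cereals is usually summarised by a mean — thousand-grain
weight — but the per-grain distribution within a head is often not a single
normal. In Triticeae cereals (wheat, rye, triticale), florets at different
spikelet positions fill to different final weights, so the distribution of
individual grain weights can be a mixture of a lighter and a heavier
component. A mean hides this structure; a mixture model quantifies it.

`grainmix` fits univariate Gaussian mixture models (GMMs)

$$p(x) = \sum_{i=1}^{k} \pi_i \, \mathcal{N}(x \mid \mu_i, \sigma_i^2),
\qquad \sum_i \pi_i = 1,$$

to per-group samples of individual grain weights (mg) by
expectation–maximisation, and chooses the number of components
$k \in \{1, \dots, k_{\max}\}$ by the small-sample corrected Akaike
criterion and the Bayesian information criterion,

$$\mathrm{AIC} = 2K - 2\ln L, \qquad
\mathrm{AICc} = \mathrm{AIC} + \frac{2K(K+1)}{n - K - 1}, \qquad
\mathrm{BIC} = K \ln n - 2\ln L,$$

where $K = 3k - 1$ is the free-parameter count of a k-component univariate
mixture. Around the model sit the preprocessing stages used in grain
phenotyping: selection of the heaviest heads per treatment group, 1.5×IQR
outlier removal, min–max scaling for shape comparison, Shapiro–Wilk
normality checks — plus a synthetic-data generator that simulates whole
cultivar × seeding-rate × sampling-time studies with known truth, so the
entire pipeline is testable end to end.

It is aimed at crop phenotyping researchers who weigh individual grains
and want to ask: *is this distribution one normal, or two, and what are
the components?*

## Worked example

Fit mixtures with k = 1, 2, 3 to a sample of 380 grain weights drawn from
a two-component truth (means 41.1 and 57.2 mg, sds 11.4 and 4.1 mg, equal
proportions — a configuration typical of a near-harvest distribution):

```r
library(grainmix)
set.seed(180)
comp <- rbinom(380, 1, 0.5)
w <- rnorm(380, ifelse(comp == 0, 41.1, 57.2), ifelse(comp == 0, 11.4, 4.1))

fits <- lapply(1:3, function(k) fit_em(w, k, seed = 180))
sel <- select_model(fits)
sel$records
#>   k K   n log_likelihood     aic    aicc     bic best_aicc best_bic
#> 1 1 2 380       -1485.84 2975.68 2975.71 2983.56     FALSE    FALSE
#> 2 2 5 380       -1427.93 2865.86 2866.02 2885.56      TRUE     TRUE
#> 3 3 8 380       -1427.53 2871.06 2871.45 2902.58     FALSE    FALSE

report_k2_components(fits[[2]])
#>   mean_low sd_low prop_low mean_high sd_high prop_high mean_diff
#> 1    39.92  11.56    0.493     56.75   4.266     0.507     16.82
```

Both criteria prefer k = 2: the two-component fit gains ~58 in
log-likelihood over a single normal, far more than its extra-parameter
penalty, while the k = 3 fit gains only 0.4 more and is penalised away.
The component report recovers the truth: means 39.9/56.7 mg (truth
41.1/57.2), proportions 0.49/0.51 (truth 0.5/0.5), and a component mean
gap of 16.8 mg (truth 16.1).

The complexity penalties themselves, at n = 300:

```r
criteria_demo(n = 300, K = c(2, 5, 8))
#>  K aic_penalty aicc_penalty bic_penalty
#>  2           4     4.040404    11.40756
#>  5          10    10.204082    28.51891
#>  8          16    16.494845    45.63026
```

## Whole-study pipeline

`run_analysis()` takes a long-format CSV (one row per grain: `cultivar`,
`seeding_rate`, `wah`, `head_id`, `weight`; other headers can be remapped)
and, per treatment group: selects the heaviest heads, filters IQR
outliers, fits k = 1..k_max, tabulates the criteria, and writes
descriptive/normality/selection/component CSVs plus density curves and a
JSON run manifest. Everything is seeded and byte-reproducible.

```r
simulate_study(default_scenarios(), "study.csv", seed = 1)
run_analysis(pipeline_config(input = "study.csv", output_dir = "out",
                             seed = 1))
```

A thin command-line front end with `simulate`, `analyze` and
`criteria-demo` subcommands is installed at
`system.file("scripts/grainmix.R", package = "grainmix")`.

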