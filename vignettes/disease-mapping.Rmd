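---
title: "Small-area disease mapping with carprev: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease mapping with carprev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carprev)
```

## The problem

`carprev` analyses the spatial distribution of treated disease prevalence
over small administrative areas (census micro-neighbourhoods of roughly
2000 adult residents). The data are a per-area case count $y_k$, a
stratified population at risk, ecological covariates, and an adjacency
structure. The scientific questions are: is the spatial distribution of
cases non-random, which ecological characteristics (economic deprivation,
migrant density, social fragmentation) explain it, and which areas carry
significantly raised risk ("hotspots")?

The package implements the full escalation strategy such studies use:
start with the simplest model and move to more complex ones only when
validity checks demand it.

## Models

All models share the count likelihood with a log link and a
log-population offset, so coefficients are log rate ratios:

$$y_k \sim \text{Poisson}(\mu_k), \qquad
\log \mu_k = \log n_k + \beta_0 + x_k^\top \beta \;[+\, \phi_k + \theta_k].$$

**Frequentist stage.** `fit_poisson()` fits the plain Poisson GLM;
`fit_negbin()` fits the NB2 model (variance $\mu + \mu^2/\theta$) when
the counts are overdispersed. Two diagnostics gate the escalation:

* **Dean's score test** (`dean_test()`), the unadjusted statistic
  $P_B = \sum_k [(y_k-\hat\mu_k)^2 - y_k] \,/\, \sqrt{2\sum_k \hat\mu_k^2}$,
  compared one-sided to N(0, 1). We chose the unadjusted variant because
  it is the standard score form for Poisson GLMs; a known consequence is
  that at a few dozen areas the null distribution sits slightly below
  N(0, 1) (a mean shift of order $p/\sqrt{2n}$ from parameter
  estimation), so the *full* null distribution is measurably non-normal
  even though the one-sided 5% rejection rate — the thing the decision
  uses — is accurately calibrated (0.047 over 1000 null replicates at
  $n = 56$ in the acceptance run).
* **Moran's I** (`moran_test()`) on the Pearson residuals of the best
  frequentist fit, with binary (not row-standardized) weights, null
  expectation $-1/(n-1)$, and either the randomization-assumption normal
  approximation or a Monte-Carlo permutation p-value. One-sided
  alternatives are the default for both diagnostics because
  overdispersion and *positive* autocorrelation are the directional
  alternatives of scientific interest.

**Bayesian stage.** `fit_car()` adds Gaussian random effects with one of
four conditional autoregressive (CAR) structures:

| structure | effect | precision of the field |
|---|---|---|
| `ind` | exchangeable $\theta$ | $\sigma^{-2} I$ |
| `iar` | intrinsic $\phi$ | $\tau^{-2}(D - W)$ (singular) |
| `bym` | $\phi + \theta$ | both of the above |
| `leroux` | $\phi$ | $\tau^{-2}[\rho(D-W) + (1-\rho)I]$ |

$W$ is the binary adjacency matrix, $D$ its degree diagonal. The Leroux
mixing parameter $\rho \in [0,1]$ interpolates between the independent
($\rho = 0$) and intrinsic ($\rho = 1$) limits; `car_precision()` exposes
these matrices directly and the limits are exact algebraic identities.

## Inference and numerical choices

Sampling is Metropolis-within-Gibbs, implemented in compiled code:

* random-walk Metropolis for each regression coefficient and each
  random-effect site (the Poisson likelihood is non-conjugate);
* conjugate inverse-gamma Gibbs draws for $\tau^2$ and $\sigma^2$;
* random-walk Metropolis with boundary reflection for $\rho$, with the
  exact log-determinant of the Leroux precision computed in $O(n)$ per
  proposal from the precomputed eigenvalues of $D - W$;
* sum-to-zero recentring of the structured field $\phi$ every sweep, for
  identifiability with the intercept. Because the recentred field has
  $n - 1$ free dimensions, the inverse-gamma update for $\tau^2$ uses
  shape $a + (n-1)/2$ under every structure; using $n/2$ with a
  constrained field biases $\tau^2$ downward. This choice also makes the
  Leroux sampler at $\rho = 1$ coincide exactly with the intrinsic one.
* proposal scales adapt only during burn-in (targeting acceptance rates
  0.2–0.6) and are frozen afterwards, preserving detailed balance in the
  retained chain. Fixed seeds give bit-identical chains.

Priors default to $\beta_j \sim N(0, 10^5)$, $\tau^2, \sigma^2 \sim$
InverseGamma(1, 0.01) and $\rho \sim U(0,1)$ — the weakly informative
conventions of the disease-mapping ecosystem; all are overridable via
`car_prior()`. Default chain sizes are 20 000 burn-in and 100 000
post-burn-in sweeps thinned by 10; the test-suite and the acceptance
script use scaled-down chains (2000–3000 burn-in, 2000–3000 retained
draws), which we verified are long enough for the checks they support.

Model comparison uses DIC $= \bar D + p_D$ with
$p_D = \bar D - D(\text{posterior mean})$, the plug-in deviance evaluated
at the posterior mean linear predictor. Convergence is monitored by the
Geweke diagnostic (`geweke_z()`), comparing the first 10% and last 50%
of each scalar chain with spectral-density-at-zero variance estimates
from an AR fit; `summary()` reports Z per parameter and the maximum
absolute Z.

`smoothed_rr()` converts posterior fitted-count samples into smoothed
relative risks $\mu_k / E_k$ and flags areas whose risk exceeds unity
with posterior probability above 0.75.

## Standardization

Expected counts are indirectly standardized: overall prevalences in the
five adjustment strata (18–24, females 25–39, males 25–39, 40–54, 55+,
the last being the reference) are applied to each area's stratum
denominators, so $\sum_k E_k = \sum_k y_k$ exactly (to 1e-9 in the
suite). Regression models adjust for demographic composition through the
four non-reference stratum proportions, with $\log n_k$ as offset.
Composite ecological indices are sums of two Z-scores; all Z-scores in
the package use the population SD (divide by $n$), treating the areas as
the complete population of units — either convention is defensible, the
package applies one consistently and tests it.

## What the synthetic generator emulates — and what it does not

`synthetic_area_data()` generates a 7×8 rook lattice (56 areas, the
nearest rectangular grid to the 53-unit catchment that motivated the
package), lognormal populations moment-matched to mean 2064 and SD 705,
Dirichlet-multinomial stratum allocations centred on the catchment
age/gender mix, spatially smooth covariates (a Leroux Gaussian field,
column-standardized), and counts from the Poisson–Leroux model at a
baseline prevalence of 358/109397, defaults $\beta_{ECON} = 0.12$,
$\rho = 0.8$, $\tau^2 = 0.3$. Within-area cases are allocated to strata
proportionally to stratum population times the catchment's stratum
relative risks, so the standardization machinery sees realistic
demographic structure.

It does **not** emulate: real administrative geometry (grid cells stand
in for irregular polygons, so degree distributions differ), stratum-level
risk effects entering the spatial model itself, measurement error in
covariates, or case-finding incompleteness. Passing tests therefore
certify the statistical machinery under the stated generative model, not
robustness to those real-data features. We deliberately did not tune the
generator to reproduce the observed per-area case SD (4.29 in the
motivating catchment), because that second moment depends on covariate
effect sizes that are not identifiable from published aggregates.

## Design decisions where the design was open

* **$r^2$ definition**: squared Pearson correlation between observed and
  fitted values — the only variant guaranteed to lie in [0, 1] for
  non-least-squares fits; the $1 - SSE/SST$ variant is attached as an
  attribute.
* **Forward selection**: strict criterion improvement (any decrease in
  AIC or DIC), ties broken toward the smaller model.
* **Pipeline escalation**: the Bayesian sweep runs when Moran's I is
  significant at 0.05, or unconditionally with `force_bayesian = TRUE`
  — provided because residual autocorrelation close to the threshold is
  often judged worth modelling anyway.
* **Exceedance reporting** uses binary hotspot flags at the 0.75 cutoff;
  the full exceedance probabilities are always returned so other cutoffs
  cost nothing.

## Known limitations

Two operating characteristics of the method itself, measured by the
acceptance suite at the study scale ($n = 56$, ~7 cases per area), are
worth stating plainly:

1. **DIC cannot separate the spatial CAR variants.** On data generated
   from the Leroux model at $\rho = 0.8$, $\tau^2 = 0.3$, the three
   spatial structures (IAR, BYM, Leroux) differ by under 1.5 DIC points
   on average while IND trails by ~4; the specific Leroux variant attains
   the minimum DIC in only a minority of replicates. Spatial-vs-nonspatial
   is detectable; *which* spatial prior is not, at this scale. A
   single-dataset DIC ranking among CAR variants should be read
   accordingly.
2. **Isolated hotspots are shrunk.** With a flat background, the
   random-effect variance posterior collapses toward zero and a lone
   doubled-risk area with $E \approx 10$ is flagged at the 0.75
   exceedance cutoff in roughly two-thirds to (at best) ~85% of
   replicates, while truly flat areas are flagged in under 4%. This is
   the standard bias-variance trade-off of Gaussian hierarchical
   smoothing: specificity is excellent, sensitivity to a single isolated
   spike is not. Clustered excesses, which support each other spatially,
   are easier to detect.

Chain-length guidance: the coverage, equivalence and hotspot checks in
the test suite use 2000–3000 retained draws, which keeps the whole suite
under two minutes on one CPU; headline analyses should use the defaults
(10 000 retained draws), for which the Geweke |Z| < 1.96 rule is the
reported convergence criterion.
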