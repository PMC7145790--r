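---
title: "Staged spatial environment-wide association analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged spatial environment-wide association analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spenwas)
```

## The analysis problem

spenwas analyses area-level disease counts against a battery of
environmental and demographic exposures, in the setting typical of national
registry studies: a few hundred administrative areas, an observed case count
`O_i` per area, stratified population denominators, and tens of partially
intercorrelated exposure variables measured (or aggregated) at area level.
The package proceeds in three stages, each of which answers a different
question:

1. **EnWAS screen** — which exposures are associated at all, ignoring
   spatial structure? One univariable Poisson regression per exposure, with
   the indirectly standardised expected count as offset, under family-wise
   Bonferroni control.
2. **Disease mapping** — which associations survive once the spatial
   dependence between neighbouring areas is modelled, and where is residual
   risk elevated? A BYM2 convolution model fitted by MCMC, giving smoothed
   relative-risk surfaces, 95% credible intervals and exceedance
   probabilities.
3. **Ecological regression** — what does a joint model of the surviving,
   non-redundant exposures estimate? Covariates passing both previous gates
   are clustered by rank correlation, one representative per cluster enters
   a multivariable BYM2 fit.

## Standardisation

Expected counts use indirect standardisation with the pooled study region
as its own reference: stratum rates `r_s = sum_i cases_is / sum_i pop_is`,
and `E_i = sum_s pop_is * r_s`. With an internal reference the calibration
identity `sum(E) = sum(O)` holds exactly, which the tests assert to 1e-9
relative error. Crude incidence uses the exact Poisson (gamma-quantile)
interval: with `x` cases the 95% bounds are the 0.025 quantile of
`Gamma(x)` and the 0.975 quantile of `Gamma(x + 1)` divided by
person-years. The exact interval stays valid at the single-digit counts
individual areas can have and converges to the normal approximation at
large counts. Person-years are population times study-period length; the
period length is a parameter (`study_years`) because registries differ in
how they construct denominators.

## The screening model

Each exposure is fitted alone in
`O_i ~ Poisson(E_i * exp(a + b x_i))`, maximised by iteratively reweighted
least squares to a relative coefficient tolerance of 1e-10 (cap 100
iterations; non-convergence is an error carrying the last iterate, never a
silent result). P-values are two-sided Wald tests. Three conventions are
deliberate:

* **Wald rather than likelihood-ratio p-values** — the counts per area are
  large enough (tens) that the two agree closely, and Wald matches standard
  GLM reporting.
* **Native covariate units** — per-unit relative risks are what area-level
  policy covariates are reported in; a `standardise = TRUE` z-score option
  exists but is off by default.
* **Complete-case per variable** — areas missing one exposure are dropped
  for that exposure only, so one patchy variable does not shrink every
  other test.

The Manhattan quantity is `-log10(p) * sign(b)`; numerically zero p-values
are clamped at 1e-300 *for plotting only* (inference keeps the raw value).
QQ plots pair the sorted observed `-log10` p-values with uniform
order-statistic midpoints `(k - 0.5) / m`. The screen makes no correction
for over- or under-dispersion: its role is a deliberately simple first
gate, and the spatial model is the stage that accounts for the correlation
structure that distorts naive Poisson inference.

## The BYM2 spatial model

Stage 2 and stage 3 share one engine:

```
O_i ~ Poisson(E_i * exp(a + X_i beta + b_i))
b   = sigma * (sqrt(phi) * u + sqrt(1 - phi) * v)
u   ~ scaled ICAR on the adjacency graph,  v ~ N(0, I)
```

The ICAR precision is the graph Laplacian `Q = D - A`, improper with one
null vector per connected component, so `u` lives under a per-component
sum-to-zero constraint. Each component is *scaled*: the geometric mean of
the constrained generalised-inverse diagonal (the marginal variances) is
divided out, so the structured field has unit typical marginal variance on
any graph and `sigma` is interpretable as the marginal standard deviation
of the combined effect while `phi` in [0, 1] is the share of its
variability that is spatially structured. Zero-neighbour areas (islands)
carry a purely unstructured effect `sigma * v_i` and are excluded from
scaling; disconnected components are scaled and constrained separately.
The per-area relative risk is `RR_i = exp(b_i)`: residual risk relative to
the covariate-adjusted study-region expectation.

### Priors

The defaults are penalised-complexity-style and configurable via
`prior_config()`:

| parameter | prior | default rationale |
|---|---|---|
| `sigma` | Exponential with `Pr(sigma > 1) = 0.01` | shrinks towards "no random effect"; a marginal sd of 1 (RRs spanning e^±2) is an extreme for area-level disease rates |
| `phi` | Uniform(0, 1) | no prior preference between spatial structure and over-dispersion |
| intercept, `beta` | Normal(0, 10) | effectively flat on the scale of log RRs |

Either `sigma` or `phi` can be fixed, which is how the model is collapsed
onto simpler ones for validation (fixing `sigma` near 0 reproduces the
frequentist screen estimates; the test suite checks agreement within two
posterior standard deviations).

### Sampler

Inference is Metropolis-within-Gibbs with a compiled core: single-site
adaptive random-walk updates for `u_i` and `v_i`, scalar adaptive random
walks for the intercept, each coefficient, `log(sigma)` and `logit(phi)`,
and one non-obvious extra move — a likelihood-invariant rescaling
`(sigma, u, v) -> (c sigma, u / c, v / c)` accepted on the prior and
Jacobian alone — which breaks the posterior correlation between `sigma`
and the latent fields that otherwise makes the variance parameters mix
slowly. Proposal scales adapt towards 0.44 acceptance during warm-up
(Robbins-Monro, step `1/sqrt(t)`) and freeze afterwards, so retained draws
come from a fixed transition kernel. The structured field is recentred to
per-component mean zero after every sweep, the standard on-the-fly
handling of the ICAR constraint in single-site samplers; retained `u`
draws sum to zero within each component to below 1e-8. Covariates are
centred and scaled internally for sampling (draws are mapped back to
native units), which keeps the intercept and slopes close to orthogonal.

Chains run sequentially with seeds derived from the user seed, so a fit is
a pure function of `(data, graph, priors, chains, iter, seed)`.
Convergence is reported, never assumed: split-R-hat (computed in-package)
and bulk effective sample size (via coda's spectral estimator) for every
model parameter, with a `converged` flag requiring R-hat < 1.01 and
ESS > 400. Fits failing the gate still return their summaries together
with the diagnostics — a flagged result is more useful than an error, but
it is never silent.

Calibration of the whole machine is checked by simulation: 50 independent
synthetic regions of 200 areas (counts at realistic magnitude, true effect
0.5 per SD, `sigma = 0.3`, `phi = 0.7`, 2 chains of 2000 iterations) must
give 95% credible intervals covering the true effect in 45-50 replicates,
and with `phi = 0.9` the posterior mean of `phi` must land above 0.5 in at
least 18 of 20 replicates. Those problem sizes were chosen as the smallest
at which coverage statements at ±4 percentage points are meaningful.

### Exceedance classification

An area is `elevated` when at least 80% of its posterior RR draws exceed
1, `lowered` symmetrically, `uncertain` otherwise; both the RR reference
point and the probability cut-off are arguments. The classification is a
deterministic function of the posterior fractions, so its tests are exact,
and raising the cut-off can only move areas into `uncertain`.

## Covariate selection

A variable enters the final regression only if its screen p-value beats
the Bonferroni threshold *and* its disease-mapping 95% CrI excludes 1
("relevant CrI" is read as excluding 1; an interval hugging but crossing 1
fails the gate, however small the screen p — the fine-particulate pattern
in the motivating literature). Candidates are grouped into connected
components of the graph joining pairs with `|rho| >= rho_max` (Spearman,
midrank ties), default `rho_max = 0.7`: the cutoff is a judgement call and
the motivating analyses chose representatives partly by expert knowledge,
so `prefer =` accepts a manual override list, while the objective default
representative is the smallest screen p-value. Selection is deterministic
and order-independent; any two selected variables are correlated below the
threshold.

## The synthetic-region generator

The generator exists so that every stage — and their interaction — can be
tested against known ground truth. Its defaults are fixed study
conditions, not tuning knobs, and emulate the scale of a national
childhood-disease registry analysis:

* **354 areas** on a Gabriel graph of random points (planar, connected,
  irregular degrees like administrative adjacency); a rook lattice is
  available for cheap regular geometry.
* **4 strata** (two childhood age bands by sex) with log-normal area
  populations (`sdlog = 0.5`, mean 17,000 children per area) and
  mildly Dirichlet-perturbed stratum shares.
* **Stratum incidence rates** of 14 and 28 per 100,000 child-years
  (younger/older band, sex-equal), averaging ~21 per 100,000 per year over
  an 11-year study period — expected counts then span roughly 5-150 with a
  median near 35, matching the magnitude at which the method is meant to
  operate.
* **53 exposures** drawn as proper-CAR spatial fields (autocorrelation
  0.9) standardised to unit marginal variance and mixed through the
  Cholesky factor of a block correlation matrix (three blocks of four at
  rho 0.85, the rest near-independent) — the "correlated pollutant group"
  structure that makes selection non-trivial.
* **True effects** on one member of each correlated block plus one
  unblocked variable (log RRs ±0.15, ±0.10 per SD), a sparse-signal
  configuration; all other 49 variables are null.
* **Random effect** with `sigma = 0.3`, `phi = 0.7`: predominantly
  spatially structured residual risk of realistic magnitude (area RRs
  mostly within e^±0.6).
* Observed counts are allocated to strata multinomially (probability
  proportional to stratum person-time at the reference rates) so indirect
  standardisation can be exercised, and split binomially into two equal
  sub-periods for the temporal-consistency check.

Under these conditions the frequentist screen typically flags ~25-30 of
the 53 variables — the spatially structured residual inflates naive
Poisson significance, exactly the pathology the staged design exists to
correct — and the mapping gate then prunes the set to the true carriers
plus their correlated proxies. What the generator does *not* emulate:
real administrative geography, registry artefacts (duplicate records,
missing identifiers), exposure measurement error correlated with
population density, or missing-by-design exposures; passing tests
therefore demonstrate statistical correctness of the machinery, not
robustness to those data pathologies.

## Numerical and interface choices

* Decile coding uses minimum-rank ties (`ceiling(rank * 10 / n)`):
  deterministic, order-independent, all-equal input collapses to decile 1.
* Population-weighted aggregation reports zero-weight areas as missing
  with a warning; missingness then propagates per-variable into the
  screen.
* GAL adjacency files use the plain dialect (count header; `id n` line
  then a neighbour-id line); asymmetric files are rejected naming the
  offending pair.
* `run_pipeline()` writes every stage output in formats the package's own
  readers parse back (CSV, GAL, JSON, optional GeoJSON), a manifest with
  seed and input hashes, and wall times in a separate log so that all
  analytical outputs are byte-identical across same-seed runs.
* The disease-mapping stage fits per-variable Bayesian models only for
  screen-significant variables by default (`map_all = TRUE` fits all):
  variables failing the screen cannot enter selection, so the extra fits
  change nothing downstream.
* The pipeline's default MCMC budget (2 chains of 2000) is sized for the
  ~35 model fits a full 53-variable run needs; single substantive fits
  deserve the `fit_bym2()` defaults (4 chains of 5000).

## Known limitations

* The sampler is a random-walk scheme: adequate and well-calibrated at
  hundreds of areas, but not competitive with integrated nested Laplace
  approximations or gradient-based MCMC at much larger problems.
* Equivalence with any particular INLA parameterisation is not claimed;
  priors differ across implementations and credible intervals will differ
  accordingly.
* Ecological inference caveats apply in full: area-level associations
  carry no individual-level causal interpretation, and the package
  deliberately stops at estimation and mapping.
* The screen's QQ plot frequently shows systematic departure from the
  null diagonal (spatial correlation masquerading as signal or its
  absence); this is displayed, not corrected — the correction *is* stage
  2.
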