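---
title: "Methods: small-area spatio-temporal modelling of DDD-standardised prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area spatio-temporal modelling of DDD-standardised prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmap)
```

# The problem

NHS prescribing extracts report, for every GP practice and month, the
quantity of each medicine dispensed. Comparing prescribing of the four
direct (non-vitamin-K) oral anticoagulants — apixaban, dabigatran
etexilate, edoxaban and rivaroxaban — across areas and years requires two
standardisations and one model:

1. **Dose standardisation.** Different products come in different unit
   strengths. The WHO defined daily dose (DDD) converts a quantity `q` of
   units at strength `s` mg into a unit-free count of assumed maintenance
   days, `q * s / DDD`. For example, 100 units at 30 mg plus 200 units at
   60 mg of a drug with DDD 60 mg is `(100*30 + 200*60)/60 = 250` DDDs.
2. **Population standardisation.** Dividing total DDDs by the area
   population and multiplying by 1,000 gives the DDD-per-1,000-population
   rate, the primary outcome.
3. **Small-area smoothing.** Area-year rates from small populations are
   noisy; a Bayesian hierarchical model borrows strength from neighbouring
   areas and from the overall temporal trend.

# The model

For area $i$ and year $j$ let $y_{ij}$ be the (integer) DDD count,
$E_{ij}$ the exposure and $\theta_{ij}$ the relative rate:

$$y_{ij}\mid\theta_{ij} \sim \mathrm{Poisson}(E_{ij}\,\theta_{ij}), \qquad
\log \theta_{ij} = \mu_{ij} = \beta_0 + \beta^\top x_{ij} + \kappa_i\,\sigma
  + \beta_3\,\mathrm{time}_{ij}.$$

We define $E_{ij}$ as the mid-year population divided by 1,000, which makes
$\theta_{ij}$ exactly the DDD-per-1,000 rate; `time` is the calendar year
minus 2019, the reference year, so $\beta_0$ is the overall log rate in
2019 and $\beta_3$ a linear yearly trend on the log scale.

The area effect is the BYM2 mixture

$$\kappa_i = \eta_i\,\sqrt{\rho/s} + \nu_i\,\sqrt{1-\rho},$$

where $\eta$ follows Besag's intrinsic conditional autoregressive (ICAR)
prior on the area adjacency graph, $\nu_i \sim N(0,1)$ independently,
$\sigma > 0$ is the single standard deviation of the combined effect and
$\rho \in [0,1]$ the fraction of its variance that is spatially
structured. The scaling factor $s$ is the geometric mean of the diagonal
of the generalised inverse of the ICAR precision restricted to the
sum-to-zero subspace of a connected component, computed per component;
dividing by $\sqrt{s}$ gives the structured term unit typical marginal
variance, which is what makes $\rho$ interpretable and priors on
$\sigma$ transferable across maps.

**Islands.** A component of size one has no ICAR distribution. Its
$\eta_i$ is fixed at zero and the area contributes through
$\nu_i\sqrt{1-\rho}$ only. This is the conventional treatment; the
alternative (giving islands the full mixture weight) changes little in
practice but would break the variance-partition reading of $\rho$.

**Sum-to-zero.** The ICAR density is improper (constant shifts within a
component are free); identifiability against $\beta_0$ requires the
component sums of $\eta$ to vanish. We use a soft constraint — the sum of
each component's $\eta$ receives a $N(0,\ 0.001\,m)$ density, $m$ the
component size — because a soft constraint keeps the posterior smooth for
gradient-based sampling. The residual slack it leaves (component mean of
order $10^{-5}$) is far below posterior noise.

## Priors

The prior families are design choices; the defaults are weakly informative and standard for disease mapping:
$\beta_0,\beta,\beta_3 \sim N(0,5)$ on the log-rate scale (a ±10 range on
the log scale is far wider than any plausible prescribing rate),
$\sigma \sim$ half-$N(0,1)$ (area effects of more than e-fold ±2.7 are
implausible), and $\rho \sim \mathrm{Beta}(1,1)$, i.e. uniform. All three
are overridable through `prior_spec()`; setting `rho_shape = c(0.5, 0.5)`
gives a U-shaped prior in the penalised-complexity spirit that favours the
pure-spatial and pure-heterogeneity corners.

# Inference

There is no probabilistic-programming dependency: the sampler is part of
the package. It is Hamiltonian Monte Carlo with analytic gradients of the
exact joint density, run on the unconstrained scale
($\log\sigma$, $\mathrm{logit}\,\rho$), with

* **dual-averaging step-size adaptation** towards a target acceptance rate
  of 0.9,
* a **diagonal metric seeded from the local curvature** (central
  differences of the analytic gradient), refreshed after the first half of
  warmup. A marginal-variance metric — the common default — is the wrong
  preconditioner here: each area's $(\eta_i,\nu_i)$ pair is individually
  wide but jointly stiff, because only the mixture $\kappa_i$ is
  identified by the data. The curvature bounds the stable step size; the
  wide, weakly identified directions are handled by long trajectories
  (default nominal path length 32 in metric-scaled units, jittered, capped
  at 512 leapfrog steps),
* **interweaved scale moves**: after every trajectory, 50 sweeps of two
  Metropolis moves that propose $\mathrm{logit}\,\rho$ (resp.
  $\log\sigma$) and *deterministically rescale* $\eta,\nu$ so the linear
  predictor is unchanged. The Poisson likelihood cancels exactly, so these
  moves walk the long ridge connecting different $(\sigma,\rho)$ values at
  prior-plus-Jacobian cost. Without them the mixing time of $\rho$
  dominates everything; with them a 100-area, 6-year fit reaches
  usable effective sample sizes in seconds. Proposal scales adapt to a
  0.44 acceptance rate during warmup.
* An optional dense Gauss–Newton metric (`control = list(dense_metric =
  TRUE)`) assembles the likelihood curvature over all coordinates plus the
  ICAR and prior precisions. In our experiments it did not beat the
  diagonal-plus-interweaving combination on this model and stays off by
  default.

Divergences (energy errors above 1000) are counted and reported. Every fit
computes split-chain **rank-normalised R-hat** and autocorrelation-based
**effective sample size** (Geyer initial monotone sequence) for every
parameter, plus `se_mean = sd/sqrt(ESS)`; a fit whose model-level
parameters exceed R-hat 1.01 or fall below ESS 400 carries warnings — it
is returned, never silently discarded. At the reduced settings used in the
tests (2 chains × 500 draws), $\rho$ typically sits around ESS 50–150;
the reported intervals are still calibrated, as the recovery and coverage
checks below verify, but for production use 4 chains × 1000 draws is the
default.

All randomness flows through R's RNG — the compiled core draws from the
same stream — so a seed plus a configuration reproduces a fit bit for bit.

# Synthetic data

The generator exists so that every pipeline stage is testable with known
ground truth, end to end, with no downloads. It emulates:

* **adjacency** — a rook-contiguity grid or a Gabriel graph of uniform
  random points (planar, connected, contiguity-like degree distribution);
  islands and disconnected maps are representable through the edge-list
  reader;
* **truth** — $\eta$ sampled exactly from the ICAR distribution
  (eigendecomposition of each component's precision, zero-sum by
  construction), $\nu$ standard normal, fixed effects from configuration;
* **counts** — Poisson draws from the exact model above;
* **prescribing rows** — each area-year DDD total disaggregated to
  practice × month × strength cells with uniform random weights, converted
  to integer unit quantities by largest-remainder apportionment. A final
  smallest-strength unit is added only when the shortfall would exceed
  half a DDD, which keeps the per-area-year error strictly under DDD/2, so
  re-aggregation (which rounds half-up) recovers every count **exactly** —
  the round-trip is lossless by construction, and the test suite asserts
  it for all four registry drugs;
* **demography** — a quarterly series, constant within each year, so the
  interpolated July value equals the annual population; and per-area
  deprivation scores and rural–urban classes.

Default study conditions used by the calibration experiments: 100 areas ×
6 years (2014–2019), population 50,000 per area (exposure 50),
$\beta_0 = \log 5$, $\beta_3 = 0.05$, $\sigma = 0.5$, $\rho = 0.7$ —
a mid-sized national map with a visible trend and substantial, mostly
spatial, area variation. The practice count per area (3) and the uniform
strength mix are conventions, not calibrated quantities: the public data
do not constrain them, and nothing downstream depends on them beyond the
conservation property.

What the generator does **not** emulate: 15-character product-level codes,
dummy practices, cost columns, practice-size heterogeneity, within-year
seasonality, and boundary changes between years. Passing tests therefore
demonstrate correctness of the pipeline's arithmetic and the model's
calibration under its own assumptions — not robustness to the messiness of
the real feed.

# Validation design

`validate_holdout()` implements a two-stage sensitivity check: mask 10%
of area-year records (simple random, `floor(0.1 N)` held out — a
percentage implies no rounding rule, and floor is the conservative
reading),
refit on the rest with the masked records' `Y` treated as missing (their
exposure, covariates and time remain, so their areas still borrow
strength), then score

* **RMSE** between posterior-median predicted rates and observed held-out
  rates, on the DDD-per-1,000 scale (the analysis's primary variable);
  the count-scale RMSE is reported alongside;
* **95% interval coverage** of the held-out counts, with intervals taken
  from the 2.5th/97.5th percentiles of simulated
  $\mathrm{Poisson}(E\,\theta^{(d)})$ replicates per posterior draw — a
  genuine posterior-predictive interval including sampling noise. We read
  "uncertainty interval of the withheld data" as predictive because a
  withheld *observation* carries Poisson noise; a $\theta$-only interval
  mode exists behind `interval_type = "theta"` for sensitivity analysis.

Masking is not stratified by year or area; with 10% of 600+ records the
chance of unbalance that matters is negligible, so simple random masking
is the documented default.

At the simulation conditions above, 10 replicates of
simulate → mask → refit at 2 chains × 500 draws give mean held-out
coverage within a couple of points of the nominal 95%, and 20 replicate
fits recover each of $\beta_0, \beta_3, \sigma, \rho$ inside the 95%
credible interval in at least 18 of 20 — both checks run in the test
suite at exactly these sizes (roughly four minutes of CPU).

# Numerical choices

* Real-valued DDD totals are rounded **half-up** to integers before
  modelling: the Poisson likelihood needs integer counts, and at realistic
  exposures the half-unit perturbation is negligible.
* Covariates are z-standardised across areas (sample standard deviation);
  the rural–urban class enters as one-hot indicators with the
  alphabetically first level as reference, also standardised.
  Zero-variance columns are dropped with a warning.
* Mid-year (July) population, linearly interpolated from the sparse
  demography series with flat extension at the edges, defines the annual
  exposure; requesting years outside the series' span is an error rather
  than an extrapolation.
* The ICAR precision is held sparse; per-component dense
  eigendecompositions compute the scaling factors. The pseudo-inverse is
  taken by inverting all eigenvalues except the single structural zero of
  each connected component.
* Degenerate inputs: graphs need ≥ 2 areas; `sigma ≤ 0`, `rho` outside
  `[0,1]`, non-positive populations, unmapped practices and demography
  gaps are all hard errors naming the offending values.

# Limitations

* The temporal term is a single linear slope in year, exactly as the model
  is written; random walks, splines or space–time interactions are out of
  scope.
* One exposure per area-year (mid-year population). Indirect age–sex
  standardisation is a documented hook (the demography files carry
  age/sex summaries) but not applied by default.
* Inference quality at very small exposures (counts near zero everywhere)
  has not been tuned; the interweaving moves rely on the field being
  likelihood-identified.
* The CLI and pipeline assume the current-vintage area mapping; area
  mergers and boundary changes across years must be resolved upstream.
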