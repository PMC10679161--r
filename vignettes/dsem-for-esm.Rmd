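---
title: "Two-level Bayesian VAR(1) for experience-sampling data: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level Bayesian VAR(1) for experience-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Experience-sampling (ESM) studies prompt participants several times a day
for about a week, yielding short, unequally spaced multivariate time series
per person. The scientific questions are about *within-person dynamics* —
how much a momentary state carries over to the next hour (inertia,
autoregression) and how much one state spills over into another
(cross-lagged effects) — and about *between-person structure*: who shows
stronger dynamics, and whether that strength correlates with stable traits
such as negative self/other schemas.

dsemr implements a dynamic structural equation model for this design: a
two-level lag-1 vector autoregression with latent person-mean centering.
For person $i$ and hourly grid cell $t$:

$$
y_{it} = \mu_i + w_{it}, \qquad
w_{it} = \Phi_i\, w_{i,t-1} + \gamma\, h_{it} + \varepsilon_{it}, \qquad
\varepsilon_{it} \sim N(0, \Sigma_w),
$$

where $y_{it}$ is the $K$-vector of momentary composites (e.g. social
anxiety, paranoia, loneliness on a 1–7 scale), $\mu_i$ the latent person
means, $\Phi_i$ the person-specific $K \times K$ lag matrix (diagonal:
autoregression; off-diagonal: cross-lagged spill-over), $h_{it}$ the clock
hour of the cell centered at its grand mean (a linear diurnal-trend
control), and $\Sigma_w$ the innovation covariance, common across persons.
Decomposing each observation into a *latent* person mean plus a deviation
avoids the bias that observed-mean centering induces in short series.

At the between level all random effects — the $K$ means and all $K^2$ lag
coefficients (6 in the bivariate model, 12 in the trivariate one) — are
jointly multivariate normal with free covariance $\Omega$. Baseline schema
scores, grand-mean centered over the analyzed sample, enter this joint
normal as observed components, so $\Omega$'s covariate blocks directly give
the correlation between every random effect and each schema
(`between_correlations()`). A binary covariate such as gender instead
enters the mean structure of the random effects
(`gender_moderation()`), mirroring the two distinct roles covariates play
in these models.

Lag effects are defined *per hour*: unequally spaced prompts are first
assigned to a one-hour grid (`build_time_grid()`, a discrete time filter),
and cells with no prompt — including entire nights — are treated as missing
at random and handled inside the sampler. Overnight carry-over therefore
attenuates through a run of missing steps rather than wrapping a 10-hour
lag into a 1-hour coefficient.

## Grid construction details

Cells are aligned to the absolute clock lattice (multiples of the interval
counted from midnight of day 1) and indices are shifted so each person's
first completed observation is cell 0. Aligning to the clock lattice
rather than to the raw first timestamp keeps the *differences* between
cell assignments consistent across persons and days, which is what the
lag-1 estimand depends on. When two prompts fall into the same cell, the
earlier keeps it and the later is shifted to the next cell if that cell is
empty, otherwise dropped; every collision is logged
(`attr(grid, "collisions")`), and `collision = "drop"` discards instead of
shifting. With hourly simulated timestamps gridding is lossless.

The hour covariate is the linear clock hour of the cell's nominal time,
centered at the grand mean over occupied cells. Linear was chosen for
parsimony; a polynomial or categorical coding could be substituted by
adding columns, but the fitted trend is a single slope per variable.

# Estimation

`dsem_fit()` runs a blocked Gibbs sampler written in C++ (RcppArmadillo).
Priors are diffuse by default: $N(0, 10^6)$ on fixed effects and the hour
slope, inverse-Wishart(identity, $K+1$) on $\Sigma_w$, and
inverse-Wishart(identity, $d+1$) on $\Omega$ of dimension $d$. The default
chain plan is 4 chains of 5000 iterations with thinning 10; the first half
of each chain is discarded as burn-in (the smoke profile for quick runs is
2 × 500, thinning 5). All draws are deterministic given the seed.

Most updates are standard conjugate blocks (fixed effects, $\Omega$,
$\Sigma_w$, $\gamma$, and the missing cells by forward-filter
backward-sampling over each missing run). The person-level updates are the
part worth documenting, because naive data augmentation fails on this
design. A night is 11+ consecutive missing cells; imputing them and then
updating $\Phi_i$ from the completed series means most of the "data"
informing $\Phi_i$ was generated under the current $\Phi_i$. For persons
with few observations the resulting chain is close to a random walk, can
drift into wildly non-normal lag matrices whose imputed bridges then
confirm them, and in the worst case diverges numerically. dsemr therefore
*collapses the missing cells out of the person-level updates*: consecutive
observed cells $t$ and $t+L$ satisfy

$$
y_{t+L} = \mu_i + \Phi_i^L (y_t - \mu_i) + \textstyle\sum_{j<L} \Phi_i^j
\gamma h_{t+L-j} + e_L, \qquad
e_L \sim N\!\Big(0, \sum_{j<L} \Phi_i^j \Sigma_w {\Phi_i^j}'\Big),
$$

which is linear in $\mu_i$ (an exact conjugate update) and yields the
marginal likelihood for a Metropolis step on $\Phi_i$, with the conjugate
conditional built from the observed lag-1 pairs as the proposal. Typical
acceptance rates are 20–70% depending on compliance. Missing cells are
then redrawn by FFBS under the updated person parameters, and the global
blocks use the completed data as usual. This partially collapsed scheme
leaves the posterior unchanged while removing the self-confirming
imputation pathology.

Two guard rails bound the state space without affecting results in
realistic regimes. Person-level lag draws are truncated to spectral radius
< 0.98 (a near-unit eigenvalue would leave the person's mean unidentified,
since $(I-\Phi_i)\mu_i$ vanishes along the unit eigenvector) and to
coefficient magnitudes < 1.5; the synthetic-data generator truncates the
person distribution to the stationary region in the same spirit. Imputed
draws are bounded at the person's observed range ± 6 within-person SDs —
far outside where bridges land under stationary dynamics, but a hard stop
for numerically explosive excursions.

Remaining numerical choices: covariance solves go through symmetrized
Cholesky factorizations with a jittered retry; inverse-Wishart draws use
the Bartlett decomposition; the first observation of each person
conditions the likelihood (no stationary-initial-condition term); and a
person's series is trimmed to start and end at observed cells.

# Reported quantities

`standardize_within()` reproduces the convention of reporting
within-person standardized fixed effects. Per draw and person, the
stationary covariance $V_i$ solves the discrete Lyapunov equation
$V = \Phi_i V \Phi_i' + \Sigma_w$ (vectorized Kronecker form;
`stationary_cov()`), and each lag coefficient is multiplied by the ratio
of predictor to outcome stationary SDs. Standardized values are averaged
over persons within a draw and summarized across draws by the posterior
median and the equal-tailed 95% credible interval; a coefficient is
flagged when the interval excludes zero. Non-stationary person draws are
excluded from that draw's average and counted. Person means are reported
on the raw 1–7 scale, where they are directly interpretable (standardizing
a mean has no substantive meaning here). The hour-trend contribution is
excluded from $V_i$ for standardization but included in the explained
share of the within-person $R^2$,
$R^2_k = 1 - \Sigma_w[k,k] / (V_i[k,k] + \gamma_k^2\,\mathrm{var}(h))$
(`within_r2()`); the univariate sanity anchors are
$\mathrm{var} = \sigma^2/(1-\phi^2)$ and $R^2 = \phi^2$.

Point estimates are posterior medians. The standardization scheme is the
per-draw-per-person one (standardize, then average), not
average-variances-then-standardize; the two differ at third order but the
former matches how person-varying dynamics are usually summarized.

`convergence()` reports the split-chain potential scale reduction factor
(floored at 1) and a Geyer initial-positive-sequence effective sample
size per scalar parameter, with a 1.1 flag threshold. The full-length
chain plan is deliberately long because random-effect covariance
parameters in these models mix slowly.

# The synthetic study generator

Because momentary data of this kind are rarely deposited, every stage is
exercised against `simulate_esm_study()`, whose defaults emulate the
motivating study design: 134 persons, 10 prompts/day for 6 days inside a
13-hour waking window starting at 09:00, pseudo-randomized one-per-block
with a 15-minute minimum gap, and per-person completion probabilities
drawn from a Beta distribution moment-matched to mean 0.721 and SD 0.16,
thinning prompts independently of the momentary values (missing at
random by construction). Ground-truth population dynamics and mean levels
follow the reported trivariate momentary model of social anxiety,
paranoia and loneliness (inertia 0.31–0.61, positive cross-lags, means
near 2), with schema correlations concentrated on the mean levels and a
few cross-lagged couplings; the bivariate subset uses the corresponding
bivariate estimates.

Choices the generator makes where no published value exists:

* **Random-effect spread.** Person means vary with the reported variances
  (0.72–0.95); lag coefficients vary with SD 0.10. Reported
  random-effect variances for lag coefficients are not usable as
  generator values — an SD near 0.7 on lag coefficients makes almost
  every simulated person non-stationary — so 0.10 was fixed as a
  realistic person-to-person spread compatible with stationarity.
* **Innovation covariance.** Unit variances with contemporaneous
  correlation 0.3. $R^2$ depends only on $\Phi$ and the correlation
  structure, not the scale.
* **Compliance distribution.** Beta, moment-matched; only the mean, SD
  and range are reported, and a Beta is the natural bounded choice.
* **Composites.** Emitted as continuous values by default, matching the
  estimation model's treatment of the data as continuous; momentary
  composites are means of 3–5 Likert items, so the continuous
  approximation is close. `likert_emulation = TRUE` rounds to the
  item-mean lattice and clips to [1, 7], and `emit_items = TRUE`
  generates integer item responses whose mean is the composite, for
  robustness checks of the continuous treatment.
* **Latent time scale.** The latent process is simulated on the same
  one-hour clock lattice the analysis grids to, so the generator's lag
  parameters are exactly the analysis estimand. Real momentary dynamics
  evolve in continuous time; passing tests therefore validate the
  pipeline against its own hourly estimand, not the continuous-time
  fidelity of a one-hour discretization.
* **Gender** has no effect by default (matching a null finding); a
  configurable additive shift on chosen lag coefficients supports
  moderation power studies.

What the generator does **not** emulate: response latency inside the
15-minute expiry window (timestamps equal prompt times), ordinal
measurement (no graded-response model), non-MAR missingness (e.g.
state-dependent non-response), and baseline questionnaires beyond the two
schema scores and gender.

# Problem sizes used in the test suite

The suite favours exact oracles (closed forms, brute-force Gaussian
conditionals, least squares, fixed-point Lyapunov iteration) on small
fixtures, plus one full-scale recovery study: 20 replicates at the study
design (134 persons, 60 scheduled prompts, ~72% compliance) fitted with
the smoke sampler, checking mean absolute fixed-effect bias below 0.05,
95% interval coverage in [85%, 100%], and recovery of the positive
inertia signs. Monte-Carlo checks of the generator use 20,000 persons or
50,000 transitions, sizes at which the checked tolerances are several
standard errors wide.

# Known limitations

* $\Sigma_w$ is common across persons; person-specific residual variances
  are not implemented. With strongly heteroscedastic persons the common
  residual acts as an average and person $R^2$ inherits that.
* Lag order is fixed at 1, and there is no model comparison machinery.
* The hour trend is linear; strong nonlinear diurnal cycles would leak
  into the autoregression.
* The collapsed Metropolis update can have low acceptance for persons
  with very few observed lag-1 pairs; their person-level estimates then
  lean on the between-person prior, which is the intended behaviour but
  worth remembering when interpreting individual trajectories.
* The truncation of person dynamics (radius < 0.98, |coefficient| < 1.5)
  is a modelling statement, not just numerics: persons with genuinely
  explosive short-run dynamics are outside the model family, as they are
  for the generator.
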