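---
title: "Prey abundance and raptor occupancy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prey abundance and raptor occupancy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyrprey)
```

`gyrprey` implements a two-stage inference chain for Arctic tundra
food-web surveys: (1) estimate herbivore abundance from single-visit
point counts partitioned into removal intervals, (2) project the fitted
models onto a landscape lattice, aggregate prey density within raptor
territories, and ask whether territory occupancy tracks those densities.
This vignette explains the models, the assumptions behind them, the
tunable parameters, and the choices made where the design was genuinely
open.

## The time-removal abundance model

Each site $i$ is surveyed once for 10 minutes, split into $J = 5$
intervals of 2 minutes. An individual is recorded only in the interval of
its first detection, which makes the interval cell probabilities
geometric in the per-interval detection probability $p_i$:

$$\pi_{ij} = p_i (1 - p_i)^{j-1}, \qquad
  \Pr(\text{never detected}) = (1 - p_i)^J .$$

Latent site abundance is Poisson,
$N_i \sim \text{Poisson}(\lambda_i)$ with
$\log \lambda_i = \beta^\top x_i + \log A$, where $A$ is the area sampled
by one count. The area constant defaults to $0.5024\ \text{km}^2$, the
published value for a 400-m radius ($\pi r^2$ is 0.5027; the printed
constant is honoured and configurable). With Poisson mixing the latent
sum collapses: interval counts are independent Poisson with means
$\lambda_i \pi_{ij}$ (the multinomial–Poisson factorization). That
closed form is the production likelihood; the explicit truncated
latent-$N$ sum is retained in `loglik_nmix_truncated()` purely as an
independent oracle, and the test suite asserts the two agree to
$10^{-8}$ at $K = 300$ — the factorization theorem as a regression test.

Detection probability is constant across the five intervals within a
survey: detection covariates (ordinal date, minutes after civil
twilight, wind speed, observer identity) are site-level, so there is no
interval-varying $p$. Observer enters as a reference-coded factor, first
level alphabetically; year is deliberately not an abundance covariate
(sample sizes per year are small and spatial differences are assumed
habitat-driven and constant).

Estimation is quasi-Newton (BFGS with the analytic gradient) from a
moment-based null start plus random restarts, followed by Newton
polishing until the gradient norm is below $10^{-6}$. Convergence
requires a positive-definite numeric Hessian; the covariance is its
inverse, and Wald 95% intervals that exclude zero define "significant"
predictors, matching the convention of the field. All-zero data push the
intercept to the $\lambda \to 0$ boundary; the fit is returned but
flagged, never silently.

### Goodness of fit

`gof_parametric_bootstrap()` compares the Pearson statistic
$\chi^2 = \sum_{ij} (y_{ij} - \hat e_{ij})^2 / \hat e_{ij}$, with
$\hat e_{ij} = \hat\lambda_i \hat\pi_{ij}$, against replicates simulated
from the fitted model and refitted. Refits start from the original
optimum — a cost-control choice that is recorded in the result and is
innocuous here because the refit likelihood differs from the original
only through resampling noise. The p-value counts replicates at least as
large as the observed statistic (ties favour the null), and
$\hat c = \chi^2_{\text{obs}} / \overline{\chi^2_{\text{boot}}}$
measures dispersion: values above 1 mean more variance than the Poisson
model expects, values below 1 under-dispersion (fewer empty sites than
predicted). Cells with near-zero expectation are excluded from the
statistic (default threshold $10^{-10}$; the policy is recorded).

## Covariate preparation

Landscape covariates (percent covers of tundra, tussock, tall shrub,
low shrub, sparse vegetation, and mean elevation) are standardized by
subtracting the mean and dividing by **two** standard deviations, which
puts continuous effects on a scale comparable to binary predictors. The
sample standard deviation ($n-1$ denominator) is used; the convention's
source does not pin down the denominator and the difference is
$O(1/n)$. Pairs with $|r| \ge 0.70$ are flagged by
`screen_collinearity()`; sites above 500 m elevation are dropped, with
the boundary site at exactly 500 m retained (the removal rule is
"greater than 500"). A scaler fitted on training data is stored in the
model object and re-applied verbatim to prediction layers — prediction
grids are never re-standardized with their own statistics.

## Density mapping and territory aggregation

`build_prediction_grid()` masks lattice cells above 500 m and cells
whose raw covariate values fall outside the training range (no
extrapolation), then standardizes with the training scaler. Cell
predictions are $\exp(\hat\beta^\top x + \log 0.64)$ — expected animals
per 0.64-km² cell — with intervals from multivariate-normal draws of the
coefficient vector (default 10,000; the delta method is available and
the two agree on the log scale within Monte-Carlo error). The study-area
total sums cell expectations, with its interval formed by summing each
coefficient draw's surface; this propagates the log-link asymmetry that
a symmetric delta interval would miss.

Territory prey density follows the corrected-area rule: member cells are
the valid cells whose centres fall within the aggregation radius of the
territory centre; the density is the summed expected per-cell count
divided by the summed area of those member cells (summing literal
densities and dividing by area would be dimensionally inconsistent).
The aggregation radius is a required argument with no silent default —
the territory extent appropriate for prey aggregation is a study
decision, not a package constant. The pipeline uses 4 km, a compromise
between a raptor's core foraging range and the 800-m lattice
resolution. Geometry is planar throughout; inputs are assumed projected.

## The stacked occupancy model

Territory-years are stacked as independent occupancy units rather than
linked by colonization/extinction dynamics: the series is short (six
seasons) and the prey-density covariates are time-constant, so a dynamic
model would have nothing to estimate its transition parameters from.
Occupancy of territory $i$ in year $t$ is

$$z_{it} \sim \text{Bernoulli}(\psi_{it}), \qquad
  \text{logit}\,\psi_{it} = \gamma^\top d_i + u_t,\quad
  u_t \sim N(0, \sigma_y^2),$$

with $d_i$ the standardized prey densities, and detection on survey $j$

$$y_{ijt} \mid z_{it} \sim \text{Bernoulli}(z_{it}\, p_{ijt}), \qquad
  \text{logit}\, p_{ijt} = \delta_0 + \delta_1\,\text{day}_{ijt} + v_i,
  \quad v_i \sim N(0, \sigma_v^2).$$

Missing surveys contribute nothing to the likelihood (an all-missing
survey column leaves it unchanged at every parameter value — a tested
contract), and territory-years with no completed survey are dropped with
a message.

### Integrating the crossed random effects

The year effect crosses the territory effect — every unit couples one
$u_t$ with one $v_i$ — so the integral does not factorize and
per-group quadrature is impossible. The marginal likelihood is computed
by a joint Laplace approximation: Newton optimization of the penalized
joint log-likelihood in $(u, v)$, with the $(T + M)$-dimensional Hessian
solved through its year-block Schur complement (a $T \times T$ system;
$T = 6$), and the log-determinant obtained from the same factorization.
Each evaluation is $O(\text{records})$; the per-unit likelihood and
derivative sweep is compiled C++ with a pure-R reference implementation
kept in the package and asserted equal in the tests.

Two exactness properties anchor the approximation. When a variance is
exactly zero the random effect is switched off rather than taken to a
limit, so the $\sigma = 0$ marginal equals the closed-form fixed-effect
likelihood to machine precision. When only one factor is active the
integral does factorize, and the package switches to adaptive
Gauss–Hermite quadrature (21 nodes, centred and scaled at the penalized
mode); the tests pin this against an independent 61-node quadrature
oracle at $10^{-4}$. Only the genuinely crossed case relies on the
Laplace approximation itself.

### Variance estimation and the boundary

The two standard deviations are estimated on the log scale with a lower
bound ($10^{-3}$ by default); a standard deviation at or below the
activation threshold $2 \times 10^{-3}$ is treated as exactly zero
inside the likelihood, so the optimizer sees the constrained model the
moment it reaches the shelf. Truth-at-zero variances create a flat
likelihood ridge in $\log\sigma$, where an optimizer can stop anywhere
on that shelf; instead of trusting the stopping point, the fit applies
two collapse rules: a standard deviation is reported as exactly 0 (with
a boundary flag) when its estimate falls below 0.01 — a variance that
prints as 0.00 at any sensible precision — or when removing the random
effect costs less than $10^{-4}$ log-likelihood units. After a
collapse, the remaining parameters are refitted with the collapsed
variance held at zero, so the reported estimates are the constrained
maximum-likelihood solution computed on the exact (quadrature or
fixed-effect) path throughout. Wald covariance for the fixed effects
comes from the numeric Hessian with boundary variances held at zero
(the log-scale parameterization has no interior curvature to report
there).
A near-singular fixed-effect information matrix — e.g. one survey per
unit and no covariates, where $\psi$ and $p$ enter only through their
product — triggers an explicit flat-ridge warning.

Mean occupancy and detection probabilities are averages of the fitted
unit-level $\psi_{it}$ and $p_{ijt}$ with random effects at their
conditional modes; the method is recorded in the result. The
MacKenzie–Bailey GOF tallies distinct detection histories within
cohorts defined by missingness pattern, pools cells with expected count
below 2 (configurable), and calibrates the Pearson statistic by
parametric bootstrap with fresh random effects drawn from the estimated
variances.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the survey design: 983 point-count
sites on an 800-m lattice, five 2-minute intervals within a 400-m
radius, 97 territories over six seasons with two surveys each and
60/1164 surveys missing. Default random-effect SDs follow the reported
pattern for the system — no year variance on occupancy, territory
detection variance 7.46 (SD $\approx 2.73$), reflecting how strongly
nest-cliff visibility differs among territories. Vegetation covers are a
per-cell Dirichlet allocation (the field data's land-cover product has
no published generative model; a compositional draw is the simplest
mechanism that gives covers summing to 100), and elevation is smoothed
Gaussian noise rescaled to 0–800 m so that the 500-m masking rule has
teeth. Missing surveys are assigned uniformly at random, although the
field cause was weather and therefore likely clustered in time.

The generator treats every detection as an independent individual.
Flocks, squirrel colonies, double counting, observer movement and
roadside bias are not simulated — so passing tests demonstrate that the
estimators recover the parameters of their own assumed data-generating
process, not that those assumptions hold for any particular field
dataset. Group-size clustering in real counts would inflate $\hat c$,
which is exactly what the GOF machinery is there to flag.

## Numerical choices and problem sizes

Tolerances: removal-model convergence at gradient norm $10^{-6}$
(Newton-polished), inner Laplace Newton at $10^{-9}$, outer optimization
at relative tolerance $10^{-10}$. Ties in bootstrap p-values count
toward the null. Degenerate inputs fail loudly: constant covariates in
standardization, counts below zero, detection histories outside
$\{0, 1, \text{NA}\}$, territories missing from the density table.

The simulation-based checks in the test suite run at deliberate sizes:
abundance parameter recovery uses 200 replicates of 1,000 sites, GOF
calibration 50 runs with 200 bootstrap replicates each at 250 sites, and
occupancy recovery 200 replicates of 500 territories × 6 years — large
enough for binomial noise on a coverage proportion (±1.5% at 200
replicates) to sit well inside the accepted 0.90–0.99 band, and small
enough to run routinely on one CPU.

## Limitations

The two-stage design plugs estimated prey densities into the occupancy
model as fixed covariates; their sampling uncertainty is not propagated,
matching the source analysis but understating occupancy-coefficient
uncertainty when prey surfaces are poorly resolved. The Poisson mixing
distribution cannot represent under-dispersed counts (territorial
spacing) except through $\hat c < 1$ diagnostics. The Laplace
approximation for the crossed design is accurate to $O(1/n)$ in the
per-effect information and degrades when territories have very few
completed surveys and large $\sigma_v$ — the regime the single-factor
quadrature path cannot rescue.
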