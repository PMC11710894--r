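# gyrprey

Hierarchical models linking Arctic herbivore abundance to Gyrfalcon
territory occupancy.

Survey programs for tundra food webs often have exactly this shape: a
single-visit point-count design for the prey (Willow Ptarmigan, Rock
Ptarmigan, Arctic ground squirrels), repeated aerial checks of raptor
nesting territories for the predator, and a landscape raster of
vegetation covers and elevation in between. `gyrprey` implements the
full inference chain for that design, for quantitative ecologists who
want the estimators as reusable, tested functions rather than a one-off
analysis script.

## The models

**Prey abundance** — a Poisson N-mixture time-removal model. Counts at
site *i* are partitioned into *J* = 5 removal intervals of 2 min; an
individual is recorded in the interval of first detection, so the cell
probabilities are geometric in the per-interval detection probability:

    pi_ij = p_i (1 - p_i)^(j-1),   logit p_i = alpha' w_i
    N_i ~ Poisson(lambda_i),       log lambda_i = beta' x_i + log A

with *A* = 0.5024 km² (400-m radius) as the area offset, making
`exp(beta' x)` a density per km². With Poisson mixing the interval
counts are independent Poisson with means `lambda_i * pi_ij`
(multinomial–Poisson factorization) — the production likelihood. The
explicit latent-abundance sum is kept as a test oracle. Fit quality is
assessed by parametric-bootstrap Pearson chi-squared and the dispersion
ratio c-hat.

**Density surfaces** — fitted models are projected onto an 800-m
lattice (cells above 500 m elevation or outside the training covariate
range are masked), totalled over the study area with MVN-draw
intervals, and aggregated within predator territories as summed
expected counts over corrected (post-masking) territory area.

**Occupancy** — a stacked multi-year occupancy model with imperfect
detection: territory-year occupancy depends on standardized prey
densities with a year random intercept, detection depends on ordinal
date with a territory random intercept. The crossed random effects are
integrated by a joint Laplace approximation (Schur-complement Newton on
the penalized joint likelihood); single-factor cases switch to adaptive
Gauss–Hermite quadrature. Goodness of fit follows MacKenzie–Bailey
history tallies with parametric bootstrap.

A synthetic-data module generates landscapes, removal counts and
territory histories with exactly the statistical structure the
estimators assume (983 sites, five 2-min intervals, 97 territories ×
6 seasons × 2 surveys with ~60 missing), so the whole pipeline is
testable without field data.

## Worked example

Simulate removal counts for a ptarmigan-like species (true density
2.1 males/km², detection 0.3 per 2-min interval, declining with date),
fit the model and check it:

```r
library(gyrprey)

cfg <- sim_config(n_sites = 300,
  abundance_coefs = c("(Intercept)" = log(2.1), tundra = 0.5),
  detection_coefs = c("(Intercept)" = qlogis(0.3), day_of_year = -0.4))
set.seed(1)
covs <- data.frame(tundra = rnorm(300, 0, 0.5))
counts <- simulate_point_counts(cfg, covs, seed = 1)
counts$day_of_year <- standardize(counts$day_of_year)$values

fit <- fit_removal(counts, removal_spec("tundra", "day_of_year"))
fit
#> Time-removal N-mixture fit (multinomial-Poisson likelihood)
#>   sites: 300   intervals: 5   offset: 0.5024 km^2
#>   logLik: -739.489   converged: TRUE (|grad| = 2.42e-14)
#>          term  submodel estimate    se  lower  upper significant
#> 1 (Intercept) abundance    0.759 0.071  0.620  0.898        TRUE
#> 2      tundra abundance    0.607 0.121  0.370  0.844        TRUE
#> 3 (Intercept) detection   -0.696 0.134 -0.959 -0.433        TRUE
#> 4 day_of_year detection   -0.502 0.245 -0.983 -0.022        TRUE

gof_parametric_bootstrap(fit, B = 100, seed = 2)
#> Parametric-bootstrap GOF (B = 100, seed = 2)
#>   Pearson chi-sq = 1487.78, p = 0.520, c-hat = 0.995
#>   policy: cells with expected < 1e-10 excluded
```

The abundance intercept 0.759 is the log density per km² at average
tundra cover: `exp(0.759)` ≈ 2.14 males/km², recovering the generating
2.1 within its interval; the tundra and date effects land within a
standard error or two of their truths (0.5 and −0.4 on the 2-SD scale).
The bootstrap p of 0.52 and c-hat of 0.995 say the Poisson removal
model describes its own data — the calibration one should demand before
trusting it on real counts. `run_pipeline()` chains this through
density mapping, territory aggregation and the occupancy stage from a
single seed.

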