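# skinkipm

Environment-dependent Integral Projection Models (IPMs) for the demography of
a small viviparous Neotropical skink.

Viviparous tropical lizards carry a reproductive strategy selected for heat
retention into environments that are warming fast: a single litter per year
after a 9–12 month gestation, so population persistence hinges on adult
survival and one annual recruitment pulse. `skinkipm` is a tested pipeline
for asking, from long-term monthly mark–recapture data, how such a
population's growth rate λ responds to temperature and rainfall — month by
month at the study site, and pixel by pixel across the species' range under
future emission scenarios. It is written for population ecologists working
with capture–mark–recapture data on size-structured ectotherms.

## The model

Vital rates are estimated from capture records and assembled into a monthly
kernel on snout–vent length (SVL) `x`:

```
n(y, t+1) = ∫ [ P(x, y) + F(x, y) ] n(x, t) dx ,   K = P + F
```

* **Growth** — von Bertalanffy in the Fabens form for recapture intervals,
  `L₁ = L₀ + (L∞ − L₀)(1 − e^(−k·Δt))`, fitted as a nonlinear mixed-effects
  model with the growth coefficient `k` varying among individuals. Inverting
  the curve, `a = t₀ + (1/k)·ln(L∞/(L∞ − L))`, assigns each animal an age at
  first capture.
* **Size-dependent survival** — a Bayesian Gompertz mortality model,
  `h(a) = exp(b₀ + b₁·a)`, fitted by MCMC to the inferred ages with the
  unknown death month marginalised and right-censoring at the study end.
* **Environment-dependent survival** — a Cormack–Jolly–Seber model with
  monthly maximum temperature, precipitation, and mean SVL as time-varying
  covariates on survival φ and detection p; all 64 additive candidate models
  are fitted and ranked by AIC.
* **Fecundity** — Bayesian litter-size-on-SVL regression (zero-truncated
  Poisson or negative binomial), compared by PSIS leave-one-out
  cross-validation; the IPM uses a constant mean litter for females above
  the 54 mm maturity threshold, restricted to the September–January breeding
  season.
* **Demography** — the kernel is discretised by the midpoint rule on a
  50-point mesh; λ is the dominant eigenvalue (power iteration), with stable
  size structure `w`, reproductive values `v`, sensitivity `s = v wᵀ/⟨v,w⟩`,
  elasticities, net reproductive rate `R₀`, and generation time
  `T = ln R₀ / ln λ`. Monthly λ series are decomposed into seasonal, trend,
  and residual variance shares, and per-pixel yearly λ is projected across
  climate raster stacks inside a buffered minimum convex polygon of
  occurrence records.

A synthetic-data generator (`truth_params()`, `simulate_population()`, …)
produces capture tables, gravid-female data, and climate rasters with known
ground truth, so every fitting stage is testable by parameter recovery; its
defaults describe a stationary reference population (geometric-mean monthly
λ = 1).

## Worked example

```r
library(skinkipm)

truth <- truth_params(seed = 42)               # known ground truth
env   <- simulate_environment(n_months = 120, seed = 42)
sim   <- simulate_population(truth, n_individuals = 800, n_months = 120, env,
                             seed = 42)

intervals <- build_recapture_intervals(sim$captures)
growth <- fit_fabens_mixed(intervals, sex = "F")
print(growth)
#> Fabens growth fit (nlme, sex F): Linf = 78.95 mm, k = 0.0946 /month (SD 0.0137),
#>   sigma = 1.28 mm, conditional R2 = 0.986, 1132 intervals / 218 individuals

fits <- truth_fits(truth, env)                 # generative vital-rate set
env$mean_svl <- 60
kernels <- kernel_series(env[13:24, ], fits)   # one calendar year
demog <- lambda_eigen(yearly_matrix(kernels),
                      P_mean = Reduce(`+`, lapply(kernels, `[[`, "P")) / 12,
                      F_mean = Reduce(`+`, lapply(kernels, `[[`, "F")) / 12)
print(demog)
#> lambda = 1.8301, R0 = 2.464, generation time = 17.9 months, mean age of mothers = 16.1 months
```

The growth fit recovers the generative parameters (true female L∞ = 79 mm,
k = 0.095/month) from 120 simulated months of monthly trapping; the yearly
matrix for one calendar year of that environment gives the within-year
growth potential of the reference population (the monthly-λ geometric mean
over the full seasonal cycle, the package's stationarity metric, is 1).

`run_pipeline(default_config())` chains all stages — simulation,
preprocessing and SVL imputation, the three survival/growth fits, fecundity,
kernels, λ series, decomposition, optional spatial projection — and writes
every artifact plus a hashed JSON manifest.

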