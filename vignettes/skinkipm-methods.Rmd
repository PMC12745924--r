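---
title: "Methods: environment-dependent IPMs for a viviparous skink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environment-dependent IPMs for a viviparous skink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: the assumptions
behind each stage, the parameters that matter, the numerical choices, and
what the synthetic tests do and do not demonstrate about real data.

## The study system and time scale

The package models a small viviparous skink of seasonal Neotropical savanna:
neonates of about 35 mm snout--vent length (SVL) born in a single annual
litter during a September--January breeding window, females mature from
54 mm (males 49 mm), sexual size dimorphism in the asymptote (females
reaching about 79 mm, males 71 mm), and monthly pitfall trapping with
individual marks. The time step is one calendar month everywhere — it
matches monthly trap checks — and all ages, rates, and hazards are monthly.

## Growth

Recaptures are paired into consecutive intervals per individual and fitted
in the Fabens form, which needs no known ages:

$$L_1 = L_0 + (L_\infty - L_0)\,(1 - e^{-k_i\,\Delta t}) + \varepsilon,
\qquad k_i \sim N(k,\sigma_k^2),\ \varepsilon \sim N(0, \sigma^2).$$

The model is fitted with `nlme` (Lindstrom--Bates approximation to the
marginal likelihood), starting from $L_\infty$ = the largest observed SVL
and $k$ = the mean standardised growth rate
$\overline{\Delta L / (\Delta t\,(L_\infty - L_0))}$; the raw mean
$\Delta L/\Delta t$ is in mm/month and is not a usable starting value for a
1/month coefficient. Control parameters default to 5000 outer iterations,
1000 penalised least-squares iterations, and a convergence tolerance of
6e-6. Two fallbacks keep degenerate inputs fittable: `nls` when the random
effect cannot be estimated (fewer than two individuals with multiple
intervals, or a singular fit), and direct least squares on
$(\log L_\infty, \log k)$ when the residual variance is numerically zero —
noise-free recovery tests exercise exactly that limit. Intervals whose
starting SVL reaches the sex-specific asymptote estimate are flagged and
removed: the growth model assumes SVL never exceeds $L_\infty$.

Consecutive-pair intervals (not all pairs) keep growth errors independent
across intervals. The conditional $R^2$ is reported as the squared Pearson
correlation between conditional (individual-level) predictions and observed
recapture lengths; no single formula is standard for nonlinear mixed models,
so the definition is deliberately simple and documented here.

Ages are assigned by the inverse curve
$a = t_0 + (1/k)\ln\!\big(L_\infty/(L_\infty - L)\big)$ with $t_0$ anchored
so that the curve passes through the neonate SVL at age 0; ages are then
post-partum months. Sizes at or above the asymptote have no finite age and
are clamped to just below $L_\infty$ with a warning; on the default mesh
this affects only the top few mesh points, where survival is lowest anyway.

## Size-dependent survival

Mortality follows a Gompertz hazard $h(a) = e^{b_0 + b_1 a}$ (log baseline
hazard $b_0$ per month; senescence slope $b_1$ per month of age), fitted per
sex by an adaptive random-walk Metropolis sampler. Each individual enters at
its inferred age at first capture (left truncation), is known alive to its
last capture, and its unknown death month is marginalised over with monthly
detection probability $p$ estimated jointly and right-censoring at the study
end. Ages at first capture are treated as known plug-ins from the inverse
growth curve, as is conventional; propagating their uncertainty is out of
scope.

Priors are weakly informative: $b_0 \sim N(0, 10^2)$, half-normal
$b_1 \sim N^+(0,1)$, uniform $p$. Two numerical choices matter for mixing
and are worth recording: the hazard is sampled in an age-centred
parameterisation $b_0^c = b_0 + b_1\bar a$ (posterior correlation between
$b_0$ and $b_1$ otherwise slows the chain badly), and $p$ is sampled on the
logit scale with its Jacobian (otherwise proposals die at the boundary when
detection is near perfect). Proposal scales adapt toward 30% acceptance
during burn-in only. Convergence is summarised by the split-chain potential
scale reduction factor; defaults mirror a 50,000-step, burn-in 5001,
thin-50, 4-chain design, scaled to 10,000 × 4 for routine use and smaller
in tests.

## Environment-dependent survival

The Cormack--Jolly--Seber likelihood is conditioned on first capture, with
logit-linear monthly survival $\varphi_t$ and detection $p_t$ in up to three
standardised covariates: monthly maximum temperature, precipitation, and the
mean SVL of captures that month (a population-structure proxy: mortality
rises with size, so months dominated by large adults should show lower
survival). Terminal non-detection uses the standard $\chi$ recursion.
Covariates are z-scored before fitting — the likelihood is invariant to
affine reparameterisation, but quasi-Newton optimisation on raw covariate
scales (temperatures near 30, rainfall near 200) is not reliable, and the
tests check the invariance on the centred scale. The full additive cross of
covariate subsets on $\varphi$ and $p$ gives 64 candidate models, each
maximised by BFGS on grouped sufficient statistics and ranked by AIC with
ties broken toward fewer parameters. Months with no captures carry the
overall mean SVL, flagged so they can be dropped.

## Fecundity

Litter size on female SVL uses a log-link count regression truncated at one
embryo (every gravid female carries at least one): zero-truncated Poisson by
default, negative binomial as the overdispersed alternative — the family is
a documented choice, not an estimate. Models are compared by PSIS
leave-one-out cross-validation on stored pointwise log-likelihoods, with the
generalised Pareto tail fitted by probability-weighted moments. The mean
litter size entering the IPM is the posterior-mean expected litter averaged
over observed SVLs, capped at the biological maximum of eight. The
size--litter relationship is estimated and reported, but the kernel uses a
constant mean litter for all mature females: with realistic sample sizes
(tens of gravid females) the slope's credible interval typically includes
zero, and the constant-litter kernel keeps the fecundity sub-kernel
separable.

## Kernel assembly and demography

The SVL axis is discretised by the midpoint rule into 50 mesh points on
30--85 mm (about 1.1 mm resolution; neonates ~35 mm, female asymptote 79 mm,
margin on both sides). The growth transition is a discretised normal centred
on the one-month Fabens prediction with the fit's residual SD; columns are
renormalised to sum to one, so eviction is handled by mass return and the
survival--growth kernel loses mass only through survival:
$P[j,i] = G[j\,|\,i]\,S(x_i)$ has column sums exactly $S(x_i)$.

Survival combines the two fitted sources on the logit scale,

$$\operatorname{logit} S(x, t) = \operatorname{logit} S_{\text{size}}(x) +
\big[\operatorname{logit}\varphi_{\text{CJS}}(z_t) -
\operatorname{logit}\varphi_{\text{CJS}}(0)\big],$$

so that survival reduces to the size-dependent estimate under the average
environment. The same additive-on-logit convention is used by the simulator,
making the combination rule a shared generative assumption rather than a
post-hoc correction. Environment enters survival only; temperature is not a
predictor of growth or litter size.

Fecundity is female-based with a 0.5 offspring sex ratio. The annual litter
is divided evenly across the five breeding months; a single-pulse
alternative is a parameter away (`breeding_months`). The probability of
reproduction for a mature female within the season is fixed at one. Newborn
sizes follow a discretised normal (35 ± 2 mm) renormalised on the mesh, with
an error if more than 1% of its mass would fall outside.

Yearly dynamics use the chronological product
$A = K_{12}\cdots K_1$. The dominant eigenvalue is found by power iteration
at tolerance 1e-10 on the shifted matrix $A + cI$ — the shift changes the
eigenvalue by exactly $c$ and the eigenvectors not at all, but guarantees
convergence for cyclic stage structures (a juvenile/adult loop with no
self-transition is periodic and defeats unshifted iteration). Reducible
matrices are rejected with the unreachable state named. $R_0$ is the
dominant eigenvalue of $F(I-P)^{-1}$ on mean monthly sub-kernels and
generation time $T = \ln R_0 / \ln \lambda_m$ in months; when $\lambda$ is
numerically 1 this ratio is undefined and is flagged, with the mean age of
mothers $\lambda\langle v, w\rangle / \langle v, F w\rangle$ reported as the
stable alternative.

The monthly population-growth metric is the dominant eigenvalue of each
single month's kernel — "what would growth be if this month persisted" — and
its geometric mean over the series is the package's stationarity summary.
This is deliberately not the 12th root of the yearly product: the two differ
substantially when breeding is pulsed, and the monthly metric is the one
that feeds the seasonal decomposition.

## Decomposition and spatial projection

Monthly series (survival, λ) are decomposed classically: centred 12-month
moving-average trend, month-wise mean seasonal component re-centred to zero,
residual remainder. Variance shares are normalised component variances over
the months where all three are defined — chosen because shares defined this
way sum to one. The decomposition is additive: the series cross no zero and
seasonal amplitude does not scale with level here; a multiplicative variant
would be a one-line change.

Spatial projection treats each pixel as an independent demographic unit (no
dispersal): per pixel and year, 12 monthly kernels from that pixel's climate
series give a yearly λ, aggregated to period means and SDs (over yearly λ
within the period), masked by the occurrence-record convex hull. The mean
SVL covariate is unobservable per pixel and is held at its study-period mean
(z-score zero). Climate stacks are opaque inputs tagged with their scenario;
no climate-model logic lives in the package. Rasters are written as 32-bit
float TIFF layers with ESRI world files and a JSON sidecar carrying the
month index, CRS tag, and value range — values are rescaled to [0,1] for
storage and restored on read, round-tripping to float32 precision.

## The synthetic generator and the reference population

`simulate_population()` generates the study the fitters expect: births only
in breeding months (including up to 36 months before the study, so the
initial population is age-structured), deterministic individual growth with
truncated-normal $k_i$ (shrinkage-free by construction), monthly deaths from
the Gompertz hazard modulated on the logit scale by the z-scored
environment, imperfect monthly detection, 1 mm SVL measurement noise, and a
fraction of unsexable animals. Mass and tail follow simple allometries so
the imputation stage has real predictors. Detection is population-wide; the
field design samples several fire-regime subplots, but with no evidence on
subplot-level detection differences the generator does not invent them.

Defaults are the reference study conditions: female $L_\infty$ 79 mm, male
71 mm, $k$ = 0.095/month (SD 0.015), $b_0 = -3.3$, $b_1 = 0.01$ (about 5% of
a cohort reaching five years), temperature coefficient $-0.4$ on logit
survival, detection intercept $-1.1$ (monthly $p \approx 0.25$), litter mean
4.48. The litter value is the one calibrated constant: it is the root of
"geometric-mean monthly λ = 1" under the default noise-free environment, so
the reference population is stationary by construction and end-to-end runs
test whether the full estimation chain returns to that point. Environmental
series default to a 27 °C baseline, 3 °C seasonal amplitude, +0.2 °C/decade
trend, and an October--May wet season.

What passing recovery tests do **not** show: the generator has no spatial
autocorrelation in climate noise, no movement, no density dependence, no
trap-level heterogeneity, and its growth is exactly von Bertalanffy — real
data violate all of these, so recovery here demonstrates correctness of the
estimation chain, not robustness to model misspecification.

## Problem sizes

Routine runs and tests use 800–1,500 individuals over 120 months (roughly
the scale of a 15-year monthly trapping study), 30 gravid females, 25-seed
replication for model-selection sign recovery at 36 occasions, and a 10×10
pixel decade for spatial checks; MCMC chains are scaled to a few thousand
steps where posterior means, not tail quantiles, are being checked.

## Known limitations

Sex-specific kernels share the female growth fit (the model is
female-based); age uncertainty from the growth inversion is not propagated
into the mortality posterior; the CJS stage has no goodness-of-fit
(median-c-hat) machinery; detection is constant in the Gompertz likelihood
rather than month-varying; and the spatial projection inherits whatever bias
the climate stacks carry, since no bias correction is applied.
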