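# blmmcor

Correlation between two longitudinal outcomes via bivariate linear mixed
models (BLMM), with explicit attention to what latent population
heterogeneity does to every correlation summary.

## The problem

In chronic-disease cohorts two outcomes are often tracked in parallel — the
motivating setting is glaucoma, with the visual-field mean deviation (MD, in
dB; outcome 1) measured semiannually and ETDRS visual acuity (VA, letters;
outcome 2) measured annually. A single Pearson correlation is meaningless
for such data: measurements are repeated within subjects, and the two
outcomes sit on different visit grids. The standard tool is a joint mixed
model: each outcome follows a linear mixed model

y₁ᵢ(t) = Zᵢα_Z + (α₀ + a₀ᵢ) + (α₁ + a₁ᵢ)t + ε₁ᵢ(t)
y₂ᵢ(t) = Zᵢβ_Z + (β₀ + b₀ᵢ) + (β₁ + b₁ᵢ)t + ε₂ᵢ(t)

and the four random effects (a₀ᵢ, b₀ᵢ, a₁ᵢ, b₁ᵢ) share an unstructured 4×4
covariance Σ. Residuals are independent, or optionally correlated between
same-time visits of the two outcomes (σ₁₂).

From a fitted model the package computes three correlation summaries:

* **Association of evolution** — ρ_int = σ_{a₀b₀}/√(σ²_{a₀}σ²_{b₀}) and
  ρ_slope = σ_{a₁b₁}/√(σ²_{a₁}σ²_{b₁}), the correlations between the
  outcomes' random intercepts and random slopes.
* **Evolution of association** — the marginal correlation
  ρ(t) = (σ_{a₀b₀} + tσ_{a₀b₁} + tσ_{a₁b₀} + t²σ_{a₁b₁} [+ σ₁₂]) /
  √(σ²_{a₀} + 2tσ_{a₀a₁} + t²σ²_{a₁} + σ²₁) √(σ²_{b₀} + 2tσ_{b₀b₁} +
  t²σ²_{b₁} + σ²₂), which starts near the (error-diluted) intercept
  correlation and converges to ρ_slope as t grows.
* **Conditional correlation** — ρ(Y₁(t), Y₂(t) | γ₀ > c₁, γ₁ > c₂), the
  marginal correlation inside the clinically "stable" stratum defined by
  thresholds on outcome 1's subject-specific intercept level γ₀ and slope
  γ₁ (defaults c₁ = −5 dB, c₂ = −0.5 dB/year), estimated by parametric
  bootstrap from the fitted joint normal of (Y₁, Y₂, γ₀, γ₁).

The point of the conditional summary: when a small subgroup of rapid
progressors contaminates an otherwise stable population, the first two
summaries can be grossly inflated, while the conditional one stays close to
the majority-population truth. The package ships a two-class mixture
simulator and scenario runner (`run_scenario`) that quantify this distortion.

## Worked example

Simulate a 300-subject cohort in which 15 subjects (5%) belong to a rapidly
progressing class, then fit the homogeneous model that (wrongly) assumes a
single population:

```r
library(blmmcor)
spec <- mixture_presets(p_progressive = 0.05)   # true rho_int/rho_slope: 0.145/0.111
sim  <- simulate_mixture(spec, seed = 20, fixed_count = TRUE)
fit  <- blmm(sim$data)
summary(fit)
#> Bivariate linear mixed model (independent errors)
#>   300 subjects, 6600 observations, log-likelihood -16569.703
#> ...
#> var.int1            4.1619    0.3929
#> var.int2           39.0210    3.6659
#> ...
#> Random-effect correlations: intercepts 0.261, slopes 0.584

marginal_correlation(fit, c(0, 2.5, 5))
#> [1] 0.177 0.393 0.549

conditional_correlation(fit, 5, n_boot = 2000, seed = 1)
#> Conditional correlation at t = 5 given gamma0 > -5, gamma1 > -0.5
#>   estimate 0.4139, 95% CI (0.2926, 0.5263), 2000/2000 replicates used
```

Reading: the generating slope correlation is 0.111, but the 5% progressive
admixture drives the fitted ρ_slope to 0.584 and the marginal correlation at
5 years to 0.55 — the association is manufactured almost entirely by the
minority class. The conditional estimate within the stable stratum (0.41
here, and lower still at earlier times) moves back toward the
homogeneous-population curve.

Empirical bootstrap intervals (subjects as resampling units) for the
random-effect correlations come from `bootstrap_correlations(sim$data,
B = 500, seed = 1)`; the error-structure choice is testable with
`anova(fit_indep, fit_corr)` (a 1-df likelihood ratio test on σ₁₂).

## Command-line tool

A thin Rscript front end over the same functions is installed at
`system.file("cli", "blmmcor", package = "blmmcor")` with subcommands
`fit`, `corr`, `conditional`, `simulate`, and `scenario`; every output embeds
the seed and a hash of the invoking configuration.

## Acceptance script

`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
re-runs the heterogeneity experiments from scratch: for each scenario level
(progressive fraction 5/10/20%, halved progressive slopes, residual
correlation 0.8 analyzed as independent) it simulates 250 replicate cohorts
of 300 subjects from the preset mixture, fits the homogeneous
independent-error model to each, and writes the replicate-averaged
random-effect correlations as JSON.
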