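---
title: "Measurement error models for energy balance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error models for energy balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Energy balance obeys the first-law identity ΔES = EI − EE: the daily change
in energy stores equals intake minus expenditure (kcal/day). Gold-standard
instruments exist for two of the three components — doubly labeled water
(DLW) measures EE essentially without bias over a ~14-day window, and DXA
body-composition scans yield ΔES after converting fat-mass and fat-free-mass
changes to energy (`delta_es_from_dxa()`, with energy densities 9500 and
1100 kcal/kg by default). Both are too expensive for large studies. Consumer
devices are cheap but biased and noisy. If a subsample wears both, a joint
model of the two instrument classes can quantify the device's bias and
noise, and then *calibrate* device-only readings back to the latent truth.

`ebmem` implements four such models for the bivariate outcome
(EE, ΔES), all treating subject *i*'s *usual* (long-run mean) values
$(X_i^{EE}, X_i^{\Delta ES})$ as latent:

* **naive** — regresses the device reading $Y_{ij}$ linearly on the
  gold-standard reading $W_{ij}$ and error-free covariates
  $Z_i$ = (gender, BMI, age), ignoring gold-standard error;
* **LMEM** — a linear measurement error model:
  $Y_{ij} \sim N(\beta_0 + \beta_1 X_i + \gamma' Z_i, \sigma_\epsilon^2)$,
  $W_{ij} \sim N(X_i, \sigma_\nu^2)$ per attribute, with a bivariate normal
  prior on the latent pair;
* **SMEMN** — replaces the linear device mean with a free-knot monotone
  cubic B-spline $s(X_i; \beta)$, keeping the bivariate normal latent
  prior;
* **SMEM** — as SMEMN, with a truncated Dirichlet process mixture latent
  prior (stick-breaking weights $\pi_h = V_h \prod_{\ell<h}(1-V_\ell)$,
  $V_h \sim \mathrm{Beta}(1, \alpha)$, $\alpha = 1$, truncation $H = 20$,
  leaving expected tail mass below $10^{-6}$).

Conditional on the latent pair and covariates, the four measurement
channels are mutually independent. Monotonicity of the spline —
non-decreasing coefficients imply a non-decreasing spline — is what makes
the fitted bias invertible for calibration.

## Estimation

The naive model and LMEM are sampled by conditionally conjugate Gibbs
(`fit_naive()`, `fit_lmem()`): normal updates for regression coefficients,
inverse-gamma for variances, a joint bivariate-normal conditional for each
latent pair, and normal / inverse-Wishart conditionals for the latent mean
and covariance. Priors follow the stated hyperparameters: N(0, 1e5) on
intercepts and covariate coefficients, N(1, 1e5) on slopes, IG(0.1, 0.1) on
variances, latent mean prior N((2400, 0), diag(1e5)), inverse-Wishart(3, I)
on latent covariances, Poisson(1) on knot counts.

The spline models are sampled by Reversible Jump MCMC (`fit_smem()`). Per
sweep and attribute:

1. a **birth / death / move** proposal on the interior knots
   (probabilities 0.35 / 0.35 / 0.30; at zero knots the whole mass goes to
   birth). Knot candidates are the current latent values — a discrete
   uniform prior chosen for computational convenience, since the latents
   move every sweep anyway. Spline and covariate coefficients carry no
   prior and are refit by OLS at each proposal (the "not fully Bayesian"
   free-knot scheme); coefficients are then deterministic given the knots,
   the Jacobian is 1, and the acceptance ratio reduces to
   likelihood × Poisson prior × proposal correction, with the
   candidate-count factors cancelling between the position prior and the
   uniform birth proposal. Proposals with non-monotone OLS coefficients are
   rejected outright.
2. an **OLS refresh** at the current knots (the latents moved last sweep);
   if the refreshed coefficients violate monotonicity the previous
   monotone fit is kept for the sweep.
3. **inverse-gamma** updates of the device and gold-standard variances.
4. a **vectorised random-walk Metropolis** update of all latent pairs
   (they are conditionally independent), with proposal sds adapted during
   burn-in towards 20–40% acceptance and frozen afterwards to preserve
   detailed balance.
5. for SMEM, the truncated stick-breaking block: categorical label update,
   Beta stick updates, and per-cluster normal / inverse-Wishart updates
   (empty clusters resampled from the prior).

**Spline domain.** Rather than recomputing the basis boundary whenever a
latent escapes it (which would change every subject's plug-in likelihood
mid-run and break detailed balance), each fit fixes a generous domain once
— the gold-standard replicate-mean range padded by 25% — and rejects latent
proposals outside it. The excluded posterior mass is negligible; the
sampler is exact on the truncated domain.

**Two replicates and the DP prior.** With only two replicate measurements
the DP variant mixes poorly (low latent acceptance, unstable cluster
parameters); `fit_smem(..., "dp")` warns in that case and SMEMN is the
recommended model.

## Calibration

For a new device reading $y$ with covariates $z$, each retained posterior
draw $r$ yields $y^* = y - \gamma^{(r)\prime} z$ and a calibrated value
$x^{(r)} = s^{(r)-1}(y^*)$, found by bracketing on the knot grid and
root-finding within the bracketing segment (tolerance $10^{-6}$ kcal) over
the draw's latent range padded by 10% — the spline is only identified where
latent mass exists. Readings beyond the attainable range return the bound
with a flag rather than an error (real devices do report out-of-range
values). The point estimate is the posterior median, robust to boundary
solutions; `credible_interval()` returns empirical (type-7) quantiles.

**When calibration helps — and when it cannot.** Calibration error is
locally $|\epsilon| / s'(x)$: it beats the raw reading where the device
bias (including the covariate offset $\gamma'Z$) is large or the bias curve
is steep. In the synthetic world shipped as default, the ΔES bias function
has unit slope and calibration yields a modest but real median improvement.
The EE bias function, however, is nearly flat (slope ≤ 0.6, mostly ≈ 0.2)
across the simulated latent range 1900–3100 kcal/day, so inversion
amplifies the ~395 kcal/day device noise several-fold; even inverting the
*true* bias function with the *true* coefficients raises the median
absolute EE error above the raw reading's (oracle check at n = 20000: raw
427 vs calibrated 638 kcal/day). The corresponding acceptance test asserts
the improvement for both attributes and is therefore expected to fail for
EE: a flat bias curve is an information-theoretic limit, not a fitting
defect. Practitioners should check the fitted spline's slope over the
latent range before trusting point calibration there; the credible
interval, which widens over flat regions, is the honest summary.

## The synthetic-data generator

`simulate_eb_dataset()` emulates a 300-subject validation study:

* covariates: gender ~ Bernoulli(0.5), age ~ Uniform(20, 40),
  BMI ~ Normal(27, 5);
* latent usual (EE, EI) pairs from a 5-component bivariate-t mixture
  (df = 5, 60 pairs per component), with usual ΔES = EI − EE exactly;
* within-person deviations $(\delta^{EE}_{ij}, \delta^{\Delta ES}_{ij})$
  bivariate normal, shared between the gold-standard and device channels of
  the same period (both instruments observe the same days);
* gold standard: $W_{ij} = X_i + \delta_{ij} + u_{ij}$ (unbiased);
* device: $Y_{ij} = m(X_i + \delta_{ij}) + \gamma' Z_i + \epsilon_{ij}$,
  with smooth monotone bias functions
  $m_{ee}(x) = 2x - 4000/(1+e^{-0.002(x-2200)})$ and
  $m_{es}(x) = 1000/(1+e^{-0.04(x-2000)}) + x$, and covariate effects
  $\gamma_{ee} = (300, 14, -7)$, $\gamma_{es} = (-200, 8, -5)$ for
  (gender, BMI, age);
* instrument errors from one of three moment-matched zero-mean families:
  normal; skew-normal with shape 4; or an equal-weight two-normal mixture
  with component means at ±1.2 component-sds, rescaled to the target sd
  (1.2 > 1 ensures two genuine modes).

Choices the underlying description leaves open, fixed once here:

* **Mixture geometry.** EE locations (1900, 2200, 2500, 2800, 3100)
  kcal/day; EI locations (2100, 2650, 2300, 2900, 2550) so mean ΔES is
  zero. The common scale matrix's cross-term is solved in closed form at
  construction so the pooled Pearson corr(EE, EI) equals the target 0.4376:
  pooled covariance = (df/(df−2))·Σ + between-location covariance.
* **Error-sd split.** Only the total gold-standard error sds (250.00 EE,
  72.86 ΔES) are constrained; the split is instrument sd 200 / within-person
  sd 150 for EE and 50 / √(72.86² − 50²) for ΔES, with within-person
  correlation 0.3. Device error sds are frozen at 395.36 (EE) and
  329.77 (ΔES), computed once so the Monte Carlo residual sds of the device
  channels (`approximate_sigma_y_truth()`, which regenerates many datasets
  and removes the mean function at the usual values) are ≈ 405.5 and
  ≈ 334 — the propagation of the within-person deviation through the bias
  function accounts for the difference.
* **Seeding.** One root seed; deterministic sub-streams per component
  (covariates, latents, deviations, each error channel) so components can
  be regenerated independently and a dataset is bit-reproducible.

What the generator does *not* emulate: real DLW isotope kinetics or DXA
precision, non-steady-state weight trajectories, unbalanced replicate
designs, informative missingness. A green simulation test therefore
establishes internal consistency of model and generator, not field
validity of any particular device.

## The simulation study

`run_study()` crosses error families × replicate counts × models over
`n_datasets` Monte Carlo datasets (default 25, scaled down from the
reference 200), with per-cell seeds derived from
(root, model, family, replicates, index) so cells are independently
re-runnable. It reports, per parameter, the mean of posterior means
("Mean Est"), the SD of posterior means across datasets ("Std Err" — the
Monte Carlo summary convention), bias against the generator truth, and
per-dataset log prediction MSE of the device mean functions. Fit failures
are counted and excluded, never silently dropped.

**PMSE evaluation points.** Each model's regression function is evaluated
at its own regressor: hierarchical models at the subject's true latent
value, the naive model at the subject's gold-standard replicate mean — the
input it actually uses. Evaluating the naive model at the true latents
would credit it with information it never sees; with its own regressor,
treating the noisy gold standard as error-free counts against its
predictions, and the expected ordering naive > LMEM > SMEMN in log-PMSE
emerges. Absolute PMSE levels depend on the latent distribution (the
evaluation points are subjects, not a fixed grid), so orderings, not
levels, are the meaningful comparison.

## Numerical notes

* Monotonicity tolerance −1e-12 on coefficient differences absorbs
  floating-point ties; degree is fixed at 3 (cubic) with clamped boundary
  knots.
* The knot count is capped at 30; OLS plug-in likelihoods carry no Occam
  factor, so parsimony rests on the Poisson(1) prior — posterior medians
  stay at four knots or fewer on default data.
* Variance Gibbs updates use the exact within/between-replicate sum-of-
  squares decomposition, so samplers work from replicate means where the
  algebra allows.
* Inverse-Wishart draws via `stats::rWishart` on the inverted scale;
  2×2 inverses are closed-form.
* `gelman_rubin()` is the classic PSRF
  $\sqrt{((n-1)/n\,W + (1+1/m)B/n)/W}$; identical chains give
  $\sqrt{(n-1)/n} \approx 1$.

## Known limitations

* Constant error variances (a working assumption of all four models);
  covariates are assumed error-free.
* The OLS plug-in treatment of spline coefficients understates their
  posterior uncertainty relative to a fully Bayesian prior; calibration
  intervals inherit this.
* Calibration inverts each attribute separately; no joint bivariate
  inversion.
* Point calibration is unreliable wherever the fitted bias curve is flat
  (see the calibration section); flagged boundary solutions and wide
  intervals signal this.
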