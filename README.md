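# ebmem — Bayesian measurement error models for energy balance

`ebmem` is an R package for researchers in physical activity, nutrition and
obesity who need reliable daily **energy expenditure (EE)** and **change in
energy stores (ΔES)** — and hence, through the energy-balance identity
ΔES = EI − EE, **energy intake** — from cheap wearable devices that are
biased and noisy. Given a validation subsample measured with both
gold-standard instruments (doubly labeled water for EE; DXA-derived ΔES)
and the device, the package fits a joint Bayesian measurement error model
and then *calibrates* device-only readings back to the latent truth with
credible intervals.

## The model

Each subject's usual (long-run mean) values
$(X_i^{EE}, X_i^{\Delta ES})$ are latent. Per replicate period $j$:

$$
\begin{aligned}
Y_{ij} &\sim N\!\big(s(X_i;\beta) + \gamma' Z_i,\ \sigma_\epsilon^2\big)
  &&\text{(device, per attribute)}\\
W_{ij} &\sim N\!\big(X_i,\ \sigma_\nu^2\big)
  &&\text{(gold standard, per attribute)}
\end{aligned}
$$

where $Z_i$ = (gender, BMI, age) are error-free covariates and
$s(\cdot;\beta)$ is a **free-knot monotone cubic B-spline** whose knot
count and positions are sampled by **Reversible Jump MCMC** (non-decreasing
coefficients ⇒ invertible bias). The latent pair carries either a bivariate
normal prior (model `smemn`) or a truncated Dirichlet process mixture
(`smem`). Simpler references — a naive linear regression of $Y$ on $W$ and
a linear measurement error model (`lmem`) — are included, all with
conditionally conjugate Gibbs samplers. Calibration inverts the fitted
spline draw by draw: $x^{(r)} = s^{(r)-1}\!\big(y - \gamma^{(r)\prime}z\big)$.

A complete synthetic-data generator reproduces the structure of a 300-subject
validation study (5-component bivariate-t latent mixture with EE–EI
correlation 0.4376, nonlinear device bias, within-person day-to-day
variation shared across instruments, normal / skew-normal / bimodal error
families), so the whole simulation study runs with no external data.

## Worked example

```r
library(ebmem)

# a synthetic validation study: 300 subjects, 4 replicate periods
ds <- simulate_eb_dataset(n_subjects = 300, n_replicates = 4, seed = 42)

# fit the spline measurement error model (bivariate-normal latent prior)
fit <- fit_smem(ds, "normal",
                chain_config(n_chains = 1, n_iterations = 3000,
                             burn_in = 1000, seed = 42))
posterior_summary(fit, c("gamma1_ee", "gamma1_es",
                         "sig_nu_ee", "sig_nu_es", "k_ee", "k_es"))
#>   parameter      mean       sd       q2.5     median      q97.5
#> 1 gamma1_ee  312.3687 7.758706  297.38388  312.70870  326.86965
#> 2 gamma1_es -186.0168 4.349785 -193.66802 -185.92788 -177.56084
#> 3 sig_nu_ee  248.9604 6.053441  237.75604  248.89862  261.06800
#> 4 sig_nu_es   73.6377 1.753043   70.14479   73.61801   77.13475
#> 5      k_ee    2.8030 1.137470    1.00000    3.00000    4.00000
#> 6      k_es    1.1505 1.107006    0.00000    1.00000    3.00000
```

Read: the device over-reports EE for males by ≈ 312 kcal/day (generator
truth 300) and under-reports ΔES by ≈ 186 (truth −200), all else equal;
the gold-standard error sds are recovered (truths 250 and 72.86 kcal/day);
both bias splines stay parsimonious (posterior median ≤ 3 knots).

```r
# calibrate a new device dES reading of 180 kcal/day for a male,
# BMI 27, age 30
cal <- calibrate(y = 180, z = c(gender = 1, bmi = 27, age = 30),
                 fit, attribute = "es")
cal
#> <eb_calibration> es: y = 180.00 -> 286.90 [275.07, 296.08] (1000 draws)
```

The reading 180 is corrected upward to a posterior median of ≈ 287 kcal/day
(the fitted device bias for this profile is ≈ −107), with a 95%
credible interval [275, 296] reflecting posterior uncertainty in the bias
spline and coefficients. A caveat that matters in practice: point
calibration is only as good as the slope of the bias curve — see the
methods vignette (`vignettes/energy-balance-measurement-error.Rmd`) for
when inversion helps and when it cannot.

Other entry points: `fit_naive()` / `fit_lmem()` (Gibbs),
`gelman_rubin()` (PSRF diagnostics), `run_study()` (Monte Carlo
parameter-recovery and log-PMSE tables), `calibrate_table()` (batch
calibration), `write_dataset()` / `read_dataset()` / `write_draws()` /
`read_draws()` (plain-text I/O), and a CLI:

```sh
Rscript -e 'ebmem::ebmem_cli()' simulate --out d.csv --seed 7
Rscript -e 'ebmem::ebmem_cli()' fit --data d.csv --out post/ --model smemn
Rscript -e 'ebmem::ebmem_cli()' calibrate --posterior post/ --new new.csv --out cal.csv
```

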