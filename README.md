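# evaluesim

Monte Carlo machinery for studying how the **E-value** — the popular
sensitivity statistic for unmeasured confounding — behaves when
propensity-score methods *amplify* the imbalance in unobserved covariates
instead of removing it.

## The problem

Propensity-score matching (PSM) and inverse probability of treatment
weighting (IPTW) balance the covariates an analyst can see. When an
unobserved covariate drives treatment choice with variation independent of
the observed ones, forcing balance on the observed covariate can *increase*
imbalance in the unobserved ones — bias amplification. The E-value,
$$E = RR + \sqrt{RR\,(RR - 1)} \qquad (RR \ge 1),$$
is a deterministic, increasing function of the estimated risk ratio, so a
*more biased* estimate produces a *larger* E-value: exactly when the
analysis is least trustworthy, the sensitivity statistic looks most
reassuring. `evaluesim` quantifies this with a fully seeded simulation.

Cohorts follow a latent-utility / logistic-cure model: an observed
confounder $X_m \sim U[0,1]$; unobserved covariates
$X_{ui} = \rho X_m + (1-\rho)\mu$ (and $X_{u2} = 0.5X_{u3} + 0.5\mu$);
treatment $T = \mathbf{1}\{V\beta_T - S + \alpha\sum X > 0\}$; cure
$C \sim \mathrm{Bernoulli}(\mathrm{expit}(\beta_T T + \beta_m X_m +
\beta_{u1}X_{u1} + \beta_{u2}X_{u2}))$ with true effect $\beta_T = 0.2$.
Sweeping $\rho$ from 0 to 0.9 moves the design from independent to nearly
collinear confounding. Five estimators are compared per replicate:
unadjusted, observed-confounder and full-information logistic regressions,
probit-based IPTW, and 1:1 greedy caliper PSM (calipers 0.001 / 0.01 / 0.1).
Diagnostics cover standardized mean differences, common support,
g-computation standardized risk ratios and E-values. The methods vignette
(`vignettes/bias-amplification-and-the-evalue.Rmd`) documents the model,
the calibration of the unprinted structural parameters and every design
choice.

## Worked example

```r
library(evaluesim)
co <- simulate_cohort(dgp_params(n_obs = 10000, rho = 0.2, seed = 42))
co
#> Simulated cohort: 10000 observations (rho = 0.2)
#>   treated fraction 0.501, cure fraction 0.663
res <- estimate_all_methods(co)
res$fits$all_confounders
#> <fit_result: all_confounders>
#>   beta_T_hat = 0.1723 (SE 0.0618), OR = 1.1880, RR = 1.0589
res$fits$no_confounders
#> <fit_result: no_confounders>
#>   beta_T_hat = 0.5007 (SE 0.0427), OR = 1.6499, RR = 1.1830
res$fits$psm_0.001
#> <fit_result: psm_0.001>
#>   beta_T_hat = 0.4137 (SE 0.0681), OR = 1.5123, RR = 1.1469
#>   n_analytic = 3940, converged = TRUE
evalue(res$fits$no_confounders$risk_ratio)$evalue   # 1.648
evalue(res$fits$all_confounders$risk_ratio)$evalue  # 1.309
```

Reading: the correctly specified model recovers $\hat\beta_T \approx 0.2$
(marginal RR ≈ 1.06 on this replicate), while the unadjusted and matched
analyses are biased upward — and the biased unadjusted estimate carries the
*larger* E-value (1.65 vs 1.31), illustrating the headline phenomenon.

A full sweep:

```r
mc <- run_monte_carlo(n_replicates = 200, master_seed = 1)  # ~6 min
write_summary(mc, "results", figures = TRUE)
```

writes `summary_long.csv` (per-ρ/method medians, SDs, percentiles),
`table1.csv` (compact per-ρ table), `replicates.csv`, a config echo, and —
with `ggplot2` — four diagnostic figures (balance, support, estimates,
bias vs E-value). A thin CLI wraps the same functions:
`exec/evaluesim run --out dir --seed 1`, `... report --in dir`,
`... evalue --rr 1.07`.

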