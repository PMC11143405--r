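# ollged

Tools for the **odd log-logistic generalized exponential distribution
(OLLGED)**, a three-parameter lifetime family for survival and
reliability data whose hazard can be increasing, decreasing, unimodal or
reversed-J — shapes the usual two-parameter families cannot all reach.
The intended users are statisticians and epidemiologists fitting
parametric lifetime models and comparing them against nested and rival
families.

## The model

The generalized exponential baseline has CDF
F(x) = (1 − e^(−λx))^α with scale λ > 0 and shape α > 0.  The odd
log-logistic transform raises its odds to a power γ > 0 and
re-normalizes:

    G(x) = F(x)^γ / [ F(x)^γ + (1 − F(x))^γ ]

γ = 1 gives back the generalized exponential (GE) distribution;
γ = α = 1 the exponential.  The package provides:

* numerically stable `dollged` / `pollged` / `qollged` / `rollged` /
  `sollged` / `hollged` (everything is computed as the logistic of
  γ·logit F with `log1p`/`expm1` primitives, so both tails stay exact),
  plus the raw transform `oll_transform`;
* quadrature moments, MGF, Galton skewness and Moors kurtosis
  (octile-based), mean residual life, mean inactivity time, and
  order-statistic densities/moments;
* the power-series expansion of the CDF (`ollged_series`) with honest
  convergence diagnostics;
* multi-start maximum-likelihood fitting in log-parameter space
  (`fit_mle`) with standard errors from the numerically observed
  information, goodness-of-fit panels (`gof_report`: −2ℓ̂, AIC, BIC,
  modified Anderson–Darling A\* and Cramér–von Mises W\*,
  Kolmogorov–Smirnov with asymptotic p-value) and model comparison
  (`compare_models`) against the GE, exponential and log-logistic
  baselines;
* Monte-Carlo bias/MSE studies of the estimator (`sim_design`,
  `run_simulation`, `simulation_table`);
* two classical datasets (`ollged_data`): 64 Kiama Blowhole eruption
  waiting times and 45 chemotherapy survival times; and a small CLI
  (`exec/ollged`, subcommands `fit | compare | simulate | dpqr |
  datasets`).

## Worked example

```r
library(ollged)

x <- ollged_data("kiama64")          # 64 eruption waiting times (seconds)
fit <- fit_mle(x, ollged_model(), seed = 1)
fit
#> Maximum-likelihood fit: OLLGED(lambda,alpha,gamma)
#>   n = 64  ( 27 start(s), converged )
#>   lambda    0.1706 ( 0.0613)
#>   alpha    44.9890 (42.6244)
#>   gamma     0.2096 ( 0.0785)
#>   log-likelihood -289.7205  (-2l = 579.4411)

compare_models(x, seed = 1)
#> Model comparison (n = 64 ); * marks the best model per criterion
#>   model minus2loglik       aic       bic  w_star  a_star ks_stat ks_pvalue
#>  ollged    579.4411* 585.4411* 591.9177* 0.1081* 0.6275*  0.0999    0.5452
#>     ged     591.3320  595.3320  599.6498  0.1441  0.9742  0.1227    0.2899
#>      ed     599.6254  601.6254  603.7843  0.1915  1.6092  0.1664    0.0579
#>     lld     593.1489  597.1489  601.4666  0.1201  0.9017 0.0998*   0.5467*

ollged_mean_variance(1, 2, 2)
#>      mean  variance
#> 1.3079177 0.3065641
```

The comparison reads: the OLLGED attains the smallest −2ℓ̂, AIC, BIC,
W\* and A\* of the four families on these data — the two extra shape
parameters buy a 20-point likelihood improvement over the exponential —
while the log-logistic is a whisker better on the KS distance.  The
three-parameter estimates sit on a long flat likelihood ridge (hence the
wide standard error on α); the fitted CDF and the fit statistics are far
more stable than the individual parameters there, a point discussed in
the methods vignette (`vignettes/ollged-methods.Rmd`).

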