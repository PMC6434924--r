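# directqr

Direct nonparametric estimation of high conditional quantiles, with the
classical linear and local-polynomial quantile regressions as exactly
solved baselines, a relative goodness-of-fit index, and a reproducible
Monte-Carlo efficiency study.

## Who this is for

Analysts modeling extreme conditional outcomes — peak snowfall given
temperature, upper-tail emissions given GDP, any setting where the
quantity of interest is $Q_y(\tau \mid x) = F^{-1}(\tau \mid x)$ at
$\tau \ge 0.95$ and a linear quantile model is too rigid.

## The estimator

Classical quantile regression minimizes the check loss
$\rho_\tau(u) = u\{\tau - I(u < 0)\}$ over lines; `directqr` additionally
implements a model-free estimator built in five steps:

1. kernel conditional density
   $\hat f(y \mid x) = \hat f(y, x) / \hat g(x)$ (covariance-whitened
   Gaussian kernel, normal-reference plug-in bandwidths);
2. conditional CDF $\hat F(y \mid x)$ by running trapezoid integration;
3. local quantiles
   $\hat\xi_i = \inf\{y : \hat F(y \mid x_i) \ge \tau\}$ inverted at
   every data point;
4. Nadaraya–Watson smoothing
   $Q_D(\tau \mid x) = \sum_i W_h(x, X_i)\, \hat\xi_i$ with
   equivalent-kernel weights ($W_h \ge 0$, $\sum W_h = 1$), which makes
   the curves non-crossing across $\tau$ by construction;
5. diagnostics (coverage, crossing, grid health).

Fits are compared with the relative index
$R(\tau) = 1 - V_D(\tau)/V_R(\tau)$, where $V$ is the mean
$\tau$-weighted absolute deviation of the data from a fitted curve;
$R > 0$ favors the direct fit.  A Monte-Carlo module reproduces the
efficiency study on Gumbel's second kind of bivariate exponential
distribution, $F(x,y) = (1-e^{-x})(1-e^{-y})(1+\alpha e^{-(x+y)})$,
whose conditional quantile is known in closed form, reporting
$\mathrm{SMSE}$ (replicate-averaged $\int_0^6 (\hat Q - Q_y)^2 dx$) and
$\mathrm{SEFF} = \mathrm{SMSE}(Q_R)/\mathrm{SMSE}(\cdot)$.

## Worked example

```r
library(directqr)
dat <- gumbel_sample(200, gumbel_params(1), seed = 42)
s   <- regression_sample(dat$y, dat$x, column_names = "x")

curves <- direct_quantile_curve(s, c(0.95, 0.99), x_eval = seq(0, 5, 0.5))
diagnose(curves, s)
#> <qr_diagnostics>
#>   tau method coverage n_extrapolated
#>  0.95 direct    0.950              0
#>  0.99 direct    0.995              0
#> no crossing violations

fitD <- direct_quantile_curve(s, 0.95, x_eval = s$X)
linD <- predict_linear_qr(fit_linear_qr(s, 0.95), s$X)
relative_R(s, fitD$q, linD$q, 0.95)
#> <gof_report> tau = 0.95  V_D = 0.116919  V_R = 0.120004  R = 0.0257
```

The empirical coverage matches the nominal levels (95% of responses fall
below the $\tau = 0.95$ curve), the two curves never cross, and
$R(0.95) > 0$ says the direct fit tracks this (nonlinear) conditional
quantile better than the linear fit.  On this draw the direct curve
follows the true quantile's rise from $\approx 1.5$ at $x = 0$ toward its
$\approx 3.7$ plateau, while the best straight line cannot bend.

A scaled study (2 minutes; drop `--scaled`-equivalent `m` back to 100 for
paper scale):

```r
report <- run_study(study_config(m = 20, n = 100, seed = 11))
cat(format_table1(report), sep = "\n")
#> tau              0.95     0.96     0.97     0.98     0.99
#> SMSE(Q_R)      28.355   35.440   70.596   52.932  184.373
#> SMSE(Q_LP)     13.076   15.103   17.832   23.131   33.608
#> SMSE(Q_D)       7.372    8.341    9.586   11.953   17.462
#> SEFF(Q_LP)     2.1686   2.3466   3.9589   2.2884   5.4859
#> SEFF(Q_D)      3.8465   4.2491   7.3643   4.4285  10.5588
```

All $\mathrm{SEFF}(Q_D) > 1$: the direct estimator beats the linear fit
at every level, and beats the local-polynomial baseline as well.

## Command line

```sh
Rscript -e 'directqr::qr_cli()' simulate --kind gumbel --n 200 --seed 7 --out pairs.csv
Rscript -e 'directqr::qr_cli()' fit --data pairs.csv --response y --covariates x \
    --tau 0.95,0.97,0.99 --method direct,linear --out curves.csv
Rscript -e 'directqr::qr_cli()' gof --data pairs.csv --response y --covariates x \
    --tau 0.95,0.99 --out gof.csv
Rscript -e 'directqr::qr_cli()' study --m 100 --n 100 --seed 7 --out study/
```

Outputs are headered CSV (provenance: version, seed, config); re-running
with the same config reproduces them byte for byte.

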