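# microdyn

Simulation, imputation and Bayesian inference of microbial community
dynamics from longitudinal data.

Microbial communities — gut microbiota, wastewater consortia, synthetic
co-cultures — are observed as time series of taxon abundances, sometimes
with parallel metabolite measurements, usually with gaps. `microdyn` is a
toolbox for the full workflow on such data:

* **Simulate** community dynamics under four model families: lag-1 vector
  autoregression (VAR), a coupled species–metabolite model (MVAR),
  generalized Lotka–Volterra ODEs (gLV) and MacArthur consumer–resource
  ODEs (CR).
* **Impute** missing observations with per-variable Gaussian-process
  regression, with uncertainty bands.
* **Infer** interaction matrices by least squares (ordinary or ridge) and
  by Bayesian MCMC with Normal, horseshoe (sparsity) and covariance
  priors, returning full posteriors with credible intervals, ESS/R-hat
  diagnostics, and AIC/BIC for model comparison.
* **Assess stability** of inferred discrete-time interaction matrices: a
  system is stable when all eigenvalues of `A` have modulus < 1, evaluated
  both for the posterior-median matrix and across all posterior samples.

The core statistical model is the VAR

```
X_t = A X_{t-1} + c + eps_t ,   eps_t ~ N(0, sigma^2)
```

whose coefficient matrix `A` encodes directed taxon–taxon influences, and
its species–metabolite extension

```
X_t = A dX_{t-1} + c_x + eps_x ,   S_t = B dX_{t-1} + c_s + eps_y
```

where `dX_{t-1} = X_{t-1} - X_{t-2}` and `B` maps abundance changes to
metabolite concentrations. See the vignette
(`vignettes/microbial-dynamics.Rmd`) for all model forms, priors and
design choices.

## Worked example: simulate, infer, assess

Simulate a 3-species community under a stable random interaction matrix
with observation noise sd 1.5 over 200 transitions, then recover the
parameters by Bayesian inference:

```r
library(microdyn)

fx <- generate_fixture("var", n_vars = 3, n_steps = 200, seed = 1,
                       noise_sd = 1.5, stability = "stable")
round(fx$params$A, 3)
#>        [,1]   [,2]  [,3]
#> [1,] -0.396  1.008 0.308
#> [2,]  0.116  0.208 0.466
#> [3,] -0.528 -0.518 0.364

post <- infer_var_bayes(fx$series, seed = 2)   # 4 chains, 1000 tune + 1000 draws
summ <- posterior_summary(post, level = 0.95)
round(summ$estimates$A, 3)
#>        [,1]   [,2]  [,3]
#> [1,] -0.398  1.015 0.281
#> [2,]  0.138  0.127 0.537
#> [3,] -0.571 -0.410 0.360

median(posterior_draws(post, "sigma"))
#> [1] 1.539587
```

The posterior-median interaction matrix sits close to the generating one
(entries within a few hundredths to a few tenths, each with a credible
interval in `summ$table`), and the noise sd is recovered at 1.54 against a
true 1.5. Stability analysis across the posterior:

```r
posterior_stability(post, "A")
#> <stability_report> 4000 posterior draws of 'A' (|eigenvalue| < 1)
#>   100.00% of sampled matrices are stable
#>   element-wise median matrix: stable (spectral radius 0.8094)
```

Every sampled matrix is inside the unit circle, matching the generator's
spectral radius of 0.8. Model comparison values for this fit:

```r
unlist(information_criteria(summ))
#>      aic      bic
#> 2240.817 2306.771
```

For gappy real-world tables the same workflow runs end to end from a YAML
config (read → GP-impute → optionally convert to relative abundances →
infer → stability report):

```r
run_pipeline("config.yaml")
```

or from the shell via the thin CLI:

```sh
microdyn pipeline --config config.yaml
microdyn impute --input series.csv --seed 1 --out imputed.csv --bands bands.csv
```

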