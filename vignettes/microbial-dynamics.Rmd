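---
title: "Models and methods for microbial community time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for microbial community time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

`microdyn` works with longitudinal abundance tables — rows are sampling
times, columns are taxa, optionally joined by metabolite columns — and
provides four things: forward simulators for common community models,
Gaussian-process imputation of missing observations, Bayesian and linear
inference of interaction matrices, and eigenvalue stability analysis of the
inferred dynamics. This vignette explains the models, the defaults, and the
design choices behind them.

## The model families

**VAR.** The lag-1 vector autoregression treats the community state
$X_t \in \mathbb{R}^n$ as a linear map of its previous value,

$$X_t = A\,X_{t-1} + c + \epsilon_t, \qquad \epsilon_t \sim N(0, \sigma^2),$$

where $A_{ij}$ captures the influence of taxon $j$ yesterday on taxon $i$
today. It is a statistical model, not a mechanistic one: it needs no growth
or uptake assumptions, handles many taxa cheaply, and can produce negative
"abundances" (a `clip_negative` option truncates at zero, off by default,
since clipping breaks the linear-Gaussian structure that inference assumes).
The intercept $c$ defaults to zero in simulation but is always estimated in
inference, where forcing it to zero would bias $A$ on non-centered data.

**MVAR.** The species–metabolite extension couples two regressions through
the lagged *change* in abundances $\Delta X_{t-1} = X_{t-1} - X_{t-2}$:

$$X_t = A\,\Delta X_{t-1} + c_x + \epsilon_x, \qquad
  S_t = B\,\Delta X_{t-1} + c_s + \epsilon_y,$$

with $S_t$ the metabolite concentrations. $A$ is the species–species
interaction matrix; $B_{kj}$ says whether growth of taxon $j$ promotes or
depletes metabolite $k$. We implement the abundance equation exactly as
written — the *level* $X_t$ regressed on the lagged difference. One can
argue the left side ought to be $\Delta X_t$ for dimensional symmetry; both
are available (`response = "level"` vs `"delta"` in `simulate_mvar()` and
`infer_mvar_bayes()`) and the as-written form is the default. We do not
silently "correct" the model, because the two variants genuinely estimate
different dynamics.

**gLV.** The generalized Lotka–Volterra ODE,
$\dot{x}_i = x_i\,(\mu_i + \sum_j M_{ij} x_j)$, with intrinsic growth rates
$\mu$ (1/time) and per-capita interactions $M$ (1/(abundance·time)).
Negative diagonal entries encode self-limitation; the single-species case
reduces to logistic growth with carrying capacity $-\mu_i / M_{ii}$.

**CR.** The MacArthur consumer–resource model with linear uptake:

$$\dot{x}_i = x_i \Big(\sum_k y_{ik}\, u_{ik} R_k - d_i\Big), \qquad
  \dot{R}_k = s_k - \delta R_k - \sum_i u_{ik}\, x_i R_k,$$

with uptake rates $u$, growth yields $y$, mortality $d$, resource supply
$s$ and dilution $\delta$. This is the simplest standard CR form; it is
deliberately modular so that users who need saturating (Monod) uptake can
substitute their own right-hand side via `simulate_glv`-style wrappers.
Only simulation is supported for CR; interaction inference is provided for
VAR, MVAR and gLV, which matches how these models are typically used on
real community data.

Time conventions: VAR/MVAR are index-based (unit lag, times $0, 1, \dots$);
gLV/CR take a real-valued, strictly increasing time grid. The two
conventions are never mixed.

## Simulation and the fixture generator

`generate_fixture()` draws random parameters and simulates from them, and
its defaults define the package's reference synthetic conditions (they are
also the conditions under which the test suite validates inference):

* VAR/MVAR interaction entries are drawn $N(0, 0.3)$ and, when a stable
  system is requested, rescaled so the spectral radius of $A$ is 0.8 —
  comfortably inside the unit circle but with visible dynamics. Unstable
  fixtures are rescaled to 1.25. Intercepts are zero and initial states
  standard normal.
* The default VAR/MVAR observation noise is Gaussian with sd 1.5, the
  noise level of the package's reference recovery experiment (3 taxa,
  200 transitions).
* gLV/CR fixtures use $N(0, 0.2)$ off-diagonal interactions with diagonal
  −1, growth rates $U(0.3, 1)$, and a 0.1 time step; their default
  measurement noise is multiplicative log-normal with sd 0.05, a small
  error chosen to represent careful densitometry rather than sequencing
  counts.

What the generator does *not* emulate: count noise (no negative-binomial
sampling layer), compositional closure (unless you apply
`to_relative_abundance()`), irregular sampling for the discrete-time
models, and measurement-device detection limits. Passing tests therefore
demonstrate correct recovery under the stated Gaussian/log-normal
observation models, not robustness to every artifact of real sequencing
data.

## Inference

### Linear

`infer_var_linear()` solves each equation of the VAR by QR least squares
(response: each variable at $t$; design: all variables at $t-1$ plus an
intercept). With full-rank designs this is the unique OLS solution, and on
zero-noise data it recovers $A$ to numerical precision. Rank-deficient
designs raise an error that points at the ridge option, which penalizes the
coefficient block (never the intercept) through the augmented-rows form.
`infer_glv()` uses gradient matching: central differences of
$\log x_i$ on the (possibly non-uniform) grid approximate the per-capita
growth rate, which is regressed on $(1, x)$. Gradient matching avoids
repeated ODE solves — it is fast and its failure modes are transparent —
at the cost of bias when sampling is sparse relative to the dynamics; it
also requires strictly positive abundances. A full ODE posterior is out of
scope.

### Bayesian

`infer_var_bayes()`, `infer_mvar_bayes()` and `infer_glv(method="bayes")`
build a hierarchical regression model and delegate sampling to JAGS
(via `rjags`), with seeds supplied per chain so every run is exactly
reproducible. Default priors, all overridable through `prior_spec()`:

| parameter | prior | default scale |
|---|---|---|
| interaction coefficients | Normal(0, `coeff_scale`²) | 1 |
| coefficients, sparse option | regularized horseshoe | `global_scale` 1, slab 2 |
| intercepts | Normal(0, `intercept_scale`²) | 5 |
| noise sds | half-Normal(`noise_scale`) | 1 |
| residual covariance (optional) | Wishart on the precision | identity scale, df $n+1$ |

The horseshoe uses half-Cauchy local and global scales with a finite slab,
so truly-zero interactions are shrunk aggressively while genuine signals
escape; it is parameterized centered, which suits Gibbs-type samplers (the
non-centered trick matters for gradient-based samplers, not here). The
covariance option places a Wishart prior on the residual precision matrix —
with identity scale and $n+1$ degrees of freedom the implied correlations
are near-uniform, playing the same regularizing role LKJ-type priors play
elsewhere. It is the default for the MVAR (where residual correlation
between taxa is the norm) and off for the VAR (independent noise keeps the
model conjugate and fast).

MCMC defaults are 4 chains, 1000 adaptation + 1000 retained iterations.
Every scalar parameter gets an effective-sample-size and $\widehat{R}$
entry in `$diagnostics`; $\widehat{R} > 1.05$ triggers a recorded warning
rather than a silent pass. `posterior_summary()` reports medians and
equal-tailed credible intervals and evaluates the model log-likelihood at
the posterior medians so `information_criteria()` (AIC $= 2k - 2\ln L$,
BIC $= k\ln n - 2\ln L$, with $n$ the number of modeled scalar
observations) can compare model families on the same data.

Missing data are never dropped silently: every estimator refuses masked
entries and directs you to `impute()`. Relative-abundance mode
(`relative = TRUE`, or `to_relative_abundance()` directly) renormalizes
each row's taxa to proportions first and stamps the output with a
non-identifiability caveat — compositional data cannot pin down absolute
interaction scales.

## Gaussian-process imputation

Each variable gets an independent GP over time (squared-exponential kernel
by default, Matérn-3/2 available), with prior mean equal to the variable's
observed average. Hyperparameters — lengthscale, signal variance, noise
variance — maximize the log marginal likelihood via L-BFGS-B from the
default start plus 5 seeded random restarts; the returned fit is never
worse than its starting point. Any subset of hyperparameters can be pinned
with `fixed`, which is how the tests compare against closed-form posteriors
and how users can impose a known noise floor. `gp_predict()` returns the
standard posterior mean and variance with equal-tailed Gaussian bands
(default level 0.95; `include_noise = TRUE` widens bands to cover new noisy
observations rather than the latent curve). `impute()` replaces exactly the
masked entries with posterior means, leaves observed values bit-identical,
and records per-entry provenance. Independent-per-variable fitting mirrors
per-taxon trajectory smoothing; it ignores cross-taxon correlation, which a
multi-output GP could exploit — a documented limitation, not an oversight.
An optional `log1p` transform is available for strictly non-negative data
but is off by default, since back-transformed bands are only approximate.

Numerical details: kernel matrices get a jitter of $10^{-10}$ (plus a
relative term) before Cholesky factorization; predictive variances are
clamped at zero; optimizer bounds keep lengthscales within
$[10^{-3}, 10^{2}] \times$ the observed time span so the marginal-likelihood
surface cannot collapse into degenerate spikes.

## Stability analysis

For a discrete-time interaction matrix, `stability_eigen()` computes the
full complex spectrum and calls the system stable when every eigenvalue has
modulus strictly below 1 — modulus exactly 1 counts as unstable, keeping
the criterion a strict inequality. `posterior_stability()` applies this
per posterior draw (chains pooled) and reports the percentage of stable
draws, alongside an *independent* classification of the element-wise
posterior-median matrix. The element-wise median is a construction choice:
it is the natural entrywise point estimate, but its spectrum is not any
kind of average of the per-draw spectra, so a stable median with, say, 85%
stable draws is a coherent (and informative) outcome — it localizes the
uncertainty in specific interactions.

## The pipeline and reproducibility

`run_pipeline()` chains read → impute → (optional relative-abundance
normalization) → Bayesian inference → posterior summary → stability report,
writing every artifact plus a provenance record (config hash, all seeds,
package and R versions). Configs are YAML with unknown keys rejected, and a
seed is mandatory — a config without one is an error, never a silent random
draw. All file writes are write-then-rename, so an interrupted run cannot
leave a truncated CSV or JSON behind. The same workflow is scriptable from
the shell through the `microdyn` executable (verbs `simulate`, `impute`,
`infer`, `stability`, `pipeline`).

## Problem sizes and what the tests establish

The validation suite exercises the package at deliberately modest sizes
chosen to make each property sharply testable: exact-recovery and oracle
checks on 2–3 taxa with 20–30 timepoints; Bayesian recovery at 3 taxa ×
200 transitions (noise sd 1.5, the reference conditions above); interval
calibration across 20 simulated replicates at noise sd 0.5; GP band
coverage over 200 held-out points from known-kernel draws; and
stability–dynamics agreement across 50 random matrices on both sides of
the unit circle. Larger communities are a matter of runtime, not of code
paths — the samplers scale as ordinary multivariate regressions.

## Known limitations

* Lag-1 models only; no higher-order VAR, no stochastic differential
  equations, no spatial structure.
* CR inference is not provided (simulation only).
* gLV inference is linearized (gradient matching), with the bias/speed
  trade-off described above.
* The GP treats variables independently and Gaussianly; counts near zero
  and detection limits violate both.
* Relative-abundance inference is supported but intrinsically
  scale-non-identifiable; interpret such interaction matrices with care.
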