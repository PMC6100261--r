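# insilico

Construction of *in-silico data sets*: model-calculated time series with
realistic, artificially superposed measurement error, plus the machinery to
use them in parameter-recovery studies.

Procedures for interpreting experimental time series (parameter estimation,
trend detection, model discrimination) are routinely tested on artificial
data. Real measurement errors are rarely independent from one sample to the
next: a drifting baseline or a slow sensor gives the error a *memory*, so a
positive error now makes a positive error at the next sampling instant more
likely. `insilico` generates exactly this kind of error — zero-mean,
normally distributed, with exponentially decaying correlation
(a Gauss–Markov process, the continuous-time analogue of an AR(1) process) —
and superposes it on any equispaced multi-column series.

The package ships a complete worked system to exercise the method end to
end: a semi-batch transesterification reactor model (biodiesel chemistry),
a nonlinear least-squares estimator for its six rate constants, and a
Monte-Carlo study engine that tabulates estimator mean ± spread per error
level.

## The error model

Measurements on an equispaced grid `t_i = t_0 + (i-1)·Δt` are

```
M_i = p_i + X_i
```

where `p_i` is the ideal (model-calculated) value and the errors `X_i` are
jointly normal, zero mean, with

```
Var(X_i)      = σ²(p_i)            (relative law: σ(p) = ε·|p|)
Corr(X_i,X_j) = exp(−|t_j − t_i|/τ)
```

with correlation time `τ`. On the sampling grid this gives a lag-one
coefficient `ρ = exp(−Δt/τ)`, and the chain is generated sequentially from
the conditional law

```
X_1 ~ N(0, σ₁²),    X_i | X_{i−1} = x ~ N(ρ·(σ_i/σ_{i−1})·x, (1−ρ²)·σ_i²)
```

## The kinetic test system

Stepwise methanolysis of a triglyceride in a perfectly mixed, constant
volume, isothermal semi-batch reactor (methanol feed, equal in/outflow set
by the residence time `τ_res`):

```
TG + MeOH <-> DG + E1   (k1, k2)
DG + MeOH <-> MG + E2   (k3, k4)        dC_j/dt = R_j(C,k) + (C_j,feed − C_j)/τ_res
MG + MeOH <-> GL + E3   (k5, k6)
```

Defaults: `k = (0.049, 0.109, 0.211, 1.213, 2.407, 0.069)`,
`C_TG,0 = 1 M`, `C_MeOH,0 = 0.023 M`, residence times 200/500/1000/2000 s,
`Δt = 30 s`, `τ = 30 s`, relative error levels 0–10%.

## Worked example

```r
library(insilico)

truth <- default_rate_constants()
conds <- default_conditions()                      # 4 residence times
ideal <- lapply(conds, simulate_reactor, k = truth)

# corrupt with 1% relative Gauss-Markov error and refit the constants
noisy <- lapply(ideal, superpose_error, spec = noise_spec(0.01, tau = 30), seed = 1)
exps  <- experiment_set(mapply(experiment, conds, noisy, SIMPLIFY = FALSE))
fit   <- fit_rate_constants(exps, init = truth)
fit
#> <isd_fit_result> converged after 4 iterations (start 1)
#>        k1        k2        k3        k4        k5        k6
#> 0.0489749 0.1088730 0.2110830 1.2127100 2.4120400 0.0692013
#>   ssq = 0.27402
```

The fitted vector sits within a fraction of a percent of the generating
constants: 1% correlated noise on all eight species barely disturbs the
estimate when all four experiments are fitted jointly. A replicate study
quantifies that spread:

```r
cfg <- study_config(error_levels = c(0, 0.01), n_replicates = 100)
run_recovery_study(cfg)
#> <isd_study_table> mean +/- sd of fitted rate constants
#>       0%  k1: 0.049  k2: 0.109  k3: 0.211  k4: 1.213  k5: 2.407  k6: 0.069  (n = 100)
#>       1%  k1: 0.04899 +/- 0.0001  k2: 0.1089 +/- 0.00038  k3: 0.211 +/- 0.00037  k4: 1.214 +/- 0.0069  k5: 2.407 +/- 0.0081  k6: 0.06901 +/- 0.0018  (n = 100)
```

A command-line interface wraps the same functions
(`inst/scripts/insilico simulate|corrupt|fit|study|plot`), configured by a
single YAML file (`inst/extdata/example_config.yaml`).

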