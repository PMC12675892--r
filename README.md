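# dctitp

Bayesian longitudinal dose-response modelling for hybrid decentralized
clinical trials.

## The problem

Hybrid decentralized trials (DCTs) collect a longitudinal endpoint —
here, weight change from baseline in a phase II multidose trial — both
*onsite* (supervised, at the clinical site) and *offsite*
(decentralized: at home or locally). Offsite measurement can shift the
apparent dose-response and inflate variability. Pooling both sources
naively biases the estimate; using only the sparse onsite visits wastes
information. `dctitp` implements the DCT-ITP model, which integrates
the two sources adaptively.

The longitudinal mean is the product of an exponential-decay time
effect and an Emax terminal dose effect, each with decentralized
shifts:

    mu(l, d, I) = kappa(l, d, I) * lambda(d, I)

    kappa(l, d, I) = (1 - exp(-[k(d) + I z(d)] t_l)) /
                     (1 - exp(-[k(d) + I z(d)] t_L))

    lambda(d, I) = (phi0 + I delta0) +
                   (phi1 + I delta1) m_d / ((phi2 + I delta2) + m_d)

    Y_jl = mu(l, d_j, I_l)
           + mu(l, d_j, I_l) / mu(L, d_j, I_l) * (s_j + I_l s*_j)
           + e_jl + I_l e*_jl

where `I_l = 1` marks a decentralized visit, `s`/`e` are
between/within-subject normal components and the starred components
load only on decentralized measurements. The decentralization shifts
`z(d)` and `delta0..delta2` carry spike-and-slab priors (a horseshoe
alternative is included), so the posterior decides from the data
whether the offsite measurements can be pooled or must be corrected;
missing outcomes are handled by Bayesian data augmentation inside the
MCMC (JAGS via `rjags`). The package also ships the decentralized-trial
simulator (visit jitter, onsite/offsite schedules, outcome-dependent
dropout and intermittent missingness), the comparator fits (onsite-only
O-ITP, pooled M-ITP, traditional T-ITP), the clinical estimands (AUC,
terminal response, and their placebo-subtracted contrasts), and the
simulation metrics (dose-averaged bias, RMSE, coverage, interval
length).

## Worked example

Simulate the motivating configuration — decentralized measurements
biased by 2 kg at the maximum dose with inflated variability — and fit
the full model and the naive pooled analysis:

```r
library(dctitp)

spec <- scenario_registry()[["3"]]      # biased decentralized source
dat  <- simulate_trial(spec, seed = 1)  # 120 subjects, ~20% missing

mc  <- mcmc_config(n_burnin = 1000, n_iter = 2000, thin = 2, seed = 42)
fit <- fit_itp(dat, mcmc = mc, variant = "dct")
fit
```

```
DCT-ITP fit (variant 'dct'): 1000 draws x 26 parameters, 118 subjects
  phi0: mean -2.859 [-5.297, -0.401]
  phi1: mean -30.089 [-37.447, -23.870]
  phi2: mean 6.020 [2.384, 11.268]
  inclusion probabilities: w_kappa=0.05, w0=0.31, w1=0.48, w2=0.36
  265 missing outcomes imputed by data augmentation
```

The Emax posterior brackets the generating values
(`phi0 = -2.5`, `phi1 = -30`, `phi2 = 5`), and the shared rate-shift
indicator `w_kappa` has collapsed from its 0.5 prior to 0.05: the
generating scenario has no rate shift, and the model pools the
time-effect information across sources accordingly. The terminal
dose-response estimand (on the centralized curve, the basis of the
estimand) and its truth:

```r
est <- summarize_estimands(estimand_draws(fit, "mu", dose_grid = c(0, 5, 15)))
cbind(est, truth = true_estimand(spec, "mu", dose_grid = c(0, 5, 15)))
```

```
   dose       mean      lower       upper truth
0     0  -2.858874  -5.297317  -0.4011409  -2.5
5     5 -16.829564 -19.333759 -14.4249249 -17.5
15   15 -24.376462 -27.097129 -21.5559461 -25.0
```

Each 95% credible interval covers the generating truth. A naive pooled
fit (`variant = "m"`) of the same data estimates
`mu_15 = -23.27 [-25.64, -20.82]`, centred 1.7 kg above the truth —
the decentralized attenuation it absorbs by ignoring the measurement
source. Averaged over replications (see the acceptance tests), the
pooled analysis carries that bias while the adaptive model does not.

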