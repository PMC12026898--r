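# ficsurr

Whole-brain biophysical circuit modelling is built around a loop that is
expensive by construction: propose model parameters, numerically integrate a
stochastic mean-field model over a structural connectome, convert the neural
activity to BOLD, and score the simulated scan against empirical functional
connectivity. `ficsurr` implements that whole loop for the
feedback-inhibition-control (FIC) dynamic mean-field model — and then removes
the integrator from the inner loop by training deep surrogate networks that
predict, directly from the parameters, (i) whether a candidate produces
physiologically plausible firing rates and (ii) what its realism cost would
be. The package is aimed at computational neuroscientists fitting mean-field
models to parcellated resting-state fMRI, and at anyone studying
surrogate-assisted evolutionary optimization of stochastic simulators.

## The model and cost in brief

Each region holds coupled excitatory/inhibitory gating variables
(reduced Wong-Wang dynamics),

> dS_E/dt = −S_E/τ_E + (1 − S_E) γ r_E(I_E) + σ ξ(t),
> dS_I/dt = −S_I/τ_I + r_I(I_I) + σ ξ(t),

with inter-regional input G · J_NMDA · Σ_j SC_kj S_E,j entering only the
excitatory current. The FIC property: the inhibitory-to-excitatory weights
w_IE are calibrated so every region's noiseless firing rate sits at ~3 Hz;
simulated candidates whose stochastic rates leave the 2.7–3.3 Hz band are
"out of range" and discarded. Spatial heterogeneity is affine in K covariate
maps — w_EE, w_EI and σ each get an intercept and K slopes, which together
with the global coupling G gives the 10-dimensional coefficient vector
(K = 2) that CMA-ES optimizes.

Realism of a within-range candidate against an empirical target is

> cost = (1 − r) + d + KS,

where r is the Pearson correlation between vectorized FC matrices, d the
absolute difference of mean FC, and KS the Kolmogorov–Smirnov distance
between the entry distributions of the functional-connectivity-dynamics
(FCD) matrices (sliding-window FC correlated window-against-window).

The surrogate component consists of a within-range classifier and an FC+FCD
cost predictor, both built on an embedding-addition architecture: parameter,
SC, FC and FCD inputs pass through separate MLPs to a common latent width
and are summed before the prediction heads. Details, defaults and the
synthetic study conditions are in the methods vignette
(`vignettes/ficsurr-methods.Rmd`).

## Worked example

```r
library(ficsurr)

spec <- synthetic_spec(n_regions = 5, seed = 1)   # synthetic study fixture
conn <- make_connectome(spec)

params <- expand_coefficients(spec$theta, conn)   # 10 coefficients -> fields
params <- calibrate_fic(params, conn)             # FIC: tune w_IE to 3 Hz
params
#> <fic_parameters> N=5, G=0.600, calibrated
#>   w_EE 0.195..0.237  w_EI 0.143..0.163  sigma 0.00544..0.00704  w_IE 1.17..1.74

traj <- integrate_neural(params, conn, duration_s = 60, burn_in_s = 20, seed = 2)
round(mean_firing_rates(traj), 2)
#> [1] 3.01 3.01 3.01 3.01 3.01                    # inside the 2.7-3.3 Hz gate
round(compute_ei_ratio(traj)$cortical_mean, 3)
#> [1] 4.15                                        # mean S_E / S_I ratio

bold <- neural_to_bold(traj, tr_s = 0.72)
fc   <- compute_fc(bold)
fcd  <- compute_fcd(bold, window_len_from_seconds(30, 0.72))

target <- make_empirical_target(spec, conn, micro_config())
realism_cost(fc, target$fc, fcd, target$fcd)
#> <realism_cost> (1-r)=0.0145  d=0.0608  KS=0.2670  total=0.3423
```

The calibrated model sits exactly in the physiological band; the short
60 s scan scores a total cost of 0.34 against the longer reference target —
mostly KS, i.e. finite-sample mismatch of the FCD entry distributions, which
is the expected noise floor behaviour for scans this short.

Fitting and surrogates follow the same grammar:

```r
fit <- fic_fit(conn, target, evaluator = "euler", epochs = 5, restarts = 3,
               seed = 1, config = micro_config(lambda = 24, mu = 6))
glance(fit)            # evaluations, within-range fraction, test cost
tidy(fit)              # one row per collated candidate
autoplot(fit)          # best cost per epoch

td  <- generate_training_data(make_triplets(8, seed = 5, config = micro_config()),
                              epochs = 2, lambda = 40, seed = 21,
                              config = micro_config())
mod <- train_surrogates(td, split = list(train = 1:6, val = 7:8))
fit_s <- fic_fit(conn, target, evaluator = "surrogate", models = mod,
                 epochs = 5, restarts = 3, seed = 1,
                 config = micro_config(lambda = 24, mu = 6))
```

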