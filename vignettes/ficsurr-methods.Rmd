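---
title: "Model, cost and surrogate methodology in ficsurr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, cost and surrogate methodology in ficsurr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ficsurr` simulates whole-brain resting-state activity with the
feedback-inhibition-control (FIC) variant of the reduced Wong-Wang dynamic
mean-field model. Each cortical region holds one excitatory and one
inhibitory population, described by synaptic gating variables $S_E, S_I \in
[0,1]$ (the fraction of open channels). Region $k$ receives the currents

$$I_E^{(k)} = W_E I_0 + w_{EE}^{(k)} S_E^{(k)}
  + G\, J_{NMDA} \sum_j SC_{kj} S_E^{(j)} - w_{IE}^{(k)} S_I^{(k)},$$
$$I_I^{(k)} = W_I I_0 + w_{EI}^{(k)} S_E^{(k)} - w_{II} S_I^{(k)},$$

which drive population rates through the sigmoidal transfer function
$r(I) = (aI - b)\,/\,(1 - e^{-d(aI-b)})$ with separate $(a, b, d)$ for the
two populations. The gating dynamics are

$$\dot S_E = -S_E/\tau_E + (1 - S_E)\,\gamma\, r_E + \sigma\,\xi(t), \qquad
  \dot S_I = -S_I/\tau_I + r_I + \sigma\,\xi(t).$$

Regions are coupled only through their excitatory populations, via the
structural connectivity (SC) matrix scaled by the global coupling constant
$G$. The fixed constants (Deco-2014 values: $a_E = 310$ nC$^{-1}$,
$b_E = 125$ Hz, $d_E = 0.16$ s, $a_I = 615$, $b_I = 177$, $d_I = 0.087$,
$\tau_E = 0.1$ s, $\tau_I = 0.01$ s, $\gamma = 0.641$,
$J_{NMDA} = 0.15$ nA, $I_0 = 0.382$ nA, $W_E = 1$, $W_I = 0.7$,
$w_{II} = 1$) live in a versioned YAML file
(`inst/extdata/fic_constants.yaml`), so an alternative transcription of the
reduction can be swapped in without touching code. The local weights
$w_{EE}, w_{EI}, w_{IE}$ are expressed in nA per unit gating (the local
NMDA scaling is absorbed into them); the long-range term keeps the explicit
$G\,J_{NMDA}$ factor.

## Heterogeneous parameterization

Three fields are spatially heterogeneous: $w_{EE}$, $w_{EI}$ and the noise
amplitude $\sigma$. Each is an affine function of $K$ spatial covariate
maps, $w^{(k)} = a + \sum_{m} b_m\, c_m^{(k)}$, giving $3(K+1) + 1$ free
coefficients including $G$ — with the default $K = 2$ maps, a
10-dimensional search space. Expanded per-region values are clamped to
$[10^{-4}, 10]$ and $G$ to $[0, 10]$, because the evolution-strategy
proposals are unbounded Gaussians; a candidate whose entire field is
clamped is flagged as degenerate.

## Feedback inhibition control

$w_{IE}$ is not optimized. `calibrate_fic()` tunes it per region so that
the noiseless temporal-mean excitatory rate sits at the physiological
target (3 Hz): it initializes $w_{IE}$ from the analytic current balance at
the homogeneous 3 Hz operating point, then applies damped fixed-point
sweeps ($w_{IE} \leftarrow w_{IE} + \eta\,(\bar r_E - r^\*)$, default
$\eta = 0.05$ nA·s, 2 s noiseless sweeps, tolerance 0.05 Hz, at most 200
sweeps). Because a short sweep can sit on an *unstable* operating point
without leaving it, convergence is only declared after a 12 s confirmation
integration also holds the target; systems that feedback inhibition cannot
stabilize (strong recurrence plus strong coupling) raise a typed
calibration error, which the optimizer treats as an out-of-range candidate.
The scheme is deliberately replaceable: it is a plain iterative root find
on the rate residual.

## Hemodynamics and the physiological gate

BOLD is generated by a classical Balloon-Windkessel model per region
(vasodilatory signal, inflow, venous volume, deoxyhemoglobin;
Friston-2003 constants in `inst/extdata/hemo_constants.yaml`), driven by
$S_E$ and Euler-integrated at the neural step, then read out through
$y = 100\,V_0\,(k_1(1-q) + k_2(1 - q/v) + k_3(1 - v))$ and decimated to one
frame per TR. Hemodynamics are regionally local and deterministic given the
neural trajectory. The neural burn-in is discarded; no additional BOLD
frames are dropped.

A candidate parameter set is *within range* when its simulated excitatory
rates stay physiologically plausible: by default every region's
post-burn-in temporal-mean rate must lie in [2.7, 3.3] Hz. The aggregation
rule is configurable (`range_rule = "mean"` gates on the across-region mean
instead); the all-region rule is the conservative reading and the default.

# The realism cost

Model realism against an empirical target is scored with three components,
all computed on strictly-upper-triangular entries in fixed row-major order:

* `corr_cost` $= 1 - r$, with $r$ the Pearson correlation between the
  vectorized simulated and empirical FC matrices;
* `mean_abs_diff` $= d = |\overline{FC}_{emp} - \overline{FC}_{sim}|$,
  which penalizes globally over- or under-synchronized signals that $r$
  cannot see;
* `ks_cost`, the Kolmogorov-Smirnov distance between the distributions of
  simulated and empirical FCD entries (sliding-window FC vectors correlated
  window-against-window, stride one frame).

The total cost is $(1 - r) + d + KS$; lower is more realistic. The diagonal
is excluded everywhere (it is constant 1 and would dilute $d$). The KS cost
compares pooled FCD entry distributions — the standard construction — not
row or column summaries; when several runs form a group target, FC is
averaged entry-wise after Fisher z-transform and FCD entries are pooled
(both conventions configurable at the call site).

# Fitting: CMA-ES with pluggable evaluators

`fic_fit()` minimizes the total cost over the coefficient vector with a
standard Hansen-style covariance matrix adaptation evolution strategy
(rank-one plus rank-$\mu$ covariance updates, log-decreasing parent
weights, cumulative step-size adaptation). Each epoch samples $\lambda$
children (reference schedule: $\lambda = 100$, top $\mu = 10$), scores them
with the chosen evaluator, and updates the distribution from the best
$\mu$. Out-of-range children receive infinite cost; if fewer than $\mu$
children are valid the update uses all valid ones with renormalized
weights, and a fully invalid epoch keeps the distribution and shrinks the
step size by 0.7. The search mean is initialized uniformly inside the
documented coefficient box and the initial per-coordinate scale is 0.3 of
each box range.

Evaluators are interchangeable:

* `"euler"` runs the full pipeline — expand, calibrate, integrate
  (Euler-Maruyama, 6 ms step), gate, BOLD, FC/FCD, cost;
* `"surrogate"` replaces integration with the trained networks (below);
* `"counting"` scores an analytic objective, exercising the exact
  bookkeeping of a schedule without integration.

The best valid child of each epoch is collated as a candidate
(`restarts` independent initializations accumulate candidates). Validation
and test phases are always integrator-backed, whichever evaluator drove
training: candidates are re-scored on a validation target, the argmin is
selected, and that candidate is scored once on a test target.

# The surrogate networks

Two networks predict, directly from parameters, what the integrator would
conclude:

* the **within-range classifier** maps (coefficients, SC) to the
  probability that the gate passes;
* the **cost predictor** maps (coefficients, SC, empirical FC, empirical
  FCD) to the three cost components, and is trained and evaluated only on
  within-range samples.

Both use an embedding-addition architecture: each input passes through its
own MLP to a shared latent width $H$, embeddings are summed into a model
embedding, and a head MLP makes the prediction. In the predictor the
FC embedding is added to the model embedding for the $(1-r, d)$ head, and
the FCD embedding for the $KS$ head. Inputs are the coefficient vector, the
SC upper triangle, the empirical-FC upper triangle, and the empirical FCD
summarized as the 100-quantile vector of its upper-triangular entries (a
fixed-length, scale-free description matched to how the KS cost consumes
the FCD; the featurization is a documented swap point).

Training data come from `generate_training_data()`: integrator-backed
CMA-ES runs on (SC, FC, FCD) triplets, every sampled child logged with its
gate label and (when within range) its ground-truth costs. Splits are by
triplet, never by row, so no empirical target contributes to both training
and validation. Features are z-scored with statistics frozen from the
training split and stored inside the model object. Losses are binary
cross-entropy (classifier) and summed squared error over the three heads
(predictor); head outputs pass through softplus, so cost predictions are
non-negative. Because the three components differ in scale by an order of
magnitude, targets are divided by their training means before the loss and
multiplied back at prediction time. Optimization is Adam with minibatches,
L2 weight decay on the weight matrices, learning-rate halving when the
validation loss plateaus, and early stopping; micro-scale defaults are
$H = 128$, two hidden layers per block, learning rate $10^{-3}$, batch 64,
weight decay $10^{-2}$, patience 60 epochs. These were selected on the
validation triplets only.

# Synthetic study conditions

The package ships a synthetic fixture generator in place of cohort data.
It emulates three properties of tractography-derived inputs: (i) SC
weights decay exponentially with distance between regions (points on a
unit sphere, geodesic metric) and carry log-normal multiplicative noise,
spanning roughly three orders of magnitude; (ii) covariate maps are
spatially smooth fields (kernel-smoothed Gaussian noise, z-scored);
(iii) "empirical" targets are produced by the simulator itself under known
ground-truth coefficients, so fitting them is a recovery experiment with a
known answer. Triplets for surrogate training are cohort-like: they share
the spatial layout and covariate maps and resample connection weights and
ground truth, mimicking bootstrapped participant groups from one dataset.
What the generator does *not* emulate: measurement noise in BOLD, head
motion and scanner artifacts, subcortical structures, conduction delays,
and the empirical mismatch between a biophysical model and real brains —
with a self-generated target the model family is correct by construction.
Passing tests therefore demonstrate the machinery (simulation, costs,
optimization, surrogate learning), not clinical realism.

The micro benchmark conditions, fixed once and used by the test suite and
the acceptance script alike: $N = 5$ regions, $K = 2$ maps, 6 ms Euler
step, TR 0.72 s, 259.2 s scans (360 frames), 30 s FCD window (41 TRs),
20 s burn-in (the production default is 60 s). The scan length was chosen
so that the finite-sample cost floor — the total cost between two
realizations of the *same* coefficients — stays below 0.5; that floor is
the attainable bound in recovery experiments. Ground-truth coefficients
for targets are drawn from the interior regime where calibration reliably
converges ($w_{EE,0} \in [0.12, 0.35]$, $w_{EI,0} \in [0.08, 0.25]$,
$\sigma_0 \in [0.003, 0.012]$, $G \in [0.2, 1.2]$); the *search* box is
deliberately wider ($w_{EE,0}$ up to 0.6, $\sigma_0$ up to 0.05, $G$ up to
3), so the sampled population genuinely spans stable and unstable, quiet
and noisy regimes and the within-range gate has a non-degenerate base
rate. The surrogate corpus uses 72 triplets (52 train / 12 validation / 8
test) with 2 CMA-ES epochs of 40 children each: at a fixed simulation
budget, many diverse targets generalize better across targets than few
deep runs.

## Protocol choices at micro scale

Two choices depart from what one would do with hour-long cohort scans,
both forced by finite-sample noise and both configurable:

* **Restarts.** Model-inversion fits use 3 random restarts of 5 epochs
  with $\lambda = 24$ rather than one long run: a uniformly drawn starting
  mean occasionally lands where no child passes the gate, and repeated
  short runs from fresh initializations are the standard remedy for
  evolution strategies on gated, noisy objectives.
* **Averaged selection.** Validation and test scores average 3 integrator
  realizations per candidate (`n_eval_seeds = 3`). With 360-frame scans a
  single-realization argmin exploits evaluation noise; averaging makes the
  selection comparable between surrogate-driven and integrator-driven arms.

# Numerical choices

* Transfer function: the removable singularity at $aI = b$ is evaluated as
  its limit $1/d$ (guard at $|aI-b| < 10^{-9}$).
* Gating is clamped to $[0,1]$ after every Euler-Maruyama step; noise is
  drawn in fixed region-major order (excitatory block then inhibitory
  block per step) from an explicitly seeded xoshiro256++ generator with
  Box-Muller normals, so a trajectory is a bit-exact function of
  (parameters, connectome, seed) and the region count is part of the
  reproducibility contract.
* The fused scan path (`simulate_scan()`) advances neural and hemodynamic
  states in one pass and is step-for-step identical to
  `integrate_neural()` followed by `neural_to_bold()`; the equality is
  asserted in the test suite.
* FCD windows are computed from rolling sums of centered series; this is
  algebraically the per-window Pearson correlation and agrees with the
  brute-force construction to ~1e-15.
* KS distance evaluates both ECDFs at the pooled sample points, which is
  the exact supremum for step functions.
* Ties in candidate ranking are broken by child index (stable order);
  derived seeds keep every stream below $2^{31}$.
* Calibration declares success only after the 12 s confirmation horizon
  (see above); its failure is a typed condition carrying per-region rate
  residuals.

# Known limitations

* The spatial covariate maps are synthetic smooth fields, not measured
  gradients; with real maps the plausible coefficient ranges would need
  re-examination.
* The surrogate networks are trained per connectome-size: feature
  dimensions are tied to $N$, so models do not transfer across
  parcellations without retraining.
* At micro scale the cost landscape is noise-dominated near its floor;
  recovered coefficients match the target's dynamics, not necessarily the
  exact generating coefficients (the problem is only weakly identifiable
  at $N = 5$).
* No delays, no subcortex, no regional heterogeneity of the hemodynamic
  model.
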