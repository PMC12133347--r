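---
title: "Bayesian inversion of an ERP neural mass model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian inversion of an ERP neural mass model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdcm)
```

## The forward model

`erpdcm` implements dynamic causal modelling of event-related potentials
(ERPs) for a single cortical source described by three coupled neural
populations: spiny-stellate cells (state $x_1$), which receive the exogenous
input; inhibitory interneurons ($x_7$); and pyramidal cells ($x_9$), whose
membrane voltage is the only observable. Each synaptic connection is a
critically damped second-order filter,
$\ddot v = \frac{H}{\tau} S(\cdot) - \frac{2}{\tau}\dot v - \frac{v}{\tau^2}$,
with maximum postsynaptic amplitude $H$ (mV) and rate constant $\tau$ (ms),
excitatory ($h_e, \tau_e$) or inhibitory ($h_i, \tau_i$). Population output
is converted to firing-rate drive by the saturating sigmoid
$S(v) = 1/(1+e^{-0.56 v}) - 0.5$, an odd function with range $(-0.5, 0.5)$.
Effective connectivity between populations is carried by four dimensionless
gains: $g_1$ (pyramidal $\to$ stellate), $g_2$ (stellate $\to$ pyramidal),
$g_3$ (pyramidal $\to$ inhibitory) and $g_4$ (inhibitory $\to$ pyramidal).
The stimulus is a Heaviside step of intensity $u$ entering the stellate
population, active from $t = 0$ over the whole window.

Synaptic transmission latency is modelled by an intrinsic delay $\delta$
(ms) acting on the membrane potentials inside the sigmoids. Rather than
solving delay differential equations, the delayed values are replaced by the
first-order surrogate $x(t-\delta) \approx x(t) - \delta \dot x(t)$. The
three delayed states have derivative states of their own
($\dot x_1 = x_4$, $\dot x_7 = x_8$, $\dot x_9 = x_5 - x_6$), so the
substitution is closed-form and the system remains an ordinary 9-state ODE.
All parameter units assume milliseconds for time constants and the delay,
consistent with the 0.1 ms integration step; the sources that introduced
this parametrization do not state units explicitly, so this is a documented
assumption.

Integration is forward Euler with a configurable step, `dt = 0.1` ms by
default, over a 200 ms window (2001 samples). Euler is deliberate: the
evaluation is cheap, exactly reproducible, and differentiable step by step,
which the gradient-based engines require. First-order convergence is
verified in the test suite by step-halving. The initial condition is the
origin, which is the exact equilibrium of the input-free system.

## Synthetic observations

`generate_observation()` integrates the model at the generative parameter
values, adds i.i.d. zero-mean Gaussian noise with sd `sigma_obs = 0.1` to
all 2001 pyramidal-voltage samples, and keeps every 10th sample starting at
index 0, yielding 201 observation points. Noise is added *before*
downsampling. The per-call seed is recorded in the object and in the CSV
header comment, and generation restores the caller's RNG state.

## Stability structure of the model

Two distinct notions of "unstable" matter here, and the package exposes
both:

* **Trajectory blow-up** (`classify_stability`): any non-finite state or
  $|x| > 10^3$. During inference such draws map to log-density $-\infty$,
  so samplers reject them instead of crashing. For this particular model
  with positive parameters, however, genuine blow-up cannot occur: the
  sigmoids saturate, every synaptic block is a damped linear filter with
  bounded drive, and the combination $x_9 - x_2 + x_3$ is conserved (which
  also means the Jacobian always carries one structural zero eigenvalue and
  equilibria form a line, parametrized by the conserved value).
* **Dynamical instability** (`classify_dynamics`): the stimulus-driven
  equilibrium loses linear stability and the evoked response rings
  indefinitely on a limit cycle instead of settling. This is the relevant
  sense in which a sizeable fraction of the prior mass is "unstable". The
  classifier integrates 1500 ms and (i) flags blow-up, (ii) if the late
  response has settled (peak-to-peak $x_9$ range below $10^{-3}$ over the
  final third), classifies by the Jacobian eigenvalues at the terminal
  state (unstable iff some real part exceeds $10^{-6}$/ms, a strict
  threshold that ignores the structural zero), and (iii) otherwise flags
  non-decaying oscillation (late-window range at least 0.8 of the
  middle-window range). The horizon is several times the slowest decay
  observed at the generative parameters; the thresholds are on the scale of
  the conserved dynamics and were fixed once, on dynamical-systems grounds.
  Under the default priors roughly a quarter of draws are dynamically
  unstable by this intrinsic criterion (an eigenvalue analysis at the
  exactly solved equilibrium gives the same rate); folklore figures closer
  to one half trace back to stiffer delay discretizations of the same
  model, which can genuinely diverge.

## Priors and likelihood

Independent Gamma priors (shape/scale parametrization) are placed on all
ten parameters; the defaults are the weakly informative set whose means sit
at the scale of the generative values. The likelihood is Gaussian with
fixed sd 0.1 — the generative value; the noise level is not inferred, since
the study design treats it as part of the measurement model. Inference
operates on $\zeta = \log\theta$ with the exact Jacobian correction; a
reduced model fixes a connectivity gain at exactly 0 and removes it from
the sampled vector entirely, so the unconstrained dimension drops by one.

Chain initialization offers three strategies: `random` (a prior draw),
`prior_tails` (each coordinate drawn uniformly from the union of the lower
and upper 2.5% prior tails, i.e. outside the central 95% interval, with
quantile levels clamped to $[10^{-6}, 1-10^{-6}]$), and explicit values.
Initializations with non-finite log density are redrawn. Tail
initialization is the recommended remedy for the multi-modality this
posterior exhibits under random starts.

## Inference engines

All engines consume the same differentiable unconstrained log joint, whose
gradient is computed by forward sensitivity analysis: the sensitivity
matrix $S = \partial x / \partial\theta$ is propagated through the Euler
recursion alongside the states in compiled code, exploiting the sparsity of
the state Jacobian. The analytic gradient is verified against central
finite differences to relative $10^{-3}$ in the tests (it agrees to
$\sim 10^{-8}$ in practice).

* **NUTS** (`run_nuts`): the self-tuning trajectory-doubling variant of
  Hamiltonian Monte Carlo with slice sampling across the implicit tree,
  dual-averaging step-size adaptation toward a target acceptance (default
  0.8), a diagonal mass matrix re-estimated at 50% and 80% of warmup, and a
  maximum tree depth (default 10, i.e. at most $2^{10}$ leapfrog steps).
  Divergences are flagged when the energy error exceeds 1000. Defaults are
  four chains with 200 warmup and 200 kept iterations.
* **ADVI** (`run_advi`): stochastic gradient ascent on the ELBO with the
  reparametrization trick and Adam (learning rate $5\times10^{-4}$, one
  ELBO sample per iteration, $10^5$ iterations by default — reading the
  stated iteration budget as $10^5$; all budgets configurable). Guides are
  Gaussian in unconstrained space: mean-field (diagonal) or full-rank
  (dense Cholesky). Draws from the fitted guide are packaged exactly like
  MCMC draws so every diagnostic applies uniformly. An optional plateau
  criterion (relative ELBO change $<10^{-8}$ over 5000 iterations) is off
  by default to mirror the fixed-budget design.
* **Laplace** (`run_laplace`): MAP by BFGS with analytic gradients,
  restarted from eight prior-tail draws; Hessian by central finite
  differences of the analytic gradient; Gaussian posterior with covariance
  $(-H)^{-1}$. The reported evidence approximation is the exact Gaussian
  integral $\log p(y,\mu) + \frac{k}{2}\log 2\pi - \frac12\log|-H|$, which
  the tests pin to the closed-form marginal likelihood of a conjugate
  linear-Gaussian model to $10^{-6}$. A commonly printed variant that keeps
  a $+k/2$ term and takes the determinant of the precision matrix itself is
  also recorded (`elbo_laplace_precision_form`) so any downstream
  comparison can audit which convention it uses; on a quadratic log joint
  that variant misses the true evidence by $k/2$ and the determinant sign.

## Diagnostics and model comparison

Split rank-normalized $\hat R$, bulk ESS (Geyer initial monotone sequence on
rank-normalized split chains, fractional ranks $(r - 3/8)/(S + 1/4)$) and
tail ESS (minimum over the 5% and 95% quantile indicator series) follow the
modern recommendations. Posterior z-scores are
$(\mathrm{mean} - \mathrm{truth})/\mathrm{sd}$ per parameter. Fit quality is
the RMSE between the observation and the noise-free prediction at the
posterior mean of the parameters (the "faithful fit" test is RMSE
$\le 0.25$, about 2.5 noise sds); the posterior-mean-parameter convention
was chosen over averaging per-draw predictions, and parameter recovery is
summarized as the RMS of *relative* errors because the parameter magnitudes
span 0.15 to 27.9, so absolute errors would be dominated by the largest
parameters.

Model comparison reports AIC and BIC (likelihood maximized by BFGS from the
posterior mean and the best posterior draw, keeping the better optimum),
WAIC (log pointwise predictive density minus the variance-based effective
parameter count) and PSIS-LOO, all on the deviance scale where smaller is
better; the positive elpd values are stored alongside. The PSIS tail uses
the profile-likelihood generalized-Pareto estimator on the largest
importance ratios, with tail size $\max(5, \lceil\min(0.2S,
3\sqrt S)\rceil)$ — the $3\sqrt S$ cap matters: an uncapped 20% tail
visibly biases the estimator relative to exact leave-one-out refits on
conjugate models, which the tests check directly. Stacking weights maximize
the average log mixture leave-one-out predictive density over the simplex
via a softmax reparametrization with multiple starts and a $10^{-8}$ ridge
toward uniform weights that breaks ties between identical members; the
achieved objective is certified in tests to dominate every single-member
vertex and the uniform weighting. Chain-level stacking treats each chain as
a member; the same code path serves model-level stacking. Stacked/pooled
predictive traces use the mixture of per-chain posterior-mean predictions.

## Experiment orchestration and problem sizes

`run_grid_experiment` / `run_tails_experiment` sweep NUTS hyperparameters
(default grid: target acceptance $\{0.6, 0.7, 0.8, 0.9, 0.95\}$ $\times$
max tree depth $\{5,6,7,8\}$, i.e. 20 settings and 80 chains at 4 chains per
setting) under random or tail initialization and record one labelled
diagnostics row per chain. `run_stacking_experiment` compares stacked
against pooled predictives over randomly initialized chains.
`run_benchmark_experiment` produces the four-method comparison table and
`run_model_comparison_experiment` the five-model criterion table (full
model plus each $g_k = 0$ reduction). `run_prior_predictive` reports the
dynamically unstable percentage of prior draws with a binomial interval.
Every experiment takes a seed, is bitwise reproducible given it, and writes
its outputs plus a JSON manifest (package version, seed, config echo) only
inside its output directory. All chain counts and iteration budgets are
arguments; the shipped tests exercise reduced configurations (tens to a few
hundred iterations, 2–8 chains, and a 1500-ms classification horizon)
chosen so the whole suite completes on a laptop-class single core, while
the defaults reproduce the study-scale settings.

## What the generator does and does not emulate

The synthetic series reproduces the stated statistical structure exactly:
one trial, additive white Gaussian noise on the full-resolution pyramidal
voltage, downsampling by decimation. It does not emulate channel-level
forward (lead-field) mixing, multi-trial averaging, correlated or
non-Gaussian noise, or any empirical MEG/EEG artifacts. Passing tests
therefore certify the inference machinery on a well-specified model; they
say nothing about robustness to model misspecification on real recordings.

## Known limitations

* The posterior is genuinely multi-modal under random initialization;
  tail initialization and stacking are mitigations, not cures, and the
  structural non-identifiability of $g_1$ (a reduced $g_1 = 0$ model fits
  the data as well as the full model) means near-ties between those two
  models under predictive criteria are expected and seed-dependent.
* Euler at a fixed step trades accuracy for differentiability and speed; no
  adaptive or higher-order integrator is provided, and no true
  delay-differential solver.
* The observation noise sd is fixed, not inferred.
* Wall-clock benchmarking across probabilistic programming backends is out
  of scope.
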