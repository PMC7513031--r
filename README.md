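# condgauss

Exact filtering, statistically accurate Fokker–Planck solution and
parameter estimation for **conditionally Gaussian multiscale stochastic
systems** in R.

## The problem and who this is for

Many multiscale stochastic models in systems biology and geophysics —
spiking-neuron lattices, epidemic and predator–prey dynamics,
nutrient-limited tumour growth, low-order turbulence and climate models —
share one structural property.  Write the state as `u = (uI, uII)` with an
observed subspace `uI` and a hidden subspace `uII`:

```
duI  = [A0(t,uI) + A1(t,uI) uII] dt + ΣI(t,uI)  dWI
duII = [a0(t,uI) + a1(t,uI) uII] dt + ΣII(t,uI) dWII
```

The drift is affine in `uII` and the diffusion does not depend on `uII`,
so **given the observed path, the hidden state is exactly Gaussian**,
`N(ūII(t), RII(t))`, with closed evolution equations

```
dūII = [a0 + a1 ūII] dt + RII A1* (ΣI ΣI*)^-1 [duI − (A0 + A1 ūII) dt]
dRII = {a1 RII + RII a1* + ΣII ΣII* − RII A1* (ΣI ΣI*)^-1 (RII A1*)*} dt
```

even though the full system is nonlinear and its statistics intermittent
and fat-tailed.  `condgauss` is for anyone who wants to exploit that
structure: state estimation of unobserved populations or gating variables,
time-dependent PDFs of systems with thousands of dimensions, and parameter
estimation from a single observed trajectory — all without ensemble Kalman
approximations or expensive particle filters in the full state space.

What it provides:

* a **model registry** (`build_model()`, `list_models()`) of 20
  conditionally Gaussian systems with their standard parameters, plus
  numerical validators of the structure and of energy-conserving
  (physics-constrained) quadratic nonlinearities;
* an **Euler–Maruyama simulator** (`simulate_sde()`,
  `ensemble_simulate()`) — the package's synthetic-data source;
* the **closed-form filter** (`filter_posterior()`), its Kalman–Bucy
  special case, and a **block-decomposed** variant that updates 1000
  instead of 40,000 covariance entries per step on the two-layer Lorenz 96
  testbed (2000 instead of 10^6 on a 500-site FitzHugh–Nagumo lattice);
* a **hybrid Fokker–Planck solver** (`hidden_marginal()`,
  `observed_marginal()`, `hybrid_joint()`, `symmetry_augment()`):
  conditional Gaussian mixtures on the hidden subspace, solve-the-equation
  plug-in kernel density estimation on the low-dimensional observed
  subspace, and statistical-symmetry pooling that turns one lattice run
  into `K` samples;
* three **parameter-estimation schemes** (`estimate_direct()`,
  `estimate_stochastic_param()`, `estimate_unresolved_fixed_point()`);
* **information-theoretic skill metrics** (`relative_entropy()`,
  `shannon_entropy_residual()`, `mutual_information()`, plus RMSE and
  pattern correlation);
* the **conditional-Gaussian-mixture particle-filter analysis step**
  (`mixture_prior()`, `analysis_update()`, `resample_particles()`);
* six end-to-end **reproduction experiments** (`run_experiment()`) and a
  thin command-line front end (`inst/cli/condgauss.R`).

## Worked example: recovering a hidden stochastic damping

The SPEKF-M model is an observed mode `u` driven by a hidden
Ornstein–Uhlenbeck damping `γ`; when `γ` transiently crosses zero the
anti-damping produces intermittent bursts in `u`.  We simulate it, filter
the hidden damping, and then estimate the *parameters* of the hidden
process from the observed trajectory alone:

```r
library(condgauss)

spec <- build_model("spekf_m")      # truth: sigma_gamma=0.5, d_gamma=0.5, gamma_hat=1
spec
#> <cg_model 'spekf_m'>  n_I = 1, n_II = 1

traj <- simulate_sde(spec, u0 = c(2, 1), T = 400, dt = 0.005, seed = 7)
traj
#> <cg_trajectory 'spekf_m'>  80000 steps, dt = 0.005, seed = 7

fit <- filter_posterior(spec, traj, init_mean = 1, init_cov = matrix(0.25))
pattern_correlation(traj$uII[, 1], fit$mean[, 1])
#> [1] 0.765

est <- estimate_unresolved_fixed_point(traj, init = c(0.1, 1, 2.5))
est
#> <cg_param_estimate>
#> sigma_gamma     d_gamma   gamma_hat
#>   0.4709987   0.5338061   0.9513573
#>   fixed-point iterations: 7 (converged: TRUE)

est$point_estimate[1]^2 / (2 * est$point_estimate[2])
#> sigma_gamma
#>   0.2077974
```

Reading the numbers: the posterior mean of `γ` tracks the hidden truth
with pattern correlation 0.77 — high at the intermittent phases where `u`
is informative, uncertain in quiescent phases.  Starting the fixed-point
iteration far from the truth (`0.1, 1, 2.5`), the scheme converges to
`(σ̂γ, d̂γ, γ̂) ≈ (0.47, 0.53, 0.95)` against the true `(0.5, 0.5, 1)`;
the implied stationary variance `σγ²/(2dγ) ≈ 0.21` is within the
finite-record error of the true `0.25` on this 400-time-unit trajectory.

The larger demonstrations run as named experiments, e.g.

```r
run_experiment("fhn_prediction", overrides = list(N = 500), out_dir = "fhn")
```

which predicts the 1-d marginals of a 1500-dimensional stochastic
FitzHugh–Nagumo lattice from a *single* simulation (blocked filter +
statistical symmetry) and scores them in relative entropy (≈ 0.01) against
a pooled 10^4-sample Monte Carlo truth.

## Command line

```sh
Rscript inst/cli/condgauss.R models
Rscript inst/cli/condgauss.R simulate --model cfg.json --T 10 --seed 1 --out traj.csv
Rscript inst/cli/condgauss.R filter   --model cfg.json --traj traj.csv --out post.csv
Rscript inst/cli/condgauss.R run      --experiment dyad_filter_regimes --out outdir
```

Model configs are JSON: `{"name": "dyad", "params": {"regime": "II"}}`.
Trajectories and tables are CSV with JSON manifests recording model, seed,
step size and package version.

See the methods vignette
(`vignettes/conditional-gaussian-framework.Rmd`) for the model class, the
numerical choices and their rationale, and known limitations.
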