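---
title: "Conditional Gaussian filtering, Fokker-Planck solution and parameter estimation with condgauss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional Gaussian filtering, Fokker-Planck solution and parameter estimation with condgauss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condgauss)
```

## The model class

`condgauss` works with coupled stochastic differential equations whose state
splits into an observed subspace $u_I$ (dimension $N_I$) and a hidden
subspace $u_{II}$ (dimension $N_{II}$):

$$
du_I = [A_0(t,u_I) + A_1(t,u_I)\,u_{II}]\,dt + \Sigma_I(t,u_I)\,dW_I, \qquad
du_{II} = [a_0(t,u_I) + a_1(t,u_I)\,u_{II}]\,dt + \Sigma_{II}(t,u_I)\,dW_{II}.
$$

All coefficients may depend arbitrarily (nonlinearly) on $u_I$, but the
drift is affine in $u_{II}$ and the diffusion does not depend on $u_{II}$.
Under this structure, $u_{II}(t)$ conditioned on the observed path
$u_I(s\le t)$ is exactly Gaussian, $\mathcal N(\bar u_{II}(t), R_{II}(t))$,
with closed moment equations

$$
d\bar u_{II} = [a_0 + a_1\bar u_{II}]\,dt
 + R_{II}A_1^*(\Sigma_I\Sigma_I^*)^{-1}\,[du_I - (A_0 + A_1\bar u_{II})\,dt],
$$
$$
dR_{II} = \{a_1 R_{II} + R_{II}a_1^* + \Sigma_{II}\Sigma_{II}^*
 - R_{II}A_1^*(\Sigma_I\Sigma_I^*)^{-1}(R_{II}A_1^*)^*\}\,dt .
$$

The conditional law is Gaussian, but the system itself is genuinely
nonlinear: marginal and joint statistics can be intermittent, skewed,
fat-tailed or multimodal, which is exactly what makes the class useful for
multiscale stochastic biology and geophysics.  The assumption that matters
in practice is that, with the large scales held fixed, the small-scale
fluctuations are close to Gaussian; the feedback of $u_{II}$ on $u_I$
remains fully nonlinear.

A model is a `cg_model`: black-box coefficient functions of `(t, uI)` plus
dimensions, names, optional positivity bounds and optional block metadata.
The registry (`list_models()`) ships spiking-neuron lattices
(`fhn_lattice`, `fhn3d`), epidemic and ecology models (`sir`,
`predator_prey`), tumour growth (`cancer`), noisy Lorenz systems (`l63`,
`l84`, `l96`, `two_layer_l96`), low-order turbulence models (`triad`,
`conceptual`, `conceptual_mod`, `climate4d`, `topographic`, `dyad`), the
SPEKF family (`spekf`, `spekf_m`, `msm`), a surface-wind model and a plain
OU process.

### Structural validation rather than symbolic analysis

Because coefficients are black boxes, the package does not derive structure
symbolically.  Every registered model also carries `drift_full`, written
directly from the model equations and independently of the
$(A_0,A_1,a_0,a_1)$ factorization.  `validate_cg_structure()` probes random
states and checks (i) second differences of the full drift along hidden
directions vanish (affinity) and (ii) the drift agrees with the declared
coefficients, so a mis-factored model is caught numerically.  Similarly,
`quadratic_energy_residual()` extracts the quadratic part of the drift as
*drift minus its affine fit at the origin*, with unit-step central
differences (exact for quadratic drifts up to roundoff), and returns the
energy flux $u\cdot B(u,u)$; for the physics-constrained models this is
zero to $10^{-14}$, which is the package's guard against energy-injecting
mis-specification.

### Conventions worth knowing

* **Complex modes** (the SPEKF observed mode and its forcing) are stored as
  interleaved real/imaginary coordinates; a complex noise amplitude
  $\sigma$ becomes $\sigma/\sqrt2$ per real component, so all filter
  algebra stays real with one covariance convention.
* **Splits are declared, not inferred.** Models admitting two conditional
  Gaussian splits register both (`l63` with `split = "x"` or `"yz"`,
  `topographic` with `split = "v"` or `"u"`); no automatic discovery is
  attempted.
* **Single-layer `l96`** is registered for simulation only: without a
  carefully chosen subset of coordinates it has no generic hidden split,
  so it carries `n_II = 0`.
* Model parameters default to the standard values used in the source
  studies.  Three models come with no published numbers (`sir`, `cancer`,
  `surface_wind`); their defaults were chosen once as epidemiologically /
  biophysically plausible magnitudes (e.g. SIR death rates
  $\mu_1 < \min(\mu_2,\mu_3)$, contact rate giving a non-trivial endemic
  cycle) and are not calibrated to any dataset.  The 4-D climate model's
  fast-mode dampings $\gamma_1,\gamma_2$ (absent from the published
  parameter list) default to 1.

## Simulation

`simulate_sde()` integrates by Euler--Maruyama with independent Wiener
increments per coordinate.  The choice is deliberate: every model in the
registry has additive or state-multiplicative noise and is integrated at
small steps, where the first-order weak bias is far below the statistical
errors of interest; higher-order and implicit schemes are out of scope.
With additive noise the scheme is strongly first order, which the test
suite verifies by refining a shared Brownian path.

Two practical choices:

* **Positivity.** Population-type models (`sir`, `predator_prey`,
  `cancer`) have multiplicative noise vanishing at zero, but a discretized
  drift step can still cross zero.  States are clipped at the declared
  bound and counted (`n_clipped`); the count is zero for unconstrained
  models.  No exact boundary treatment is attempted -- the underlying
  singularity is an open analytical problem, and clipping leaves the
  dynamics untouched away from the boundary.
* **Step sizes.** Each registry entry stores a default `dt`.  The stiff
  FitzHugh--Nagumo lattice ($\epsilon = 0.01$, diffusion $d_u = 1$) has an
  explicit-Euler stability limit $dt < \epsilon/(2d_u) = 0.005$ from the
  periodic second-difference Laplacian alone, so its default is 0.002.

`ensemble_simulate()` derives per-member seeds deterministically from one
seed, so ensembles are bit-reproducible given `(seed, L, dt)`.

## Filtering

`filter_posterior()` discretizes the moment equations with explicit Euler
on the observation grid, using the observed increments
$du_I = u_I(t+\Delta t) - u_I(t)$.  The covariance is symmetrized each
step; the scheme carries the same first-order bias as the simulator, which
is documented rather than corrected.  Degenerate observed noise
($\Sigma_I\Sigma_I^*$ singular) raises an error naming the offending rows;
`regularize = TRUE` adds $\lambda I$ with $\lambda = 10^{-10}\,
\mathrm{tr}/n$ when the condition number exceeds $10^{12}$ -- off by
default because well-posed models never need it.  Covariance blow-up
(entries above $10^8$) aborts with the failure time.  One stiffness caveat
mirrors the simulator: when the contraction rate $R\,A_1^2/\Sigma_I^2$
approaches $1/dt$ (tight observations, wide initial covariance, or the
FHN $1/\epsilon$ coupling), the explicit update overshoots; use a smaller
step or a tighter initialization.

`kalman_bucy()` is the linear special case.  It shares the code path --
the function only asserts that all coefficients are constant in $u_I$ --
so its agreement with `filter_posterior()` is exact by construction, and
the steady-state covariance solves the algebraic Riccati equation (checked
against the closed-form root in the tests).

### Block decomposition

Large lattice models satisfy a structural condition: the interaction
coefficients $A_{1,k}, a_{1,k}$ of group $k$ depend only on the group's own
observed coordinates, while $A_{0}, a_{0}$ may couple everything.  Then a
block-diagonal initial covariance stays block diagonal forever, and
`filter_posterior_blocked()` evolves each block independently within a step
(order-independent updates -- the parallelizable contract) while the means
remain globally coupled.  The bookkeeping is the point: the two-layer
Lorenz 96 testbed at $I = 40, J = 5$ updates $25\times40 = 1000$ covariance
entries per step instead of $200^2 = 40{,}000$ (2.5%), and the 500-site FHN
lattice $500\times4 = 2000$ instead of $10^6$.  `check_block_condition()`
probes the condition numerically; agreement with the full filter on a
small instance is part of the test suite (below $10^{-8}$).

## Solving the Fokker-Planck equation statistically

The time-dependent PDF of the full system is represented as a Gaussian
mixture over a *small* ensemble of $L$ observed trajectories:

* hidden marginal (`hidden_marginal()`): equal-weight mixture of the $L$
  conditional Gaussians -- parametric, exact given the paths;
* observed marginal (`observed_marginal()`): Gaussian kernel density
  estimate over the $L$ endpoints, with per-dimension solve-the-equation
  plug-in bandwidths (`kde_bandwidth()`, implemented with
  `stats::bw.SJ(method = "ste")`; Silverman's rule as a warning-emitting
  fallback for tiny or pathological samples);
* joint (`hybrid_joint()`): the tensor product, component by component, so
  marginalization in either direction is exact rather than approximate.

The bandwidth matrix is diagonal.  The observed subspaces this solver is
designed for have $N_I \le 3$ effective dimensions per kernel, where the
loss from ignoring kernel cross-correlations is small and the plug-in
theory is reliable; the spatial correlation of the full field is carried by
the mixture means, not by the kernels.

**Statistical symmetry.** On a homogeneous lattice every site has the same
law, so the $K$ site-wise Gaussians of a *single* run act as $K$ samples:
the effective ensemble size is $K L$.  `symmetry_augment()` pools them into
1-d marginals, or 2-d joints by pairing site $k$ with site $k+\mathrm{offset}$
(cyclic wrap) with diagonal per-component covariance; it refuses models not
flagged symmetric (the inhomogeneous two-layer Lorenz 96, for instance).
The package's headline demonstration (`run_experiment("fhn_prediction")`)
predicts the 1500-dimensional FHN lattice marginals from one simulation
($L = 1$, $K = 500$) within relative entropy 0.01--0.05 of a pooled Monte
Carlo truth.

**Scales used for verification.** Monte Carlo truths in the tests use
$10^4$ pooled samples (e.g. 20 lattice runs x 500 sites) rather than the
$1.5\times10^5$--$4\times10^7$ a full study would employ; the relative
entropy thresholds (0.1 for lattice marginals, looser than the asymptotic
accuracy of the method) were set to sit well above the sampling noise of
truths this size.  Passing these tests shows the estimator agrees with the
model's own sampled law at that resolution; it says nothing about fitting
real laboratory data, where model misspecification would dominate.

## Parameter estimation

Three schemes ride on the filter, all based on appending unknown parameters
$\Lambda$ that enter the observed drift affinely to the hidden state
(`param_model()` describes the affine structure; `l63_param_model()` is the
shipped example).

1. **Direct** (`estimate_direct()`): $d\Lambda = 0$.  The parameter
   posterior variance has no positive source term, hence is monotonically
   non-increasing, and $R_{II} = 0$ is the noise-free fixed point; the test
   suite checks the scheme against the conjugate Bayesian regression closed
   form on a constant-drift model.  Convergence slows as observation noise
   grows.
2. **Stochastic parameterized** (`estimate_stochastic_param()`): each
   parameter follows an OU prior process with damping $d$, mean $\hat\Lambda$
   and noise $\sigma_\Lambda$.  The deliberate model error buys a much
   faster (exponential vs algebraic) convergence rate; the point estimate is
   the time-average of the posterior mean over a window, by default the
   final 80% of the record (the shipped Lorenz 63 reproduction uses
   $t\in[10,50]$ and the published prior: means biased $+20\%$, damping 0.5
   -- a 2-time-unit decorrelation -- and noise levels putting the truth one
   standard deviation from the prior mean).  With observation noise 15 on
   all three coordinates this lands all three parameters within 10--12% of
   truth, against the 20% prior bias.
3. **Fixed point for unresolved processes**
   (`estimate_unresolved_fixed_point()`): for a hidden OU damping observed
   only through its effect on a resolved mode, iterate:
   filter with the current $(\sigma_\gamma, d_\gamma, \hat\gamma)$; pool
   the conditional Gaussians over time instants into an equilibrium
   mixture; update $\hat\gamma \leftarrow$ mean of conditional means,
   $d_\gamma \leftarrow 1/\tau$, $\sigma_\gamma \leftarrow \sqrt{2 d_\gamma
   R_{eq}}$ with $R_{eq} = \overline{R(t) + (\mu(t)-\bar\mu)^2}$.

   Two numerical choices were genuinely open.  The decorrelation time
   $\tau$ is the *integrated autocorrelation time* of the conditional-mean
   series: trapezoid over the sample ACF up to its first non-positive lag,
   times $dt$ -- chosen because it equals $1/d$ exactly for an OU process,
   matching the update rule's intent.  The stopping rule is relative change
   below $10^{-2}$ on all three parameters.  Under that rule the iteration
   takes 6--7 updates from a distant start, with the iterates already
   within a few percent of the fixed point by iteration 5; on a
   1000-time-unit record the recovered stationary variance
   $\sigma_\gamma^2/(2d_\gamma)$ lands within finite-record error of the
   true 0.25 (longer records tighten it, which is one of the consistency
   tests).

## Model-error metrics

`rmse()` and `pattern_correlation()` are the traditional path-wise scores.
The information metrics are deliberately tail-sensitive:
`relative_entropy()` (Gaussian closed form, or trapezoid quadrature with
densities floored at $10^{-300}$ and an `Inf`-with-flag result when more
than $10^{-4}$ of the truth mass sits on floored cells),
`shannon_entropy_residual()` (entropy of the KDE of $u - u^M$, closed form
under a Gaussian flag) and `mutual_information()`, computed *through the
identity* $M = \mathcal P(p(u,u^M),\,\pi(u)\pi(u^M))$ so the
relative-entropy code path is shared and non-negativity is inherited.  The
default usage is path-wise: statistics pooled over all sample points of a
single realization, which is how the twin experiments
(`run_experiment("dyad_filter_regimes")`) score filters.

## The mixture particle-filter analysis step

For multiscale assimilation the forecast prior is a conditional Gaussian
mixture (`mixture_prior()`): $Q$ particles for the large scales, each
carrying a Gaussian small-scale law.  A mixed linear observation
$v = \bar G\bar u + G'(\bar u)u' + \sigma_\theta$ (`linear_mixed_obs()`)
updates each particle by a standard Kalman analysis and reweights by the
marginal likelihood $I_j$, which is Gaussian *in closed form* (the
integral of a Gaussian likelihood against a Gaussian prior); the quadrature
evaluation of $I_j$ is kept in the tests as an oracle, not in the code
path.  Rank-deficient $G'(\bar u)$ raises an error rather than
pseudo-inverting -- the observation operator's row rank is a modelling
assumption the code refuses to repair silently.  Weight underflow across
*all* particles falls back to uniform weights with a warning;
`resample_particles()` implements multinomial resampling below an
effective-sample-size fraction.  The forecast step is intentionally
pluggable: any per-particle forecast (e.g. `simulate_sde()` +
`filter_posterior()`) can feed the next analysis; no superparameterization
forecast model is included.

## Reproduction experiments, sizes and limitations

`run_experiment()` regenerates six named studies at desk scale, writing
CSV tables plus a JSON manifest (model, seed, step, package version) that
reproduces the run exactly.  Default problem sizes, chosen so the full test
suite runs in minutes on one core: FHN lattice $N = 100$ (500 in the
acceptance-grade run) with a $10^4$-sample pooled truth; two-layer Lorenz
96 at $I = 8, J = 2$, $L = 100$; Lorenz 63 records of 25--50 time units at
$dt = 0.002$; SPEKF-M records of 1000 time units at $dt = 0.005$; dyad twin
experiments of 200 time units.

Known limitations, by design: explicit first-order discretization
everywhere (no smoothing/backward pass, no continuous--discrete observation
models off the simulation grid); diagonal KDE bandwidths; no grid-based PDE
solution of the Fokker--Planck equation; no symbolic structure derivation;
the spatially extended geophysical systems are represented only by their
low-order conditional Gaussian reductions in the registry.
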