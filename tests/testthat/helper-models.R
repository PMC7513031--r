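# shared fixtures: small analytically tractable models

# scalar linear filtering model: duI = uII dt + sI dW, duII = -a uII dt + sII dW
linear_scalar_model <- function(a = 1, sI = 0.5, sII = 1) {
  cg_model(1, 1,
           A0 = function(t, uI) 0,
           A1 = function(t, uI) matrix(1, 1, 1),
           a0 = function(t, uI) 0,
           a1 = function(t, uI) matrix(-a, 1, 1),
           SigmaI = function(t, uI) sI,
           SigmaII = function(t, uI) sII,
           name = "linear_scalar")
}

# positive root of the steady-state Riccati equation
# -2 a R + sII^2 - R^2 / sI^2 = 0
riccati_root <- function(a, sI, sII) sI^2 * (-a + sqrt(a^2 + sII^2 / sI^2))

# drift-only mean-reverting parameter model: duI = lambda dt + sigma dW
constant_drift_param_model <- function(sigma = 0.5) {
  param_model(n_I = 1, n_par = 1,
              A0 = function(t, uI) 0,
              A1_lambda = function(t, uI) matrix(1, 1, 1),
              SigmaI = function(t, uI) sigma,
              par_names = "lambda")
}

# observed (x, y, z) trajectory of the noisy Lorenz 63 system
l63_obs_traj <- function(noise, T, dt, seed) {
  spec <- build_model("l63", sigma_x = noise, sigma_y = noise,
                      sigma_z = noise)
  tr <- simulate_sde(spec, c(1.5, -1.5, 25), T = T, dt = dt, seed = seed)
  structure(list(t = tr$t, uI = cbind(tr$uI[, 1], tr$uII), uII = NULL,
                 dt = dt, seed = seed, n_clipped = 0L, model = "l63_obs"),
            class = "cg_trajectory")
}
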