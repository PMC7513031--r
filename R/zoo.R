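# Registry of conditionally Gaussian test models.
#
# Each builder returns a cg_model whose observed/hidden split is the one
# under which the hidden subspace is conditionally Gaussian.  drift_full is
# written directly from the model equations, independently of the
# coefficient factorization, so that validate_cg_structure() is a genuine
# cross-check.

.cg_registry <- new.env(parent = emptyenv())

register_model <- function(name, description, builder) {
  assign(name, list(description = description, builder = builder),
         envir = .cg_registry)
}

#' List registered models
#' @return data frame with columns `name` and `description`.
#' @export
list_models <- function() {
  nm <- sort(ls(.cg_registry))
  data.frame(name = nm,
             description = vapply(nm, function(n)
               get(n, envir = .cg_registry)$description, character(1)),
             row.names = NULL)
}

#' Instantiate a registered model
#'
#' @param name registered model identifier (see [list_models()]).
#' @param ... parameter overrides; unspecified parameters fall back to the
#'   model's standard values.
#' @return a [cg_model()].
#' @export
build_model <- function(name, ...) {
  if (!exists(name, envir = .cg_registry))
    stop("unknown model name '", name, "'; see list_models()")
  get(name, envir = .cg_registry)$builder(...)
}

merge_params <- function(defaults, override) {
  for (nm in names(override)) {
    if (!nm %in% names(defaults))
      stop("unknown parameter '", nm, "'")
    if (!is.function(override[[nm]]) && !is.null(defaults[[nm]]) &&
        length(defaults[[nm]]) > 1 && length(override[[nm]]) == 1)
      override[[nm]] <- rep(override[[nm]], length(defaults[[nm]]))
    defaults[[nm]] <- override[[nm]]
  }
  defaults
}

cyc <- function(i, n) ((i - 1L) %% n) + 1L

## ---- Lorenz models -------------------------------------------------------

build_l63 <- function(sigma = 10, rho = 28, beta = 8 / 3,
                      sigma_x = 5, sigma_y = 5, sigma_z = 5,
                      split = c("x", "yz")) {
  split <- match.arg(split)
  p <- list(sigma = sigma, rho = rho, beta = beta,
            sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
            split = split)
  drift <- function(t, u) {
    # state order depends on the split; map to (x, y, z)
    if (split == "x") { x <- u[1]; y <- u[2]; z <- u[3] }
    else { y <- u[1]; z <- u[2]; x <- u[3] }
    d <- c(sigma * (y - x), x * (rho - z) - y, x * y - beta * z)
    if (split == "x") d else d[c(2, 3, 1)]
  }
  if (split == "x") {
    cg_model(
      n_I = 1, n_II = 2,
      A0 = function(t, uI) -sigma * uI[1],
      A1 = function(t, uI) matrix(c(sigma, 0), 1, 2),
      a0 = function(t, uI) c(rho * uI[1], 0),
      a1 = function(t, uI) matrix(c(-1, uI[1], -uI[1], -beta), 2, 2),
      SigmaI = function(t, uI) sigma_x,
      SigmaII = function(t, uI) c(sigma_y, sigma_z),
      state_names_I = "x", state_names_II = c("y", "z"),
      drift_full = drift, physics_constrained = TRUE,
      name = "l63", params = p, default_dt = 0.005)
  } else {
    cg_model(
      n_I = 2, n_II = 1,
      A0 = function(t, uI) c(-uI[1], -beta * uI[2]),
      A1 = function(t, uI) matrix(c(rho - uI[2], uI[1]), 2, 1),
      a0 = function(t, uI) sigma * uI[1],
      a1 = function(t, uI) matrix(-sigma, 1, 1),
      SigmaI = function(t, uI) c(sigma_y, sigma_z),
      SigmaII = function(t, uI) sigma_x,
      state_names_I = c("y", "z"), state_names_II = "x",
      drift_full = drift, physics_constrained = TRUE,
      name = "l63", params = p, default_dt = 0.005)
  }
}
register_model("l63", "noisy Lorenz 63 (uI = x, uII = (y,z); split = 'yz' for the converse)",
               function(...) do.call(build_l63, list(...)))

build_l84 <- function(a = 0.25, b = 4, f = 8, g = 1,
                      sigma_x = 0.1, sigma_y = 0.1, sigma_z = 0.1) {
  p <- mget(c("a", "b", "f", "g", "sigma_x", "sigma_y", "sigma_z"))
  # state order (y, z, x): the wave phases are observed, the zonal flow x is
  # hidden (the drifts of y and z are affine in x, that of x is affine in x)
  drift <- function(t, u) {
    y <- u[1]; z <- u[2]; x <- u[3]
    c(-b * x * z + x * y - y + g,
      b * x * y + x * z - z,
      -(y^2 + z^2) - a * (x - f))
  }
  cg_model(
    n_I = 2, n_II = 1,
    A0 = function(t, uI) c(-uI[1] + g, -uI[2]),
    A1 = function(t, uI) matrix(c(-b * uI[2] + uI[1], b * uI[1] + uI[2]), 2, 1),
    a0 = function(t, uI) -(uI[1]^2 + uI[2]^2) + a * f,
    a1 = function(t, uI) matrix(-a, 1, 1),
    SigmaI = function(t, uI) c(sigma_y, sigma_z),
    SigmaII = function(t, uI) sigma_x,
    state_names_I = c("y", "z"), state_names_II = "x",
    drift_full = drift, physics_constrained = TRUE,
    name = "l84", params = p, default_dt = 0.005)
}
register_model("l84", "noisy Lorenz 84 (uI = (y,z), uII = x)",
               function(...) do.call(build_l84, list(...)))

l96_dv_defaults <- c(0.2, 0.5, 1, 2, 5)
l96_sv_defaults <- c(0.5, 0.2, 0.1, 0.1, 0.1)

build_two_layer_l96 <- function(I = 40, J = 5, F = 8, sigma_u = 1,
                                dbar = NULL, gamma = NULL,
                                d_v = NULL, sigma_v = NULL) {
  if (is.null(dbar)) dbar <- 1 + 0.7 * cos(2 * pi * seq_len(I) / J)
  if (is.null(gamma)) gamma <- 0.1 + 0.25 * cos(2 * pi * seq_len(I) / J)
  if (is.null(d_v)) d_v <- l96_dv_defaults[pmin(seq_len(J), 5L)]
  if (is.null(sigma_v)) sigma_v <- l96_sv_defaults[pmin(seq_len(J), 5L)]
  stopifnot(length(dbar) == I, length(gamma) == I,
            length(d_v) == J, length(sigma_v) == J)
  p <- mget(c("I", "J", "F", "sigma_u", "dbar", "gamma", "d_v", "sigma_v"))
  im1 <- cyc(seq_len(I) - 1L, I); ip1 <- cyc(seq_len(I) + 1L, I)
  im2 <- cyc(seq_len(I) - 2L, I)
  vidx <- function(i) (i - 1L) * J + seq_len(J)   # v_{i,1..J}
  drift <- function(t, u) {
    ui <- u[seq_len(I)]
    v <- matrix(u[I + seq_len(I * J)], nrow = J)   # column i = v_{i,.}
    du <- ui[im1] * (ui[ip1] - ui[im2]) +
      gamma * ui * colSums(v) - dbar * ui + F
    dv <- sweep(-v * d_v, 2, gamma * ui^2, `-`)
    c(du, as.vector(dv))
  }
  A0 <- function(t, uI)
    uI[im1] * (uI[ip1] - uI[im2]) - dbar * uI + F
  A1 <- function(t, uI) {
    M <- matrix(0, I, I * J)
    for (i in seq_len(I)) M[i, vidx(i)] <- gamma[i] * uI[i]
    M
  }
  a0 <- function(t, uI) as.vector(vapply(seq_len(I),
    function(i) rep(-gamma[i] * uI[i]^2, J), numeric(J)))
  a1c <- diag(-rep(d_v, I), I * J)
  blocks <- cg_blocks(uI_idx = as.list(seq_len(I)),
                      uII_idx = lapply(seq_len(I), vidx))
  a1blk <- diag(-d_v, J)
  block_coefs <- function(t, uI) list(
    A0 = A0(t, uI), a0 = a0(t, uI),
    A1 = lapply(seq_len(I), function(i)
      matrix(gamma[i] * uI[i], 1, J)),
    a1 = rep(list(a1blk), I),
    SI = rep(list(sigma_u), I),
    SII = rep(list(sigma_v), I))
  cg_model(
    n_I = I, n_II = I * J,
    A0 = A0, A1 = A1, a0 = a0,
    a1 = function(t, uI) a1c,
    SigmaI = function(t, uI) rep(sigma_u, I),
    SigmaII = function(t, uI) rep(sigma_v, I),
    state_names_I = paste0("u", seq_len(I)),
    state_names_II = paste0("v", rep(seq_len(I), each = J), ".",
                            rep(seq_len(J), I)),
    drift_full = drift, blocks = blocks, block_coefs = block_coefs,
    physics_constrained = TRUE,
    name = "two_layer_l96", params = p, default_dt = 0.005)
}
register_model("two_layer_l96",
               "two-layer Lorenz 96 (uI = large-scale u_i, uII = small-scale v_{i,j}; K = I blocks)",
               function(...) do.call(build_two_layer_l96, list(...)))

build_l96 <- function(I = 40, F = 8, dbar = 1, sigma_u = 1) {
  p <- mget(c("I", "F", "dbar", "sigma_u"))
  if (length(dbar) == 1) dbar <- rep(dbar, I)
  im1 <- cyc(seq_len(I) - 1L, I); ip1 <- cyc(seq_len(I) + 1L, I)
  im2 <- cyc(seq_len(I) - 2L, I)
  drift <- function(t, u) u[im1] * (u[ip1] - u[im2]) - dbar * u + F
  cg_model(
    n_I = I, n_II = 0,
    A0 = function(t, uI) drift(t, uI),
    A1 = function(t, uI) matrix(0, I, 0),
    a0 = function(t, uI) numeric(0),
    a1 = function(t, uI) matrix(0, 0, 0),
    SigmaI = function(t, uI) rep(sigma_u, I),
    SigmaII = function(t, uI) numeric(0),
    drift_full = drift, physics_constrained = TRUE,
    name = "l96", params = p, default_dt = 0.005)
}
register_model("l96",
               "single-layer Lorenz 96 with noise (simulation only; no generic hidden split)",
               function(...) do.call(build_l96, list(...)))

## ---- low-order climate / turbulence models -------------------------------

build_climate4d <- function(L12 = 1, L13 = 0.5, L24 = 0.5, a1 = 2, a2 = 1,
                            d1 = -1, d2 = -0.4,
                            sigma_x1 = 0.5, sigma_x2 = 2,
                            sigma_y1 = 0.5, sigma_y2 = 1,
                            b123 = 1.5, b213 = 1.5, b312 = -3,
                            F1 = 0, F2 = 0, F3 = 0, F4 = 0,
                            gamma1 = 1, gamma2 = 1, eps = 1) {
  p <- mget(c("L12", "L13", "L24", "a1", "a2", "d1", "d2",
              "sigma_x1", "sigma_x2", "sigma_y1", "sigma_y2",
              "b123", "b213", "b312", "F1", "F2", "F3", "F4",
              "gamma1", "gamma2", "eps"))
  drift <- function(t, u) {
    x1 <- u[1]; x2 <- u[2]; y1 <- u[3]; y2 <- u[4]
    c(-x2 * (L12 + a1 * x1 + a2 * x2) + d1 * x1 + F1 + L13 * y1 + b123 * x2 * y1,
      x1 * (L12 + a1 * x1 + a2 * x2) + d2 * x2 + F2 + L24 * y2 + b213 * x1 * y1,
      -L13 * x1 + b312 * x1 * x2 + F3 - gamma1 / eps * y1,
      -L24 * x2 + F4 - gamma2 / eps * y2)
  }
  cg_model(
    n_I = 2, n_II = 2,
    A0 = function(t, uI) c(
      -uI[2] * (L12 + a1 * uI[1] + a2 * uI[2]) + d1 * uI[1] + F1,
      uI[1] * (L12 + a1 * uI[1] + a2 * uI[2]) + d2 * uI[2] + F2),
    A1 = function(t, uI) matrix(c(L13 + b123 * uI[2], b213 * uI[1],
                                  0, L24), 2, 2),
    a0 = function(t, uI) c(-L13 * uI[1] + b312 * uI[1] * uI[2] + F3,
                           -L24 * uI[2] + F4),
    a1 = function(t, uI) diag(c(-gamma1 / eps, -gamma2 / eps)),
    SigmaI = function(t, uI) c(sigma_x1, sigma_x2),
    SigmaII = function(t, uI) c(sigma_y1, sigma_y2) / sqrt(eps),
    state_names_I = c("x1", "x2"), state_names_II = c("y1", "y2"),
    drift_full = drift, physics_constrained = TRUE,
    name = "climate4d", params = p, default_dt = 0.005)
}
register_model("climate4d",
               "4D stochastic climate model with multiplicative-noise coupling (uI = climate (x1,x2), uII = weather (y1,y2))",
               function(...) do.call(build_climate4d, list(...)))

triad_regimes <- list(
  I = list(eps = 1, Iu = 1, sigma1 = 0.5, L12 = 0.4, L13 = 0.4, L23 = 0,
           gamma1 = 2.5, gamma2 = 0.4, gamma3 = 0.4,
           sigma2 = 1.2, sigma3 = 0.8, F = 2),
  II = list(eps = 0.1, Iu = 5, sigma1 = 0.5, L12 = 1, L13 = 1, L23 = 10,
            gamma1 = 2, gamma2 = 0.1, gamma3 = 0.1,
            sigma2 = 1.2, sigma3 = 0.8, F = 2))

build_triad <- function(regime = "I", ...) {
  p <- merge_params(triad_regimes[[match.arg(regime, c("I", "II"))]], list(...))
  with(p, {
    drift <- function(t, u)
      c(-gamma1 * u[1] + L12 * u[2] + L13 * u[3] + Iu * u[1] * u[2] + F,
        -L12 * u[1] - gamma2 / eps * u[2] + L23 * u[3] - Iu * u[1]^2,
        -L13 * u[1] - L23 * u[2] - gamma3 / eps * u[3])
    cg_model(
      n_I = 1, n_II = 2,
      A0 = function(t, uI) -gamma1 * uI[1] + F,
      A1 = function(t, uI) matrix(c(L12 + Iu * uI[1], L13), 1, 2),
      a0 = function(t, uI) c(-L12 * uI[1] - Iu * uI[1]^2, -L13 * uI[1]),
      a1 = function(t, uI) matrix(c(-gamma2 / eps, -L23,
                                    L23, -gamma3 / eps), 2, 2),
      SigmaI = function(t, uI) sigma1,
      SigmaII = function(t, uI) c(sigma2, sigma3) / sqrt(eps),
      state_names_I = "u1", state_names_II = c("u2", "u3"),
      drift_full = drift, physics_constrained = TRUE,
      name = "triad", params = p, default_dt = 0.005)
  })
}
register_model("triad",
               "nonlinear triad model with multiscale features (uI = u1, uII = (u2,u3))",
               function(...) do.call(build_triad, list(...)))

build_conceptual <- function(K = 5, d_u = 0.01, gamma = 1.5, F = -0.15,
                             d_v = NULL, sigma_v = NULL) {
  if (is.null(d_v)) d_v <- 1 + 0.02 * seq_len(K)^2
  # stationary energy sigma_v^2/(2 d_v) follows a -5/3 spectrum
  if (is.null(sigma_v)) sigma_v <- sqrt(2 * d_v * 0.004 * (1 + seq_len(K))^(-5/3))
  p <- mget(c("K", "d_u", "gamma", "F", "d_v", "sigma_v"))
  drift <- function(t, u) {
    v <- u[seq_len(K)]; uu <- u[K + 1]
    c(-d_v * v - gamma * uu * v,
      -d_u * uu + gamma * sum(v^2) + F)
  }
  cg_model(
    n_I = K, n_II = 1,
    A0 = function(t, uI) -d_v * uI,
    A1 = function(t, uI) matrix(-gamma * uI, K, 1),
    a0 = function(t, uI) gamma * sum(uI^2) + F,
    a1 = function(t, uI) matrix(-d_u, 1, 1),
    SigmaI = function(t, uI) sigma_v,
    SigmaII = function(t, uI) 0,
    state_names_I = paste0("v", seq_len(K)), state_names_II = "u",
    drift_full = drift, physics_constrained = TRUE,
    name = "conceptual", params = p, default_dt = 0.005)
}
register_model("conceptual",
               "conceptual turbulence model (uI = fluctuations v_k, uII = mean flow u)",
               function(...) do.call(build_conceptual, list(...)))

build_conceptual_mod <- function(K = 5, d_u = 0.1, F = 0.5, sigma_u = 2,
                                 gamma = NULL, d_v = NULL, sigma_v = NULL) {
  if (is.null(gamma)) gamma <- rep(0.25, K)
  if (is.null(d_v)) d_v <- c(0.2, 0.5, 1, 2, 5)[pmin(seq_len(K), 5L)]
  if (is.null(sigma_v)) sigma_v <- c(0.5, 0.2, 0.1, 0.1, 0.1)[pmin(seq_len(K), 5L)]
  p <- mget(c("K", "d_u", "F", "sigma_u", "gamma", "d_v", "sigma_v"))
  drift <- function(t, u) {
    uu <- u[1]; v <- u[1 + seq_len(K)]
    c(-d_u * uu + sum(gamma * uu * v) + F,
      -d_v * v - gamma * uu^2)
  }
  cg_model(
    n_I = 1, n_II = K,
    A0 = function(t, uI) -d_u * uI[1] + F,
    A1 = function(t, uI) matrix(gamma * uI[1], 1, K),
    a0 = function(t, uI) -gamma * uI[1]^2,
    a1 = function(t, uI) diag(-d_v, K),
    SigmaI = function(t, uI) sigma_u,
    SigmaII = function(t, uI) sigma_v,
    state_names_I = "u", state_names_II = paste0("v", seq_len(K)),
    drift_full = drift, physics_constrained = TRUE,
    name = "conceptual_mod", params = p, default_dt = 0.005)
}
register_model("conceptual_mod",
               "modified conceptual turbulence model (uI = mean flow u, uII = fluctuations v_k)",
               function(...) do.call(build_conceptual_mod, list(...)))

build_topographic <- function(omega = 1, beta = 0.5, d_v1 = 1, d_v2 = 1,
                              sigma_v1 = 0.2, sigma_v2 = 0.2,
                              split = c("v", "u"), sigma_u = 0.1) {
  split <- match.arg(split)
  p <- mget(c("omega", "beta", "d_v1", "d_v2", "sigma_v1", "sigma_v2",
              "split", "sigma_u"))
  if (split == "v") {
    drift <- function(t, u) {
      v1 <- u[1]; v2 <- u[2]; uu <- u[3]
      c(-d_v1 * v1 - 2 * omega * uu - beta * v2 + uu * v2,
        -d_v2 * v2 + beta * v1 - uu * v1,
        omega * v1)
    }
    cg_model(
      n_I = 2, n_II = 1,
      A0 = function(t, uI) c(-d_v1 * uI[1] - beta * uI[2],
                             -d_v2 * uI[2] + beta * uI[1]),
      A1 = function(t, uI) matrix(c(-2 * omega + uI[2], -uI[1]), 2, 1),
      a0 = function(t, uI) omega * uI[1],
      a1 = function(t, uI) matrix(0, 1, 1),
      SigmaI = function(t, uI) c(sigma_v1, sigma_v2),
      SigmaII = function(t, uI) 0,
      state_names_I = c("v1", "v2"), state_names_II = "u",
      drift_full = drift, physics_constrained = TRUE,
      name = "topographic", params = p, default_dt = 0.005)
  } else {
    # mean flow observed: stochastic noise added to u
    drift <- function(t, u) {
      uu <- u[1]; v1 <- u[2]; v2 <- u[3]
      c(omega * v1,
        -d_v1 * v1 - 2 * omega * uu - beta * v2 + uu * v2,
        -d_v2 * v2 + beta * v1 - uu * v1)
    }
    cg_model(
      n_I = 1, n_II = 2,
      A0 = function(t, uI) 0,
      A1 = function(t, uI) matrix(c(omega, 0), 1, 2),
      a0 = function(t, uI) c(-2 * omega * uI[1], 0),
      a1 = function(t, uI) matrix(c(-d_v1, beta - uI[1],
                                    -beta + uI[1], -d_v2), 2, 2),
      SigmaI = function(t, uI) sigma_u,
      SigmaII = function(t, uI) c(sigma_v1, sigma_v2),
      state_names_I = "u", state_names_II = c("v1", "v2"),
      drift_full = drift, physics_constrained = TRUE,
      name = "topographic", params = p, default_dt = 0.005)
  }
}
register_model("topographic",
               "topographic mean-flow interaction model (uI = (v1,v2); split = 'u' observes the mean flow)",
               function(...) do.call(build_topographic, list(...)))

## ---- reaction-diffusion models in neuroscience and ecology ---------------

build_fhn_lattice <- function(N = 500, eps = 0.01, d_u = 1,
                              delta1 = 0.2, delta2 = 0.4, a = 1.05,
                              d_gamma = 1, gamma_hat = 1, sigma_gamma = 0.6) {
  p <- mget(c("N", "eps", "d_u", "delta1", "delta2", "a",
              "d_gamma", "gamma_hat", "sigma_gamma"))
  ip1 <- cyc(seq_len(N) + 1L, N); im1 <- cyc(seq_len(N) - 1L, N)
  iv <- 2L * seq_len(N) - 1L; ig <- 2L * seq_len(N)   # uII = (v1,g1,...,vN,gN)
  drift <- function(t, u) {
    ui <- u[seq_len(N)]
    v <- u[N + iv]; g <- u[N + ig]
    lap <- if (N > 1) d_u * (ui[ip1] + ui[im1] - 2 * ui) else 0
    du <- (lap + ui - ui^3 / 3 - v) / eps
    dvg <- numeric(2 * N)
    dvg[iv] <- g * ui + a
    dvg[ig] <- -d_gamma * (g - gamma_hat)
    c(du, dvg)
  }
  A0 <- function(t, uI) {
    lap <- if (N > 1) d_u * (uI[ip1] + uI[im1] - 2 * uI) else 0
    (lap + uI - uI^3 / 3) / eps
  }
  a0v <- local({ z <- numeric(2 * N); z[iv] <- a; z[ig] <- d_gamma * gamma_hat; z })
  sIIv <- local({ z <- numeric(2 * N); z[iv] <- delta2; z[ig] <- sigma_gamma; z })
  A1blk <- matrix(c(-1 / eps, 0), 1, 2)
  block_coefs <- function(t, uI) list(
    A0 = A0(t, uI), a0 = a0v,
    A1 = rep(list(A1blk), N),
    a1 = lapply(seq_len(N), function(i)
      matrix(c(0, 0, uI[i], -d_gamma), 2, 2)),
    SI = rep(list(delta1 / sqrt(eps)), N),
    SII = rep(list(c(delta2, sigma_gamma)), N))
  blocks <- cg_blocks(uI_idx = as.list(seq_len(N)),
                      uII_idx = lapply(seq_len(N), function(i) c(iv[i], ig[i])),
                      symmetric = TRUE)
  cg_model(
    n_I = N, n_II = 2 * N,
    A0 = A0,
    A1 = function(t, uI) {
      M <- matrix(0, N, 2 * N)
      M[cbind(seq_len(N), iv)] <- -1 / eps
      M
    },
    a0 = function(t, uI) a0v,
    a1 = function(t, uI) {
      M <- matrix(0, 2 * N, 2 * N)
      M[cbind(iv, ig)] <- uI
      M[cbind(ig, ig)] <- -d_gamma
      M
    },
    SigmaI = function(t, uI) rep(delta1 / sqrt(eps), N),
    SigmaII = function(t, uI) sIIv,
    state_names_I = paste0("u", seq_len(N)),
    state_names_II = as.vector(rbind(paste0("v", seq_len(N)),
                                     paste0("g", seq_len(N)))),
    drift_full = drift, blocks = blocks, block_coefs = block_coefs,
    symmetric = TRUE,
    name = "fhn_lattice", params = p, default_dt = 0.002)
}
register_model("fhn_lattice",
               "stochastically coupled FitzHugh-Nagumo lattice with multiplicative noise (uI = u_i, uII = (v_i, gamma_i); K = N blocks)",
               function(...) do.call(build_fhn_lattice, list(...)))

build_fhn3d <- function(eps = 0.01, delta1 = 0.2, delta2 = 0.4, a = 1.05,
                        d_gamma = 1, gamma_hat = 1, sigma_gamma = 0.6) {
  p <- mget(c("eps", "delta1", "delta2", "a", "d_gamma", "gamma_hat",
              "sigma_gamma"))
  drift <- function(t, u)
    c((u[1] - u[1]^3 / 3 - u[2]) / eps,
      u[3] * u[1] + a,
      -d_gamma * (u[3] - gamma_hat))
  cg_model(
    n_I = 1, n_II = 2,
    A0 = function(t, uI) (uI[1] - uI[1]^3 / 3) / eps,
    A1 = function(t, uI) matrix(c(-1 / eps, 0), 1, 2),
    a0 = function(t, uI) c(a, d_gamma * gamma_hat),
    a1 = function(t, uI) matrix(c(0, 0, uI[1], -d_gamma), 2, 2),
    SigmaI = function(t, uI) delta1 / sqrt(eps),
    SigmaII = function(t, uI) c(delta2, sigma_gamma),
    state_names_I = "u", state_names_II = c("v", "gamma"),
    drift_full = drift,
    name = "fhn3d", params = p, default_dt = 0.002)
}
register_model("fhn3d",
               "single-site FitzHugh-Nagumo model with stochastic gain (uI = u, uII = (v, gamma))",
               function(...) do.call(build_fhn3d, list(...)))

build_predator_prey <- function(k = 2, m = 0.8, h = 0.4, sigma0 = 0.05,
                                noise = c("saturating", "linear")) {
  noise <- match.arg(noise)
  p <- mget(c("k", "m", "h", "sigma0", "noise"))
  f <- if (noise == "saturating") function(u) sigma0 * u / sqrt(1 + u^2)
       else function(u) sigma0 * u
  drift <- function(t, u)
    c(u[1] * (1 - u[1]) - u[1] / (u[1] + h) * u[2],
      k * u[1] / (u[1] + h) * u[2] - m * u[2])
  cg_model(
    n_I = 1, n_II = 1,
    A0 = function(t, uI) uI[1] * (1 - uI[1]),
    A1 = function(t, uI) matrix(-uI[1] / (uI[1] + h), 1, 1),
    a0 = function(t, uI) 0,
    a1 = function(t, uI) matrix(k * uI[1] / (uI[1] + h) - m, 1, 1),
    SigmaI = function(t, uI) f(uI[1]),
    SigmaII = function(t, uI) 0,
    state_names_I = "u", state_names_II = "v",
    lower_I = 0, lower_II = 0,
    drift_full = drift,
    name = "predator_prey", params = p, default_dt = 0.005)
}
register_model("predator_prey",
               "stochastic predator-prey model, multiplicative noise vanishing at 0 (uI = prey u, uII = predator v)",
               function(...) do.call(build_predator_prey, list(...)))

build_sir <- function(beta = 1.2, mu1 = 0.1, mu2 = 0.2, mu3 = 0.15,
                      b = 0.2, alpha = 0.4, sigma0 = 0.05) {
  stopifnot(mu1 < min(mu2, mu3))
  p <- mget(c("beta", "mu1", "mu2", "mu3", "b", "alpha", "sigma0"))
  drift <- function(t, u)
    c(-beta * u[1] * u[2] - mu1 * u[1] + b,
      beta * u[1] * u[2] - mu2 * u[2] - alpha * u[2],
      alpha * u[2] - mu3 * u[3])
  cg_model(
    n_I = 1, n_II = 2,
    A0 = function(t, uI) -mu1 * uI[1] + b,
    A1 = function(t, uI) matrix(c(-beta * uI[1], 0), 1, 2),
    a0 = function(t, uI) c(0, 0),
    a1 = function(t, uI) matrix(c(beta * uI[1] - mu2 - alpha, alpha,
                                  0, -mu3), 2, 2),
    SigmaI = function(t, uI) sigma0 * uI[1],
    SigmaII = function(t, uI) c(0, 0),
    state_names_I = "S", state_names_II = c("I", "R"),
    lower_I = 0, lower_II = c(0, 0),
    drift_full = drift,
    name = "sir", params = p, default_dt = 0.005)
}
register_model("sir",
               "stochastically coupled SIR epidemic model (uI = S, uII = (I, R))",
               function(...) do.call(build_sir, list(...)))

build_cancer <- function(alpha = 0.3, lambda = 2, k = 1, Gamma = 1,
                         occup_n = 1, occup_c = 0.5,
                         sigma_G = 0.05, sigma_N = 0.05) {
  p <- mget(c("alpha", "lambda", "k", "Gamma", "occup_n", "occup_c",
              "sigma_G", "sigma_N"))
  drift <- function(t, u)
    c(-k^2 * u[1] + Gamma * occup_c * u[2] * (1 - u[1]),
      -alpha^2 * (occup_n + lambda * occup_c) * u[2])
  cg_model(
    n_I = 1, n_II = 1,
    A0 = function(t, uI) -k^2 * uI[1],
    A1 = function(t, uI) matrix(Gamma * occup_c * (1 - uI[1]), 1, 1),
    a0 = function(t, uI) 0,
    a1 = function(t, uI) matrix(-alpha^2 * (occup_n + lambda * occup_c), 1, 1),
    SigmaI = function(t, uI) sigma_G,
    SigmaII = function(t, uI) sigma_N,
    state_names_I = "G", state_names_II = "N",
    lower_I = 0, lower_II = 0,
    drift_full = drift,
    name = "cancer", params = p, default_dt = 0.005)
}
register_model("cancer",
               "nutrient-limited avascular tumour growth model (uI = growth factor G, uII = nutrient N)",
               function(...) do.call(build_cancer, list(...)))

## ---- SPEKF family and other filtering models -----------------------------

build_spekf <- function(sigma_u = 1, d_gamma = 0.8, sigma_gamma = 2,
                        gamma_hat = 2.5, d_omega = 0.6, sigma_omega = 1,
                        omega_hat = 2, d_b = 0.8, sigma_b = 1, b_hat = 0,
                        forcing = function(t) 2 * exp(0.2i * t)) {
  p <- mget(c("sigma_u", "d_gamma", "sigma_gamma", "gamma_hat", "d_omega",
              "sigma_omega", "omega_hat", "d_b", "sigma_b", "b_hat"))
  # complex state interleaved as real coordinates: uI = (Re u, Im u),
  # uII = (gamma, omega, Re b, Im b)
  drift <- function(t, u) {
    F <- forcing(t)
    ur <- u[1]; ui <- u[2]; g <- u[3]; om <- u[4]; br <- u[5]; bi <- u[6]
    c(-g * ur - om * ui + Re(F) + br,
      om * ur - g * ui + Im(F) + bi,
      -d_gamma * (g - gamma_hat),
      -d_omega * (om - omega_hat),
      -d_b * (br - Re(b_hat)),
      -d_b * (bi - Im(b_hat)))
  }
  s2 <- sqrt(2)
  cg_model(
    n_I = 2, n_II = 4,
    A0 = function(t, uI) { F <- forcing(t); c(Re(F), Im(F)) },
    A1 = function(t, uI) matrix(c(-uI[1], -uI[2],
                                  -uI[2], uI[1],
                                  1, 0,
                                  0, 1), 2, 4),
    a0 = function(t, uI) c(d_gamma * gamma_hat, d_omega * omega_hat,
                           d_b * Re(b_hat), d_b * Im(b_hat)),
    a1 = function(t, uI) diag(c(-d_gamma, -d_omega, -d_b, -d_b)),
    SigmaI = function(t, uI) rep(sigma_u / s2, 2),
    SigmaII = function(t, uI) c(sigma_gamma, sigma_omega,
                                sigma_b / s2, sigma_b / s2),
    state_names_I = c("u_re", "u_im"),
    state_names_II = c("gamma", "omega", "b_re", "b_im"),
    drift_full = drift,
    name = "spekf", params = p, default_dt = 0.005)
}
register_model("spekf",
               "stochastic parameterized extended Kalman filter model: observed complex mode with hidden OU damping/phase/forcing",
               function(...) do.call(build_spekf, list(...)))

build_msm <- function(sigma_u = 1, gamma_hat = 2.5, omega_hat = 2, b_hat = 0,
                      forcing = function(t) 2 * exp(0.2i * t)) {
  p <- mget(c("sigma_u", "gamma_hat", "omega_hat", "b_hat"))
  drift <- function(t, u) {
    F <- forcing(t)
    c(-gamma_hat * u[1] - omega_hat * u[2] + Re(F) + Re(b_hat),
      omega_hat * u[1] - gamma_hat * u[2] + Im(F) + Im(b_hat))
  }
  s2 <- sqrt(2)
  cg_model(
    n_I = 2, n_II = 0,
    A0 = drift,
    A1 = function(t, uI) matrix(0, 2, 0),
    a0 = function(t, uI) numeric(0),
    a1 = function(t, uI) matrix(0, 0, 0),
    SigmaI = function(t, uI) rep(sigma_u / s2, 2),
    SigmaII = function(t, uI) numeric(0),
    state_names_I = c("u_re", "u_im"),
    drift_full = drift,
    name = "msm", params = p, default_dt = 0.005)
}
register_model("msm", "mean stochastic model (linear Gaussian baseline for the SPEKF model)",
               function(...) do.call(build_msm, list(...)))

build_spekf_m <- function(sigma_gamma = 0.5, d_gamma = 0.5, gamma_hat = 1,
                          sigma_u = 0.5, F = 2) {
  p <- mget(c("sigma_gamma", "d_gamma", "gamma_hat", "sigma_u", "F"))
  drift <- function(t, u) c(-u[2] * u[1] + F,
                            -d_gamma * (u[2] - gamma_hat))
  cg_model(
    n_I = 1, n_II = 1,
    A0 = function(t, uI) F,
    A1 = function(t, uI) matrix(-uI[1], 1, 1),
    a0 = function(t, uI) d_gamma * gamma_hat,
    a1 = function(t, uI) matrix(-d_gamma, 1, 1),
    SigmaI = function(t, uI) sigma_u,
    SigmaII = function(t, uI) sigma_gamma,
    state_names_I = "u", state_names_II = "gamma",
    drift_full = drift,
    name = "spekf_m", params = p, default_dt = 0.005)
}
register_model("spekf_m",
               "SPEKF-M model: real observed mode with hidden OU damping (uI = u, uII = gamma)",
               function(...) do.call(build_spekf_m, list(...)))

build_surface_wind <- function(Pi_u = 0.5, cdh = 0.1, tau = 5,
                               sigma_eta = 0.3, sigma_u = 0.1,
                               sigma_v = 0.1) {
  p <- mget(c("Pi_u", "cdh", "tau", "sigma_eta", "sigma_u", "sigma_v"))
  drift <- function(t, u) {
    sp <- sqrt(u[1]^2 + u[2]^2)
    c(Pi_u - cdh * sp * u[1] + u[3],
      -cdh * sp * u[2] + u[4],
      -u[3] / tau, -u[4] / tau)
  }
  cg_model(
    n_I = 2, n_II = 2,
    A0 = function(t, uI) {
      sp <- sqrt(uI[1]^2 + uI[2]^2)
      c(Pi_u - cdh * sp * uI[1], -cdh * sp * uI[2])
    },
    A1 = function(t, uI) diag(1, 2),
    a0 = function(t, uI) c(0, 0),
    a1 = function(t, uI) diag(-1 / tau, 2),
    SigmaI = function(t, uI) c(sigma_u, sigma_v),
    SigmaII = function(t, uI) rep(sigma_eta, 2),
    state_names_I = c("u", "v"), state_names_II = c("eta_u", "eta_v"),
    drift_full = drift,
    name = "surface_wind", params = p, default_dt = 0.005)
}
register_model("surface_wind",
               "idealized surface wind model with OU ageostrophic forcing (uI = (u,v), uII = (eta_u, eta_v))",
               function(...) do.call(build_surface_wind, list(...)))

dyad_regimes <- list(I = list(d_u = 0.8, d_v = 0.8, gamma = 1.2, F_u = 1),
                     II = list(d_u = 0.8, d_v = 0.8, gamma = 1.2, F_u = 0))

build_dyad <- function(regime = "I", sigma_u = 0.2, sigma_v = 2, ...) {
  p <- merge_params(dyad_regimes[[match.arg(regime, c("I", "II"))]], list(...))
  p$sigma_u <- sigma_u; p$sigma_v <- sigma_v
  with(p, {
    drift <- function(t, u) c(-d_u * u[1] + gamma * u[1] * u[2] + F_u,
                              -d_v * u[2] - gamma * u[1]^2)
    cg_model(
      n_I = 1, n_II = 1,
      A0 = function(t, uI) -d_u * uI[1] + F_u,
      A1 = function(t, uI) matrix(gamma * uI[1], 1, 1),
      a0 = function(t, uI) -gamma * uI[1]^2,
      a1 = function(t, uI) matrix(-d_v, 1, 1),
      SigmaI = function(t, uI) sigma_u,
      SigmaII = function(t, uI) sigma_v,
      state_names_I = "u", state_names_II = "v",
      drift_full = drift, physics_constrained = TRUE,
      name = "dyad", params = p, default_dt = 0.005)
  })
}
register_model("dyad",
               "physics-constrained dyad model of mean-flow / fluctuation interaction (uI = u, uII = v)",
               function(...) do.call(build_dyad, list(...)))

build_ou <- function(d = 0.5, mean = 1, sigma = 0.5) {
  p <- mget(c("d", "mean", "sigma"))
  drift <- function(t, u) -d * (u - mean)
  cg_model(
    n_I = 1, n_II = 0,
    A0 = function(t, uI) -d * (uI - mean),
    A1 = function(t, uI) matrix(0, 1, 0),
    a0 = function(t, uI) numeric(0),
    a1 = function(t, uI) matrix(0, 0, 0),
    SigmaI = function(t, uI) sigma,
    SigmaII = function(t, uI) numeric(0),
    state_names_I = "gamma",
    drift_full = drift,
    name = "ou", params = p, default_dt = 0.005)
}
register_model("ou",
               "scalar Ornstein-Uhlenbeck process (stationary variance sigma^2 / (2 d))",
               function(...) do.call(build_ou, list(...)))
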