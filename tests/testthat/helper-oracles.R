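# Shared fixtures and independent numeric oracles for the test suite.

ex_nsfd <- worked_example("nsfd_ns")
ex_euler <- worked_example("euler_ns")

# flip-critical companion of the Euler NS example: same parameters with the
# half-saturation constant moved to its closed-form flip-critical value at
# the stated step size (cross-checked by bisection in the tests)
flip_eta <- 0.736811507576121
flip_params <- function() {
  base <- ex_euler$params
  a_crit <- pd_critical_a(base, flip_eta)
  suppressWarnings(plankton_params(r = base$r, k = base$k, alpha = base$alpha,
                                   a = a_crit, m = base$m, beta = base$beta,
                                   rho = base$rho, delta = base$delta))
}

# random parameter set satisfying the interior-existence condition:
# beta > delta + rho and k r (beta - delta - rho) > a delta (k m + r)
rand_admissible_params <- function() {
  repeat {
    r <- runif(1, 0.5, 4); k <- runif(1, 0.2, 2)
    alpha <- runif(1, 0.2, 4); a <- runif(1, 0.1, 1.5)
    m <- runif(1, 0.05, 1); delta <- runif(1, 0.05, 1)
    rho <- runif(1, 0.05, 2)
    beta_min <- delta + rho + a * delta * (k * m + r) / (k * r)
    beta <- beta_min * runif(1, 1.05, 2.5)
    pp <- suppressWarnings(plankton_params(r = r, k = k, alpha = alpha, a = a,
                                           m = m, beta = beta, rho = rho,
                                           delta = delta))
    fp <- fixed_points(pp)
    if (fp$interior_exists) return(pp)
  }
}

# one step of the selected map as a plain function of a length-2 state
map_eval <- function(map_kind, params, eta, s, theta = NULL) {
  switch(map_kind,
         euler = as.numeric(euler_step(params, eta, s)),
         nsfd = as.numeric(nsfd_step(params, eta, s)),
         hybrid = as.numeric(hybrid_step(params, eta, theta, s)))
}

# Richardson-extrapolated central-difference Jacobian oracle
num_jacobian <- function(map_kind, params, eta, s, theta = NULL) {
  s <- as.numeric(s)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- 1e-5 * max(1, abs(s[j]))
    cd <- function(hh) {
      sp <- s; sm <- s
      sp[j] <- sp[j] + hh; sm[j] <- max(sm[j] - hh, 0)
      (map_eval(map_kind, params, eta, sp, theta) -
         map_eval(map_kind, params, eta, sm, theta)) / (sp[j] - sm[j])
    }
    J[, j] <- (4 * cd(h / 2) - cd(h)) / 3
  }
  J
}

# eigenvalue-modulus classification oracle (independent of the Jury route)
modulus_classify <- function(T, D, tol = 1e-9) {
  disc <- T^2 - 4 * D
  mods <- if (disc < 0) rep(sqrt(D), 2) else
    abs(c((T + sqrt(disc)) / 2, (T - sqrt(disc)) / 2))
  if (any(abs(mods - 1) < tol)) "non-hyperbolic"
  else if (all(mods < 1)) "sink"
  else if (all(mods > 1)) "source"
  else "saddle"
}

# evaluate a 4x4 bivariate coefficient matrix at (x, y)
poly_val <- function(cm, x, y) {
  s <- 0
  for (i in 0:3) for (j in 0:3) s <- s + cm[i + 1, j + 1] * x^i * y^j
  s
}
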