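test_that("NSFD and Euler Jacobians at extinction have the closed diagonal form", {
  pp <- ex_nsfd$params; eta <- 0.3
  Jn <- map_jacobian("nsfd", pp, eta, c(0, 0))
  expect_equal(Jn, matrix(c(1 + pp$r * eta, 0, 0, 1 / (1 + pp$delta * eta)),
                          2, 2, byrow = TRUE), tolerance = 1e-14)
  Je <- map_jacobian("euler", pp, eta, c(0, 0))
  expect_equal(Je, matrix(c(1 + pp$r * eta, 0, 0, 1 - pp$delta * eta),
                          2, 2, byrow = TRUE), tolerance = 1e-14)
})

test_that("Euler Jacobian at the coexistence point matches the published matrix", {
  fp <- fixed_points(ex_euler$params)
  J <- map_jacobian("euler", ex_euler$params, ex_euler$eta_printed, fp$interior)
  Jpub <- ns_example_polynomials()$jacobian_printed
  expect_equal(J, Jpub, tolerance = 1e-4)
  cp <- char_poly(J)
  expect_equal(cp$T, 1.8281041990948645, tolerance = 1e-10)
  expect_equal(cp$D, 1, tolerance = 1e-10)
})

test_that("char_poly returns trace and determinant", {
  cp <- char_poly(diag(2))
  expect_equal(cp$T, 2); expect_equal(cp$D, 1)
  J <- matrix(c(197.876, -45.7371, -4.30368, 1), 2, 2, byrow = TRUE)
  expect_equal(char_poly(J)$T, 198.876, tolerance = 1e-12)
})

test_that("Jury classification matches worked cases and orders eigenvalues", {
  expect_identical(jury_classify(list(T = 0, D = 0.5))$class, "sink")
  expect_identical(jury_classify(list(T = 0, D = 2))$class, "source")
  sad <- jury_classify(list(T = -1.5, D = 0.3))
  expect_identical(sad$class, "saddle")
  expect_equal(sort(Re(sad$eigenvalues)), c(-1.2623475, -0.2376525),
               tolerance = 1e-6)
  nh <- jury_classify(list(T = 1.8281041990948645, D = 1))
  expect_identical(nh$class, "non-hyperbolic")
  expect_gte(Im(nh$eigenvalues[1]), 0)
  # real pair ordering: larger modulus first
  rl <- jury_classify(list(T = 0.5, D = -0.5))
  expect_gte(Mod(rl$eigenvalues[1]), Mod(rl$eigenvalues[2]))
})

test_that("Jury verdict equals the eigenvalue-modulus oracle when F(1) > 0", {
  set.seed(41)
  n_checked <- 0
  while (n_checked < 2000) {
    T <- runif(1, -4, 4); D <- runif(1, -2, 3)
    if (1 - T + D <= 0) next
    n_checked <- n_checked + 1
    expect_identical(jury_classify(list(T = T, D = D))$class,
                     modulus_classify(T, D))
  }
})

test_that("fallback classification is flagged when F(1) <= 0", {
  # one multiplier beyond +1: F(1) < 0
  jc <- jury_classify(list(T = 198.876, D = 1.03853))
  expect_false(jc$lemma_hypothesis_ok)
  expect_identical(jc$class, "saddle")
})

test_that("analytic Jacobians agree with the finite-difference oracle", {
  set.seed(51)
  for (q in 1:150) {
    pp <- rand_admissible_params()
    eta <- runif(1, 0.05, 1)
    s <- c(runif(1, 0.05, 2), runif(1, 0.05, 2))
    for (mk in c("euler", "nsfd", "hybrid")) {
      th <- if (mk == "hybrid") runif(1, 0.2, 1) else NULL
      Ja <- map_jacobian(mk, pp, eta, s, theta = th)
      Jn <- num_jacobian(mk, pp, eta, s, theta = th)
      expect_lt(max(abs(Ja - Jn) / pmax(abs(Ja), 1e-6)), 1e-6)
    }
  }
})

test_that("fixed-point classification matches the closed-form criteria", {
  # extinction point of the NSFD map is always a saddle
  set.seed(61)
  for (q in 1:20) {
    pp <- rand_admissible_params()
    rep0 <- classify_fixed_point("nsfd", pp, runif(1, 0.05, 1), "trivial")
    expect_identical(rep0$class, "saddle")
  }
  # boundary point: closed criterion vs eigenvalues, both branches
  repb <- classify_fixed_point("nsfd", ex_nsfd$params, 0.3, "boundary")
  expect_true(repb$criterion_agrees)
  lhs <- with(ex_nsfd$params, k * r * beta)
  rhs <- with(ex_nsfd$params, a * delta * (k * m + r) + k * r * (delta + rho))
  expect_identical(repb$class, if (lhs < rhs) "sink" else "saddle")
  # interior NSFD point below criticality is a sink
  repi <- classify_fixed_point("nsfd", ex_nsfd$params, 0.2, "interior")
  expect_identical(repi$class, "sink")
  expect_true(all(repi$moduli < 1))
})

test_that("closed-form U values equal F(1), F(-1) of the interior Jacobian", {
  set.seed(71)
  for (q in 1:100) {
    pp <- rand_admissible_params()
    eta <- runif(1, 0.01, 1)
    U <- U_values(pp, eta)
    fp <- fixed_points(pp)
    cp <- char_poly(map_jacobian("nsfd", pp, eta, fp$interior))
    expect_lt(abs(U[["U1"]] - (1 - cp$T + cp$D)), 1e-8)
    expect_lt(abs(U[["Um1"]] - (1 + cp$T + cp$D)), 1e-8)
    expect_gt(U[["U1"]], 0)
    expect_gt(U[["Um1"]], 0)
  }
})

test_that("controlled characteristic polynomial matches the hybrid Jacobian", {
  fp <- fixed_points(ex_euler$params)
  eta <- ex_euler$eta_printed
  for (th in c(0.11, 0.4, 0.77, 1)) {
    cpc <- controlled_char_poly(ex_euler$params, eta, th)
    cpj <- char_poly(map_jacobian("hybrid", ex_euler$params, eta, fp$interior,
                                  theta = th))
    expect_lt(abs(cpc$T - cpj$T), 1e-8)
    expect_lt(abs(cpc$D - cpj$D), 1e-8)
  }
  # at theta = 1 it reduces to the uncontrolled Euler polynomial
  cp1 <- controlled_char_poly(ex_euler$params, eta, 1)
  cpe <- char_poly(map_jacobian("euler", ex_euler$params, eta, fp$interior))
  expect_equal(cp1$T, cpe$T, tolerance = 1e-12)
  expect_equal(cp1$D, cpe$D, tolerance = 1e-12)
  expect_equal(cp1$D, 1, tolerance = 1e-10)
})

test_that("controlled determinant and stability verdict do not involve alpha", {
  base <- ex_euler$params
  mod <- suppressWarnings(plankton_params(r = base$r, k = base$k,
                                          alpha = 2.5 * base$alpha, a = base$a,
                                          m = base$m, beta = base$beta,
                                          rho = base$rho, delta = base$delta))
  eta <- ex_euler$eta_printed
  for (th in c(0.3, 0.9)) {
    expect_equal(controlled_char_poly(base, eta, th)$D,
                 controlled_char_poly(mod, eta, th)$D, tolerance = 1e-14)
    expect_identical(hybrid_interior_stable(base, eta, th)$stable,
                     hybrid_interior_stable(mod, eta, th)$stable)
  }
})

test_that("closed-form hybrid stability agrees with Jury sink verdict", {
  eta <- ex_euler$eta_printed
  st <- hybrid_interior_stable(ex_euler$params, eta, 0.1)
  expect_true(st$applicable)
  expect_true(st$stable)
  expect_identical(jury_classify(controlled_char_poly(ex_euler$params, eta,
                                                      0.1))$class, "sink")
  # at theta = 1 and the critical step size the pair sits on the unit circle
  st1 <- hybrid_interior_stable(ex_euler$params, eta, 1)
  expect_false(st1$stable)
  expect_identical(jury_classify(controlled_char_poly(ex_euler$params, eta,
                                                      1))$class,
                   "non-hyperbolic")
  # grid check: lemma verdict tracks the Jury verdict where applicable
  for (th in seq(0.05, 0.95, by = 0.1)) {
    st_th <- hybrid_interior_stable(ex_euler$params, eta, th)
    if (st_th$applicable) {
      cls <- jury_classify(controlled_char_poly(ex_euler$params, eta,
                                                th))$class
      expect_identical(st_th$stable, cls == "sink")
    }
  }
})
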