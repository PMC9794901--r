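test_that("closed-form and bisection critical step sizes agree (NSFD)", {
  cf <- ns_critical_eta(ex_nsfd$params)
  expect_equal(cf$eta_hat, 0.4099821209080988, tolerance = 1e-10)
  num <- ns_critical_eta_numeric("nsfd", ex_nsfd$params)
  expect_lt(abs(cf$eta_hat - num$eta_crit) / num$eta_crit, 1e-10)
  expect_true(num$complex_pair)
  expect_lt(max(abs(Mod(num$multipliers) - 1)), 1e-8)
  # within 1% of the published digit string (known source-internal mismatch)
  expect_lt(abs(cf$eta_hat - ex_nsfd$eta_printed) / ex_nsfd$eta_printed, 0.01)
  # determinant equals 1 at the closed-form value
  fp <- fixed_points(ex_nsfd$params)
  D <- char_poly(map_jacobian("nsfd", ex_nsfd$params, cf$eta_hat,
                              fp$interior))$D
  expect_equal(D, 1, tolerance = 1e-6)
})

test_that("bisection recovers the published Euler critical step size", {
  num <- ns_critical_eta_numeric("euler", ex_euler$params)
  expect_equal(num$eta_crit, 0.4681150757612096, tolerance = 1e-6)
  expect_true(num$complex_pair)
  expect_error(ns_critical_eta_numeric("euler", ex_euler$params,
                                       bracket = c(0.01, 0.1)),
               "no sign change")
})

test_that("closed-form critical eta requires an interior point", {
  pp <- suppressWarnings(plankton_params(r = 1, k = 1, alpha = 1, a = 1,
                                         m = 1, beta = 0.3, rho = 0.3,
                                         delta = 0.2))
  expect_error(ns_critical_eta(pp), "interior fixed point")
})

test_that("Taylor expansions carry the Jacobian as degree-1 block and
           approximate the map to fourth order", {
  set.seed(81)
  for (q in 1:20) {
    pp <- rand_admissible_params()
    eta <- runif(1, 0.05, 1)
    s <- c(runif(1, 0.1, 1.5), runif(1, 0.1, 1.5))
    for (mk in c("euler", "nsfd")) {
      tay <- taylor_expand(mk, pp, eta, s)
      J <- map_jacobian(mk, pp, eta, s)
      expect_equal(c(tay$cp[2, 1], tay$cp[1, 2]), c(J[1, 1], J[1, 2]),
                   tolerance = 1e-10)
      expect_equal(c(tay$cz[2, 1], tay$cz[1, 2]), c(J[2, 1], J[2, 2]),
                   tolerance = 1e-10)
      # quartic remainder: residual shrinks ~16x when displacement halves
      resid <- function(d) {
        target <- map_eval(mk, pp, eta, s + d)
        approx <- c(s[1] + poly_val(tay$cp, d[1], d[2]),
                    s[2] + poly_val(tay$cz, d[1], d[2]))
        max(abs(target - approx))
      }
      d <- c(8e-3, -6e-3)
      r1 <- resid(d); r2 <- resid(d / 2)
      expect_lt(r2, r1 / 8 + 1e-14)
    }
  }
})

test_that("Euler Taylor expansion at the NS point reproduces the published J3", {
  fp <- fixed_points(ex_euler$params)
  tay <- taylor_expand("euler", ex_euler$params, ex_euler$eta_printed,
                       fp$interior)
  expect_lt(max(abs(tay$const)), 1e-12)
  Jpub <- ns_example_polynomials()$jacobian_printed
  expect_equal(matrix(c(tay$cp[2, 1], tay$cp[1, 2],
                        tay$cz[2, 1], tay$cz[1, 2]), 2, 2, byrow = TRUE),
               Jpub, tolerance = 1e-4)
})

test_that("normal form has the rotation linear block and round-trips", {
  fp <- fixed_points(ex_euler$params)
  num <- ns_critical_eta_numeric("euler", ex_euler$params)
  tay <- taylor_expand("euler", ex_euler$params, num$eta_crit, fp$interior)
  nf <- normal_form(tay, num$multipliers[1])
  J <- map_jacobian("euler", ex_euler$params, num$eta_crit, fp$interior)
  rot <- solve(nf$Tmat) %*% J %*% nf$Tmat
  expect_equal(rot, matrix(c(nf$lambda, nf$omega, -nf$omega, nf$lambda), 2, 2),
               tolerance = 1e-8)
  # transforming the normal-form nonlinearity back with the inverse
  # similarity recovers the original nonlinear Taylor part
  Ti <- solve(nf$Tmat)
  Ft_back <- planktomaps:::poly_compose_linear(nf$Ft, Ti)
  Gt_back <- planktomaps:::poly_compose_linear(nf$Gt, Ti)
  h1_back <- nf$Tmat[1, 1] * Ft_back + nf$Tmat[1, 2] * Gt_back
  h2_back <- nf$Tmat[2, 1] * Ft_back + nf$Tmat[2, 2] * Gt_back
  h1 <- planktomaps:::poly_keep_degrees(tay$cp, 2:3)
  h2 <- planktomaps:::poly_keep_degrees(tay$cz, 2:3)
  expect_equal(planktomaps:::poly_keep_degrees(h1_back, 2:3), h1,
               tolerance = 1e-10)
  expect_equal(planktomaps:::poly_keep_degrees(h2_back, 2:3), h2,
               tolerance = 1e-10)
  expect_error(normal_form(tay, complex(real = 1.2, imaginary = 0.9)),
               "modulus")
})

test_that("xi layer reproduces the published coefficients from the published
           polynomials", {
  fx <- ns_example_polynomials()
  xi <- xi_coefficients(fx)
  for (nm in names(fx$xi_printed)) {
    expect_lt(Mod(xi[[nm]] - fx$xi_printed[[nm]]) / Mod(fx$xi_printed[[nm]]),
              1e-4)
  }
  # zero polynomials give zero coefficients
  z4 <- matrix(0, 4, 4)
  expect_true(all(xi_coefficients(list(Ft = z4, Gt = z4)) == 0))
})

test_that("Lyapunov quantity matches its published value and reductions", {
  fx <- ns_example_polynomials()
  xi <- xi_coefficients(fx)
  expect_equal(lyapunov_quantity(xi, fx$rho1), fx$F_printed,
               tolerance = 1e-3)
  zero_xi <- c(xi20 = 0 + 0i, xi11 = 0 + 0i, xi02 = 0 + 0i, xi21 = 0 + 0i)
  expect_equal(lyapunov_quantity(zero_xi, fx$rho1), 0)
  only21 <- c(xi20 = 0 + 0i, xi11 = 0 + 0i, xi02 = 0 + 0i, xi21 = 1 + 0i)
  expect_equal(lyapunov_quantity(only21, fx$rho1), Re(Conj(fx$rho1)),
               tolerance = 1e-12)
})

test_that("transversality closed form matches the finite-difference slope", {
  cf <- ns_critical_eta(ex_nsfd$params)
  tv <- ns_transversality(ex_nsfd$params, cf$eta_hat, "nsfd")
  expect_false(tv$degenerate)
  expect_lt(abs(tv$slope - tv$fd_slope) / abs(tv$fd_slope), 1e-4)
  # Euler example: modulus straddles 1 on either side of criticality
  fp <- fixed_points(ex_euler$params)
  modat <- function(eta) {
    cp <- char_poly(map_jacobian("euler", ex_euler$params, eta, fp$interior))
    sqrt(cp$D)
  }
  expect_gt(modat(0.47), 1)
  expect_lt(modat(0.46), 1)
  tve <- ns_transversality(ex_euler$params, 0.4681150757612096, "euler")
  expect_lt(abs(tve$slope - tve$fd_slope) / abs(tve$fd_slope), 1e-4)
})

test_that("ns_report assembles a consistent record for both maps", {
  repe <- ns_report("euler", ex_euler$params)
  expect_true(repe$criticality_found)
  expect_equal(repe$eta_hat, 0.4681150757612096, tolerance = 1e-6)
  expect_lt(repe$F_quantity, 0)
  expect_match(repe$direction, "attracting")
  expect_true(repe$nondegeneracy_ok)
  expect_true(repe$transversality_ok)

  repn <- ns_report("nsfd", ex_nsfd$params)
  expect_true(repn$criticality_found)
  expect_gt(repn$eta_hat, 0); expect_lt(repn$eta_hat, 1)
  expect_equal(repn$eta_hat, repn$eta_hat_closed_form, tolerance = 1e-8)

  pp <- suppressWarnings(plankton_params(r = 1, k = 1, alpha = 1, a = 1,
                                         m = 1, beta = 0.3, rho = 0.3,
                                         delta = 0.2))
  rep0 <- ns_report("euler", pp)
  expect_false(rep0$interior_exists)
})
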