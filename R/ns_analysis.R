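# Neimark-Sacker machinery: critical step size, transversality,
# similarity transform to normal form, xi-coefficients and the first
# Lyapunov quantity with bifurcation direction.

#' Closed-form critical step size for the NSFD map
#'
#' The coexistence point of the NSFD map has a complex multiplier pair on the
#' unit circle at
#' \deqn{\hat\eta = \frac{(\beta-\rho)\,[a(km+r)(\beta+\delta-\rho) - kr(\beta-\delta-\rho)]}
#'   {rk(\beta-\delta-\rho)(\beta^2-2\beta\rho+\rho(\delta+\rho)) -
#'    a\delta(2\beta^2-3\beta\rho+\rho(\delta+\rho))(r+km)}.}
#' The companion modulus inequality (which guarantees the pair is genuinely
#' complex) is evaluated and reported alongside.
#'
#' @inheritParams U_values
#' @return List with \code{eta_hat} and \code{modulus_condition_ok}.
#' @export
ns_critical_eta <- function(params) {
  check_params(params)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  r <- params$r; k <- params$k; a <- params$a; m <- params$m
  be <- params$beta; rho <- params$rho; de <- params$delta
  num <- (be - rho) * (a * (k * m + r) * (be + de - rho) - k * r * (be - de - rho))
  den <- r * k * (be - de - rho) * (be^2 - 2 * be * rho + rho * (de + rho)) -
    a * de * (2 * be^2 - 3 * be * rho + rho * (de + rho)) * (r + k * m)
  if (abs(den) < 1e-14)
    stop("degenerate: closed-form denominator vanishes", call. = FALSE)
  eta_hat <- num / den
  ok <- NA
  if (is.finite(eta_hat) && eta_hat > 0) {
    A <- a * k * m + (a + k) * r
    lhs <- A^2 * de / (be - rho)^2 +
      4 * a * (k * m + r) * A / (be - rho) +
      4 * k * de * (1 + r * eta_hat) *
        (a * (k * m + r) + k * r * (1 + be * eta_hat)) /
        (be + be * de * eta_hat - rho) +
      4 * a^2 * (k * m + r)^2 * de / (be - de - rho)^2
    rhs <- 4 * k^2 * r * (1 + r * eta_hat) +
      4 * a * (k * m + r) * A / (be - de - rho)
    ok <- lhs < rhs
  }
  list(eta_hat = eta_hat, modulus_condition_ok = ok)
}

#' Numerical critical step size via determinant bisection
#'
#' Locates the \eqn{\eta} at which the selected map's Jacobian determinant at
#' the interior fixed point equals 1 (a complex pair crossing the unit
#' circle), by root bracketing and bisection to \eqn{|\Delta\eta| \le 10^{-12}}.
#'
#' @inheritParams map_jacobian
#' @param bracket length-2 numeric search interval for \eqn{\eta}.
#' @return List with \code{eta_crit}, the multipliers there, and
#'   \code{complex_pair} (TRUE when \eqn{T^2 - 4D < 0} at the root).
#' @export
ns_critical_eta_numeric <- function(map_kind, params, bracket = c(0.01, 1)) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd"))
  check_params(params)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  pt <- fps$interior
  f <- function(eta) char_poly(map_jacobian(map_kind, params, eta, pt))$D - 1
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("no sign change of det - 1 on the bracket", call. = FALSE)
  root <- stats::uniroot(f, bracket, tol = 1e-13)$root
  cp <- char_poly(map_jacobian(map_kind, params, root, pt))
  ev <- char_roots(cp$T, cp$D)
  list(eta_crit = root, multipliers = ev,
       complex_pair = cp$T^2 - 4 * cp$D < 0)
}

#' Similarity transform of a Taylor expansion to rotation normal form
#'
#' Given a degree-3 Taylor expansion of a planar map about a fixed point with
#' a complex multiplier pair \eqn{\lambda \pm i\omega} on the unit circle,
#' applies the similarity transformation with matrix columns
#' \eqn{(\theta_{12}, 0)} and \eqn{(\lambda-\theta_{11}, -\omega)} so the
#' linear part becomes the rotation-like block
#' \eqn{[[\lambda, -\omega], [\omega, \lambda]]}. The nonlinear remainders
#' are returned as coefficient matrices in \eqn{(u, v)}.
#'
#' @param taylor a \code{\link{map_taylor}} object at a fixed point.
#' @param multiplier the critical multiplier \eqn{\lambda + i\omega}
#'   (positive imaginary part); \eqn{|\lambda + i\omega|} must be within
#'   \code{1e-6} of 1.
#' @return Object of class \code{ns_normal_form}: list with \code{lambda},
#'   \code{omega}, \code{Ft}, \code{Gt} (4x4 coefficient matrices of the
#'   transformed nonlinear parts), and the transform matrix \code{Tmat}.
#' @export
normal_form <- function(taylor, multiplier) {
  stopifnot(inherits(taylor, "map_taylor"))
  lam <- Re(multiplier); om <- Im(multiplier)
  if (om <= 1e-12)
    stop("real multipliers: the similarity transform needs a complex pair",
         call. = FALSE)
  if (abs(Mod(multiplier) - 1) > 1e-6)
    stop("multiplier modulus differs from 1 by more than 1e-6", call. = FALSE)
  th11 <- poly_partial(taylor$cp, 1, 0)
  th12 <- poly_partial(taylor$cp, 0, 1)
  if (abs(th12) < 1e-14)
    stop("degenerate transform: off-diagonal Jacobian entry vanishes", call. = FALSE)
  Tmat <- matrix(c(th12, lam - th11, 0, -om), 2, 2)
  Tinv <- solve(Tmat)
  h1 <- poly_keep_degrees(taylor$cp, 2:3)
  h2 <- poly_keep_degrees(taylor$cz, 2:3)
  h1u <- poly_compose_linear(h1, Tmat)
  h2u <- poly_compose_linear(h2, Tmat)
  Ft <- Tinv[1, 1] * h1u + Tinv[1, 2] * h2u
  Gt <- Tinv[2, 1] * h1u + Tinv[2, 2] * h2u
  structure(list(lambda = lam, omega = om, Ft = Ft, Gt = Gt, Tmat = Tmat),
            class = "ns_normal_form")
}

#' Normal-form coefficients for the Neimark-Sacker Lyapunov quantity
#'
#' The four complex combinations of second and third partial derivatives of
#' the transformed map components \eqn{\tilde F, \tilde G} at the origin:
#' \deqn{\xi_{20} = \tfrac18[\tilde F_{uu} - \tilde F_{vv} + 2\tilde G_{uv}
#'   + i(\tilde G_{uu} - \tilde G_{vv} - 2\tilde F_{uv})],}
#' \eqn{\xi_{11}} (quarter combination), \eqn{\xi_{02}} (eighth) and
#' \eqn{\xi_{21}} (sixteenth, third order).
#'
#' @param nf an \code{\link{normal_form}} result, or any list with 4x4
#'   coefficient matrices \code{Ft}, \code{Gt}.
#' @return Named complex vector \code{c(xi20, xi11, xi02, xi21)}.
#' @export
xi_coefficients <- function(nf) {
  Ft <- nf$Ft; Gt <- nf$Gt
  Xuu <- poly_partial(Ft, 2, 0); Xvv <- poly_partial(Ft, 0, 2)
  Xuv <- poly_partial(Ft, 1, 1)
  Yuu <- poly_partial(Gt, 2, 0); Yvv <- poly_partial(Gt, 0, 2)
  Yuv <- poly_partial(Gt, 1, 1)
  xi20 <- complex(real = Xuu - Xvv + 2 * Yuv,
                  imaginary = Yuu - Yvv - 2 * Xuv) / 8
  xi11 <- complex(real = Xuu + Xvv, imaginary = Yuu + Yvv) / 4
  xi02 <- complex(real = Xuu - Xvv - 2 * Yuv,
                  imaginary = Yuu - Yvv + 2 * Xuv) / 8
  xi21 <- complex(real = poly_partial(Ft, 3, 0) + poly_partial(Ft, 1, 2) +
                    poly_partial(Gt, 2, 1) + poly_partial(Gt, 0, 3),
                  imaginary = poly_partial(Gt, 3, 0) + poly_partial(Gt, 1, 2) -
                    poly_partial(Ft, 2, 1) - poly_partial(Ft, 0, 3)) / 16
  c(xi20 = xi20, xi11 = xi11, xi02 = xi02, xi21 = xi21)
}

#' First Lyapunov quantity of the Neimark-Sacker bifurcation
#'
#' \deqn{\digamma = -\mathrm{Re}\Big[\frac{(1-2\varrho_1)\varrho_2^2}{1-\varrho_1}
#'   \xi_{20}\xi_{11}\Big] - \tfrac12|\xi_{11}|^2 - |\xi_{02}|^2 +
#'   \mathrm{Re}(\varrho_2 \xi_{21}).}
#' Negative values give a supercritical bifurcation (an attracting invariant
#' closed curve is born past criticality); positive values a subcritical
#' (repelling) one.
#'
#' @param xi named complex vector as returned by \code{\link{xi_coefficients}}.
#' @param rho1 critical multiplier with positive imaginary part,
#'   \eqn{|\varrho_1| = 1} within \code{1e-6}.
#' @param rho2 its conjugate (default).
#' @return The real quantity \eqn{\digamma}.
#' @export
lyapunov_quantity <- function(xi, rho1, rho2 = Conj(rho1)) {
  if (abs(Mod(rho1) - 1) > 1e-6)
    stop("|rho1| must equal 1 within 1e-6", call. = FALSE)
  -Re((1 - 2 * rho1) * rho2^2 / (1 - rho1) * xi[["xi20"]] * xi[["xi11"]]) -
    0.5 * Mod(xi[["xi11"]])^2 - Mod(xi[["xi02"]])^2 +
    Re(rho2 * xi[["xi21"]])
}

#' Transversality of the multiplier modulus at NS criticality
#'
#' At a complex pair the squared multiplier modulus equals the Jacobian
#' determinant, so the crossing speed is \eqn{d|\varrho|/d\eta = D'(\eta)/2}
#' at \eqn{D(\hat\eta) = 1}. The closed-form value is obtained by symbolic
#' differentiation of the determinant of the map's Jacobian at the interior
#' point with respect to \eqn{\eta}; a central finite difference of the
#' eigenvalue modulus serves as an independent check (\code{fd_slope}).
#'
#' @inheritParams map_jacobian
#' @param eta_hat critical step size (determinant equal to 1 there).
#' @return List with \code{slope} (closed form), \code{fd_slope}, and
#'   \code{degenerate} (TRUE when \eqn{|slope| < 10^{-12}}).
#' @export
ns_transversality <- function(params, eta_hat, map_kind = "nsfd") {
  map_kind <- match.arg(map_kind, c("euler", "nsfd"))
  check_params(params); check_eta(eta_hat)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  pt <- fps$interior
  # symbolic d(det)/d(eta): det = f_p g_z - f_z g_p with each partial an
  # expression in (p, z, eta); differentiate the product rule terms.
  fp_ <- map_partial_expr(map_kind, "p", 1, 0)
  fz_ <- map_partial_expr(map_kind, "p", 0, 1)
  gp_ <- map_partial_expr(map_kind, "z", 1, 0)
  gz_ <- map_partial_expr(map_kind, "z", 0, 1)
  env <- eval_env(params, eta_hat, NULL, pt[["p"]], pt[["z"]])
  dDdeta <- eval(stats::D(fp_, "eta"), env) * eval(gz_, env) +
    eval(fp_, env) * eval(stats::D(gz_, "eta"), env) -
    eval(stats::D(fz_, "eta"), env) * eval(gp_, env) -
    eval(fz_, env) * eval(stats::D(gp_, "eta"), env)
  slope <- dDdeta / 2
  h <- 1e-6 * max(1, eta_hat)
  modat <- function(eta) {
    cp <- char_poly(map_jacobian(map_kind, params, eta, pt))
    max(Mod(char_roots(cp$T, cp$D)))
  }
  fd <- (modat(eta_hat + h) - modat(eta_hat - h)) / (2 * h)
  list(slope = slope, fd_slope = fd, degenerate = abs(slope) < 1e-12)
}

#' Full Neimark-Sacker report for a map's interior fixed point
#'
#' Assembles the numerically located criticality, the closed-form step size
#' (NSFD map), transversality, the nondegeneracy conditions
#' (\eqn{\hat p(0) \neq 0, 1}, i.e. \eqn{\varrho^m \neq 1} for
#' \eqn{m = 1,\dots,4}), the \eqn{\xi} coefficients via the numeric
#' Taylor-and-transform path, the Lyapunov quantity \eqn{\digamma} and the
#' direction of the bifurcating invariant curve. Failed preconditions are
#' reported as named flags rather than errors.
#'
#' @inheritParams ns_critical_eta_numeric
#' @return Object of class \code{ns_report}.
#' @export
ns_report <- function(map_kind, params, bracket = c(0.01, 1)) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd"))
  check_params(params)
  fps <- fixed_points(params)
  if (!fps$interior_exists) {
    return(structure(list(map_kind = map_kind, interior_exists = FALSE),
                     class = "ns_report"))
  }
  crit <- tryCatch(ns_critical_eta_numeric(map_kind, params, bracket),
                   error = function(e) NULL)
  if (is.null(crit)) {
    return(structure(list(map_kind = map_kind, interior_exists = TRUE,
                          criticality_found = FALSE),
                     class = "ns_report"))
  }
  eta_hat <- crit$eta_crit
  closed <- if (map_kind == "nsfd") ns_critical_eta(params) else NULL
  rho1 <- crit$multipliers[1]
  phat0 <- 2 * Re(rho1)
  # rho^m != 1 for m = 1..4 <=> phat(0) not in {-2, -1, 0, 2} (pair e^{+-i t})
  nondeg <- all(abs(phat0 - c(-2, -1, 0, 2)) > 1e-8)
  tv <- ns_transversality(params, eta_hat, map_kind)
  tay <- taylor_expand(map_kind, params, eta_hat, fps$interior)
  nf <- normal_form(tay, rho1)
  xi <- xi_coefficients(nf)
  F_quantity <- lyapunov_quantity(xi, rho1)
  direction <- if (F_quantity < 0) {
    "attracting invariant curve for eta > eta_hat"
  } else if (F_quantity > 0) {
    "repelling invariant curve for eta < eta_hat"
  } else "degenerate (F = 0)"
  structure(list(map_kind = map_kind, interior_exists = TRUE,
                 criticality_found = TRUE,
                 eta_hat = eta_hat,
                 eta_hat_closed_form = if (!is.null(closed)) closed$eta_hat else NA_real_,
                 modulus_condition_ok = if (!is.null(closed)) closed$modulus_condition_ok else NA,
                 complex_pair = crit$complex_pair,
                 multipliers = crit$multipliers,
                 p_hat0 = phat0,
                 transversality = tv$slope,
                 transversality_ok = !tv$degenerate,
                 nondegeneracy_ok = nondeg,
                 xi = xi, F_quantity = F_quantity, direction = direction),
            class = "ns_report")
}

#' @export
print.ns_report <- function(x, ...) {
  cat("<ns_report>", x$map_kind, "map\n")
  if (!isTRUE(x$interior_exists)) {
    cat("  interior fixed point absent\n"); return(invisible(x))
  }
  if (!isTRUE(x$criticality_found)) {
    cat("  no determinant crossing located in the bracket\n")
    return(invisible(x))
  }
  cat(sprintf("  eta_hat (bisection) : %.12g\n", x$eta_hat))
  if (is.finite(x$eta_hat_closed_form))
    cat(sprintf("  eta_hat (closed form): %.12g\n", x$eta_hat_closed_form))
  cat(sprintf("  multipliers: %s\n",
              paste(format(x$multipliers, digits = 10), collapse = ", ")))
  cat(sprintf("  transversality d|rho|/deta = %.6g; nondegeneracy %s\n",
              x$transversality, if (isTRUE(x$nondegeneracy_ok)) "ok" else "FAILED"))
  cat(sprintf("  F quantity = %.8g -> %s\n", x$F_quantity, x$direction))
  invisible(x)
}
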