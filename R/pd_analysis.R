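# Period-doubling (flip) machinery for the Euler map: critical-parameter
# formula, eigenvalue -1 detection, center-manifold reduction and the
# L11/L12 quantities with bifurcation direction.

#' Closed-form flip-critical half-saturation constant
#'
#' For fixed \eqn{\eta} and the remaining parameters, the value of the
#' half-saturation constant \eqn{a} at which the Euler map's interior point
#' acquires a multiplier \eqn{-1}:
#' \deqn{a = \frac{-k(-\beta+\delta+\rho)\,[-\beta(4+r\delta\eta^2) + 4\rho +
#'   r\delta\eta(-2+\eta(\delta+\rho))]}
#'   {(km+r)\delta\eta\,[-\beta(2+\delta\eta) + 2\rho + \delta(-2+\eta(\delta+\rho))]}.}
#'
#' @param params a \code{\link{plankton_params}}; its \code{a} field is
#'   ignored (the function solves for it).
#' @param eta step size (> 0).
#' @return The critical value \code{a_crit}.
#' @export
pd_critical_a <- function(params, eta) {
  check_params(params); eta <- check_eta(eta)
  r <- params$r; k <- params$k; m <- params$m
  be <- params$beta; rho <- params$rho; de <- params$delta
  num <- -k * (-be + de + rho) *
    (-be * (4 + r * de * eta^2) + 4 * rho + r * de * eta * (-2 + eta * (de + rho)))
  den <- (k * m + r) * de * eta *
    (-be * (2 + de * eta) + 2 * rho + de * (-2 + eta * (de + rho)))
  if (abs(den) < 1e-14)
    stop("degenerate: closed-form denominator vanishes", call. = FALSE)
  num / den
}

#' Flip-criticality check at the interior point
#'
#' TRUE when the characteristic polynomial of the selected map's Jacobian at
#' the interior fixed point satisfies \eqn{F(-1) = 0} (within \code{tol})
#' with \eqn{D \notin \{1, -1\}} -- a real multiplier at \eqn{-1} with the
#' second multiplier off the unit circle.
#'
#' @inheritParams map_jacobian
#' @param tol tolerance on \eqn{F(-1)} and on the \eqn{D} exclusions.
#' @return List with \code{flip}, \code{multipliers}, \code{Fm1}, \code{D}.
#' @export
pd_check <- function(params, eta, map_kind = "euler", tol = 1e-9) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd"))
  check_params(params); eta <- check_eta(eta)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  cp <- char_poly(map_jacobian(map_kind, params, eta, fps$interior))
  Fm1 <- 1 + cp$T + cp$D
  flip <- abs(Fm1) <= tol && abs(cp$D - 1) > tol && abs(cp$D + 1) > tol
  list(flip = flip, multipliers = char_roots(cp$T, cp$D),
       Fm1 = Fm1, D = cp$D)
}

#' Quadratic center manifold at a flip point
#'
#' For a planar map already in the eigenbasis of a flip-critical Jacobian,
#' \eqn{u' = -u + f(u,v)}, \eqn{v' = \psi_2 v + g(u,v)} with
#' \eqn{|\psi_2| \neq 1}, the invariant center manifold through the origin is
#' \eqn{v = M_{11} u^2 + M_{12} u\bar\eta + O(3)}. Matching powers in the
#' invariance equation gives \eqn{M_{11} = g_{20}/(1-\psi_2)} and, when the
#' parameter block is supplied, \eqn{M_{12} = -g_{u\bar\eta}/(1+\psi_2)}.
#' \eqn{M_{13} = 0} always.
#'
#' @param f_uv,g_uv 4x4 coefficient matrices of the nonlinear parts in
#'   \eqn{(u, v)}.
#' @param psi2 the second (non-critical) multiplier, \eqn{|\psi_2| \neq 1}.
#' @param g_ueta optional coefficient of \eqn{u \bar\eta} in \eqn{g}.
#' @return List with \code{M11}, \code{M12} (NA when \code{g_ueta} missing)
#'   and \code{M13 = 0}.
#' @export
center_manifold <- function(f_uv, g_uv, psi2, g_ueta = NULL) {
  if (abs(abs(psi2) - 1) < 1e-8)
    stop("no spectral gap: |psi2| = 1", call. = FALSE)
  M11 <- g_uv[3, 1] / (1 - psi2)
  M12 <- if (is.null(g_ueta)) NA_real_ else -g_ueta / (1 + psi2)
  list(M11 = M11, M12 = M12, M13 = 0)
}

#' Direction quantity of the flip bifurcation from reduced-map coefficients
#'
#' For the reduced scalar map \eqn{G(u) = -u + a_{11}u^2 + a_{15}u^3 + \dots},
#' \deqn{L_{12} = \big(\tfrac12 G_{uu}\big)^2 + \tfrac16 G_{uuu}
#'   = a_{11}^2 + a_{15}.}
#' Positive: the bifurcating period-two orbit is stable; negative: unstable.
#'
#' @param a11 coefficient of \eqn{u^2} in the reduced map.
#' @param a15 coefficient of \eqn{u^3}.
#' @return \code{L12}.
#' @export
flip_L12 <- function(a11, a15) a11^2 + a15

#' Period-doubling report for the Euler map's interior point
#'
#' At a flip-critical parameter point (multiplier \eqn{-1}), reduces the map
#' to its one-dimensional center manifold: Taylor expansion about the fixed
#' point, similarity transform to the eigenbasis \eqn{S = [v_{-1}, v_{\psi_2}]},
#' quadratic manifold \eqn{v = M_{11}u^2 + M_{12}u\bar\eta}, reduced map
#' coefficients and the quantities \eqn{L_{11}} (transversality,
#' \eqn{\partial^2 G/\partial u\partial\bar\eta}, computed as
#' \eqn{(S^{-1} J'(\eta) S)_{11}} -- the Euler fixed point does not move with
#' \eqn{\eta}, so \eqn{\partial G/\partial\bar\eta = 0} at the origin) and
#' \eqn{L_{12}} with the direction of Theorem-style flip classification.
#'
#' @inheritParams pd_check
#' @param eta flip-critical step size (multiplier within \code{crit_tol}
#'   of \eqn{-1}).
#' @param crit_tol tolerance on \eqn{|\psi_1 + 1|} at entry.
#' @return Object of class \code{pd_report}: \code{psi2}, \code{M11},
#'   \code{M12}, \code{a_coeffs} (\code{a11}, \code{a12}, \code{a15};
#'   \code{a13}, \code{a14} reported as NA -- they do not enter the
#'   direction), \code{L11}, \code{L12}, \code{direction}.
#' @export
pd_report <- function(params, eta, crit_tol = 1e-6) {
  check_params(params); eta <- check_eta(eta)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  pt <- fps$interior
  J <- map_jacobian("euler", params, eta, pt)
  eg <- eigen(J)
  if (any(Mod(Im(eg$values)) > 1e-10))
    stop("multipliers are complex; not a flip point", call. = FALSE)
  vals <- Re(eg$values)
  i1 <- which.min(abs(vals + 1)); i2 <- 3 - i1
  if (abs(vals[i1] + 1) > crit_tol)
    stop("no multiplier within crit_tol of -1; locate criticality first",
         call. = FALSE)
  psi2 <- vals[i2]
  if (abs(abs(psi2) - 1) < 1e-8)
    stop("no spectral gap: |psi2| = 1", call. = FALSE)
  S <- cbind(Re(eg$vectors[, i1]), Re(eg$vectors[, i2]))
  Si <- solve(S)
  tay <- taylor_expand("euler", params, eta, pt)
  h1 <- poly_keep_degrees(tay$cp, 2:3)
  h2 <- poly_keep_degrees(tay$cz, 2:3)
  h1u <- poly_compose_linear(h1, S)
  h2u <- poly_compose_linear(h2, S)
  f_uv <- Si[1, 1] * h1u + Si[1, 2] * h2u
  g_uv <- Si[2, 1] * h1u + Si[2, 2] * h2u
  # parameter block: for the Euler map J(eta) = I + eta * A with A the
  # Jacobian of the continuous right-hand side, so J'(eta) = A exactly.
  A <- (J - diag(2)) / eta
  B <- Si %*% A %*% S
  L11 <- B[1, 1]           # a12 = d(mu_1)/d(eta) in the frozen eigenbasis
  g_ueta <- B[2, 1]        # u * etabar coefficient of g
  cm <- center_manifold(f_uv, g_uv, psi2, g_ueta = g_ueta)
  a11 <- f_uv[3, 1]
  a15 <- f_uv[4, 1] + f_uv[2, 2] * cm$M11
  L12 <- flip_L12(a11, a15)
  direction <- if (abs(L11) < 1e-12 || abs(L12) < 1e-12) {
    "inconclusive (degenerate L)"
  } else if (L12 > 0) "stable period-2 beyond criticality" else
    "unstable period-2 beyond criticality"
  structure(list(point = pt, eta = eta, psi2 = psi2,
                 M11 = cm$M11, M12 = cm$M12,
                 a_coeffs = c(a11 = a11, a12 = L11, a13 = NA_real_,
                              a14 = NA_real_, a15 = a15),
                 L11 = L11, L12 = L12, direction = direction,
                 f_uv = f_uv, g_uv = g_uv, S = S),
            class = "pd_report")
}

#' @export
print.pd_report <- function(x, ...) {
  cat(sprintf("<pd_report> Euler map at (%.7g, %.7g), eta = %.10g\n",
              x$point[["p"]], x$point[["z"]], x$eta))
  cat(sprintf("  psi2 = %.8g, M11 = %.6g, M12 = %.6g\n", x$psi2, x$M11, x$M12))
  cat(sprintf("  a11 = %.6g, a15 = %.6g\n",
              x$a_coeffs[["a11"]], x$a_coeffs[["a15"]]))
  cat(sprintf("  L11 = %.6g, L12 = %.6g -> %s\n", x$L11, x$L12, x$direction))
  invisible(x)
}

#' Locate a flip-critical step size by bisection
#'
#' Bisection on \eqn{F(-1)(\eta) = 0} for the Euler map's interior point.
#'
#' @inheritParams pd_check
#' @param bracket search interval for \eqn{\eta}.
#' @return The critical \eqn{\eta}, or \code{NA} when \eqn{F(-1)} does not
#'   change sign on the bracket.
#' @export
pd_critical_eta <- function(params, bracket = c(1e-3, 1), map_kind = "euler") {
  map_kind <- match.arg(map_kind, c("euler", "nsfd"))
  check_params(params)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  f <- function(eta) {
    cp <- char_poly(map_jacobian(map_kind, params, eta, fps$interior))
    1 + cp$T + cp$D
  }
  if (f(bracket[1]) * f(bracket[2]) > 0) return(NA_real_)
  stats::uniroot(f, bracket, tol = 1e-13)$root
}

#' Behavioral period-2 detector
#'
#' Iterates the selected map, discards a transient and inspects the tail:
#' \code{"period-2"} when alternate iterates coincide (within \code{1e-8})
#' while consecutive iterates stay apart (at least \code{1e-4});
#' \code{"fixed-point"} when consecutive iterates coincide; otherwise
#' \code{"other"}. Divergent orbits return \code{"diverged"}.
#'
#' @inheritParams map_jacobian
#' @param s0 initial state.
#' @param n post-transient iterates inspected.
#' @param transient iterates discarded first.
#' @return One of \code{"period-2"}, \code{"fixed-point"}, \code{"other"},
#'   \code{"diverged"}.
#' @export
period2_oracle <- function(params, eta, s0, n = 64, transient = 5000,
                           map_kind = "euler", theta = NULL) {
  orb <- iterate_map(map_kind, params, eta, s0, n = transient + n,
                     theta = theta)
  if (orb$diverged) return("diverged")
  tail_states <- orb$states[(transient + 1):(transient + n + 1), , drop = FALSE]
  d_alt <- max(abs(tail_states[-(1:2), ] - tail_states[1:(nrow(tail_states) - 2), ]))
  d_con <- max(abs(tail_states[-1, ] - tail_states[-nrow(tail_states), ]))
  if (d_con <= 1e-8) "fixed-point"
  else if (d_alt <= 1e-8 && d_con >= 1e-4) "period-2"
  else "other"
}
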