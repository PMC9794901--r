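#' Jacobian matrix of a plankton map at a point
#'
#' Closed-form partial derivatives of the Euler, NSFD or hybrid-controlled map
#' evaluated at an arbitrary state. The hybrid Jacobian is the convex
#' combination \eqn{\Theta^3 J_{euler} + (1-\Theta^3) I}.
#'
#' @inheritParams euler_step
#' @param map_kind one of \code{"euler"}, \code{"nsfd"}, \code{"hybrid"}.
#' @param theta control parameter, required for \code{map_kind = "hybrid"}.
#' @return A 2x2 numeric matrix.
#' @examples
#' par <- plankton_params(2.4917, 0.217, 0.217, 0.217, 0.217, 2.09, 0.217, 0.32)
#' map_jacobian("nsfd", par, 0.3, c(0, 0))
#' @export
map_jacobian <- function(map_kind, params, eta, s, theta = NULL) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd", "hybrid"))
  check_params(params); eta <- check_eta(eta); s <- as_state(s)
  p <- s[["p"]]; z <- s[["z"]]
  r <- params$r; k <- params$k; al <- params$alpha; a <- params$a
  m <- params$m; be <- params$beta; rho <- params$rho; de <- params$delta
  if (a + p <= 0) stop("degenerate denominator: a + p <= 0", call. = FALSE)
  if (map_kind == "nsfd") {
    Dp <- 1 + eta * (r * p / k + al * z / (a + p) + m * p)
    dDp_dp <- eta * (r / k - al * z / (a + p)^2 + m)
    dDp_dz <- eta * al / (a + p)
    Nz <- 1 + eta * be * p / (a + p)
    Dz <- 1 + eta * (de + rho * p / (a + p))
    dNz_dp <- eta * be * a / (a + p)^2
    dDz_dp <- eta * rho * a / (a + p)^2
    J <- matrix(c((1 + eta * r) * (Dp - p * dDp_dp) / Dp^2,
                  -(1 + eta * r) * p * dDp_dz / Dp^2,
                  z * (dNz_dp * Dz - Nz * dDz_dp) / Dz^2,
                  Nz / Dz),
                nrow = 2, byrow = TRUE)
    return(J)
  }
  # Euler Jacobian; hybrid derives from it
  Je <- matrix(c(1 + eta * (r - 2 * r * p / k - al * z * a / (a + p)^2 - 2 * m * p),
                 -eta * al * p / (a + p),
                 eta * (be - rho) * z * a / (a + p)^2,
                 1 + eta * ((be - rho) * p / (a + p) - de)),
               nrow = 2, byrow = TRUE)
  if (map_kind == "euler") return(Je)
  theta <- check_theta(theta)
  theta^3 * Je + (1 - theta^3) * diag(2)
}

#' Characteristic polynomial of a 2x2 matrix
#'
#' Returns trace and determinant so that \eqn{F(\omega) = \omega^2 - T\omega + D}.
#'
#' @param J a 2x2 numeric matrix with finite entries.
#' @return List of class \code{char_poly} with elements \code{T} and \code{D}.
#' @export
char_poly <- function(J) {
  if (!is.matrix(J) || !all(dim(J) == c(2, 2)) || any(!is.finite(J)))
    stop("J must be a finite 2x2 matrix", call. = FALSE)
  structure(list(T = J[1, 1] + J[2, 2],
                 D = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]),
            class = "char_poly")
}

# internal: eigenvalues of omega^2 - T omega + D, deterministic order:
# nonnegative imaginary part first; for real pairs, larger modulus first.
char_roots <- function(T, D) {
  disc <- T^2 - 4 * D
  if (disc < 0) {
    re <- T / 2; im <- sqrt(-disc) / 2
    c(complex(real = re, imaginary = im), complex(real = re, imaginary = -im))
  } else {
    rts <- c((T + sqrt(disc)) / 2, (T - sqrt(disc)) / 2)
    rts <- rts[order(-abs(rts), rts)]
    as.complex(rts)
  }
}

#' Jury-criterion classification of a planar map's multipliers
#'
#' Classifies a fixed point from the trace and determinant of its Jacobian
#' using the Jury conditions \eqn{F(1) = 1 - T + D}, \eqn{F(-1) = 1 + T + D}
#' and \eqn{D}: sink iff \eqn{F(-1) > 0, D < 1} (given \eqn{F(1) > 0}),
#' source iff \eqn{F(-1) > 0, D > 1}, saddle iff \eqn{F(-1) < 0};
#' \eqn{F(-1) = 0} (real multiplier at \eqn{-1}) or \eqn{T^2 < 4D, D = 1}
#' (complex pair on the unit circle) are non-hyperbolic. When the hypothesis
#' \eqn{F(1) > 0} fails the classification falls back to the eigenvalue
#' moduli directly and the result is flagged.
#'
#' @param c a \code{\link{char_poly}} or a list with elements \code{T}, \code{D}.
#' @param tol non-hyperbolicity tolerance on \eqn{||\omega| - 1|}.
#' @return List of class \code{jury_class}: \code{class} (one of
#'   \code{"sink"}, \code{"source"}, \code{"saddle"}, \code{"non-hyperbolic"}),
#'   \code{eigenvalues}, \code{moduli}, \code{F1}, \code{Fm1},
#'   \code{lemma_hypothesis_ok}.
#' @examples
#' jury_classify(list(T = 0, D = 0.5))$class
#' @export
jury_classify <- function(c, tol = 1e-9) {
  T <- c$T; D <- c$D
  F1 <- 1 - T + D
  Fm1 <- 1 + T + D
  ev <- char_roots(T, D)
  mods <- Mod(ev)
  hyp_ok <- F1 > 0
  cls <- if (any(abs(mods - 1) < tol)) {
    "non-hyperbolic"
  } else if (hyp_ok) {
    if (Fm1 > 0 && D < 1) "sink"
    else if (Fm1 > 0 && D > 1) "source"
    else "saddle"  # F(-1) < 0
  } else {
    # direct moduli fallback
    if (all(mods < 1)) "sink" else if (all(mods > 1)) "source" else "saddle"
  }
  structure(list(class = cls, eigenvalues = ev, moduli = mods,
                 F1 = F1, Fm1 = Fm1, lemma_hypothesis_ok = hyp_ok),
            class = "jury_class")
}

#' Stability report for a named fixed point
#'
#' Assembles Jacobian, characteristic polynomial, Jury values and the
#' topological class of one of the map's fixed points. For the NSFD boundary
#' point the closed-form sink criterion
#' \eqn{kr\beta < a\delta(km+r) + kr(\delta+\rho)} is evaluated alongside and
#' reported in \code{criterion_agrees}.
#'
#' @inheritParams map_jacobian
#' @param which_point \code{"trivial"}, \code{"boundary"} or \code{"interior"}.
#' @return List of class \code{stability_report}.
#' @export
classify_fixed_point <- function(map_kind, params, eta, which_point,
                                 theta = NULL, tol = 1e-9) {
  which_point <- match.arg(which_point, c("trivial", "boundary", "interior"))
  fps <- fixed_points(params)
  pt <- fps[[which_point]]
  if (is.null(pt))
    stop("no such fixed point: the interior point does not exist for these parameters",
         call. = FALSE)
  J <- map_jacobian(map_kind, params, eta, pt, theta)
  cp <- char_poly(J)
  jc <- jury_classify(cp, tol)
  crit <- NA
  if (map_kind == "nsfd" && which_point == "boundary") {
    lhs <- params$k * params$r * params$beta
    rhs <- params$a * params$delta * (params$k * params$m + params$r) +
      params$k * params$r * (params$delta + params$rho)
    closed <- if (lhs < rhs) "sink" else "saddle"
    crit <- identical(closed, jc$class)
  }
  structure(list(point = pt, map_kind = map_kind, eta = eta, theta = theta,
                 jacobian = J, char = cp, F1 = jc$F1, Fm1 = jc$Fm1,
                 eigenvalues = jc$eigenvalues, moduli = jc$moduli,
                 class = jc$class,
                 lemma_hypothesis_ok = jc$lemma_hypothesis_ok,
                 criterion_agrees = crit),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s map at (%.7g, %.7g), eta = %g%s\n",
              x$map_kind, x$point[["p"]], x$point[["z"]], x$eta,
              if (!is.null(x$theta)) sprintf(", theta = %g", x$theta) else ""))
  cat(sprintf("  T = %.10g, D = %.10g, F(1) = %.6g, F(-1) = %.6g\n",
              x$char$T, x$char$D, x$F1, x$Fm1))
  cat(sprintf("  multipliers: %s (moduli %.8g, %.8g)\n",
              paste(format(x$eigenvalues, digits = 8), collapse = ", "),
              x$moduli[1], x$moduli[2]))
  cat("  class:", x$class, "\n")
  invisible(x)
}

#' Jury values for the NSFD interior point, closed form
#'
#' Evaluates the printed closed forms
#' \deqn{U(1) = \delta\eta^2 (r k(\beta-\delta-\rho) - a\delta(r+km)) /
#'   (k(1+r\eta)(\beta+\beta\delta\eta-\rho))}
#' and the matching expression for \eqn{U(-1)}. Under the interior-existence
#' condition both are provably positive: the NSFD map admits no flip
#' (period-doubling) bifurcation at the coexistence point.
#'
#' @inheritParams continuous_rhs
#' @param eta step size (> 0).
#' @return \code{c(U1 =, Um1 =)}.
#' @export
U_values <- function(params, eta) {
  check_params(params); eta <- check_eta(eta)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  r <- params$r; k <- params$k; a <- params$a; m <- params$m
  be <- params$beta; rho <- params$rho; de <- params$delta
  U1 <- de * eta^2 * (r * k * (be - de - rho) - a * de * (r + k * m)) /
    (k * (1 + r * eta) * (be + be * de * eta - rho))
  Um1 <- (4 + eta * (r * (4 + de * eta) +
                       2 * (a * k * m + (a + k) * r) * de / (k * (be - rho)) -
                       de^2 * eta * (a * (k * m + r) + k * r * (1 + be * eta)) /
                       (k * (be + be * de * eta - rho)) -
                       4 * a * (k * m + r) * de / (k * (be - de - rho)))) /
    (1 + r * eta)
  c(U1 = U1, Um1 = Um1)
}

#' Characteristic polynomial of the hybrid-controlled map at the interior point
#'
#' Closed-form trace and determinant of the controlled map's Jacobian at the
#' coexistence fixed point, as functions of the gain \eqn{\Theta}:
#' at \eqn{\Theta = 1} they reduce to the uncontrolled Euler values.
#'
#' @inheritParams U_values
#' @param theta control parameter in (0, 1].
#' @return A \code{\link{char_poly}}.
#' @export
controlled_char_poly <- function(params, eta, theta) {
  check_params(params); eta <- check_eta(eta); theta <- check_theta(theta)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  r <- params$r; k <- params$k; a <- params$a; m <- params$m
  be <- params$beta; rho <- params$rho; de <- params$delta
  g <- eta * theta^3
  A <- a * k * m + (a + k) * r
  T <- 2 + A * de * g / (k * (be - rho)) +
    2 * a * (k * m + r) * de * g / (k * (-be + de + rho))
  D <- 1 + r * de * g^2 + A * de * g * (-1 + de * g) / (k * (-be + rho)) +
    2 * a * (k * m + r) * de * g / (k * (-be + de + rho))
  structure(list(T = T, D = D), class = "char_poly")
}

#' Closed-form stability test for the hybrid-controlled interior point
#'
#' Evaluates the two closed-form inequalities for local asymptotic stability
#' of the coexistence point of the controlled map. \code{applicable} reports
#' whether the first inequality (the hypothesis) holds; when it does,
#' \code{stable} matches the Jury sink verdict on
#' \code{\link{controlled_char_poly}}.
#'
#' @inheritParams controlled_char_poly
#' @return List with \code{applicable}, \code{stable}, and the two evaluated
#'   quantities \code{lhs1} (must be < 0) and \code{lhs2} (must be > 0).
#' @export
hybrid_interior_stable <- function(params, eta, theta) {
  check_params(params); eta <- check_eta(eta); theta <- check_theta(theta)
  r <- params$r; k <- params$k; a <- params$a; m <- params$m
  be <- params$beta; rho <- params$rho; de <- params$delta
  g <- eta * theta^3
  A <- a * k * m + (a + k) * r
  lhs1 <- r * g + A * (-1 + de * g) / (k * (-be + rho)) +
    2 * a * (k * m + r) / (k * (-be + de + rho))
  lhs2 <- 4 + a * m * de * g * ((-2 + de * g) / (-be + rho) +
                                  4 / (-be + de + rho)) +
    r * de * g * (g + (a + k) * (-2 + de * g) / (k * (-be + rho)) +
                    4 * a / (k * (-be + de + rho)))
  list(applicable = lhs1 < 0, stable = (lhs1 < 0) && (lhs2 > 0),
       lhs1 = lhs1, lhs2 = lhs2)
}
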