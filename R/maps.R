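#' Right-hand side of the continuous plankton model
#'
#' Evaluates the vector field of the continuous-time system
#' \deqn{dp/dt = r p (1 - p/k) - \alpha p z/(a + p) - m p^2,}
#' \deqn{dz/dt = \beta p z/(a + p) - \rho p z/(a + p) - \delta z.}
#' The quadratic \code{m p^2} is phytoplankton mortality from an external toxic
#' substance; the Holling type-II terms are grazing, conversion and
#' toxin-mediated zooplankton loss.
#'
#' @param params a \code{\link{plankton_params}} object.
#' @param s state, a length-2 numeric \code{(p, z)} with non-negative entries.
#' @return Named numeric \code{c(dp =, dz =)}.
#' @examples
#' par <- plankton_params(2.4917, 0.217, 0.217, 0.217, 0.217, 2.09, 0.217, 0.32)
#' continuous_rhs(par, c(0.1, 1))
#' @export
continuous_rhs <- function(params, s) {
  check_params(params); s <- as_state(s)
  p <- s[["p"]]; z <- s[["z"]]
  if (params$a + p <= 0) stop("degenerate denominator: a + p <= 0", call. = FALSE)
  hold <- p / (params$a + p)
  dp <- params$r * p * (1 - p / params$k) - params$alpha * z * hold -
    params$m * p^2
  dz <- params$beta * z * hold - params$rho * z * hold - params$delta * z
  c(dp = dp, dz = dz)
}

#' One step of the forward-Euler discretization
#'
#' Applies \code{s + eta * continuous_rhs(params, s)}. The Euler map does not
#' preserve positivity; negative or non-finite outputs are flagged via the
#' \code{"clean"} attribute rather than clamped.
#'
#' @inheritParams continuous_rhs
#' @param eta discretization step size (> 0).
#' @return Next state with attribute \code{clean} (TRUE when both components
#'   are finite and non-negative).
#' @examples
#' par <- plankton_params(2.4917, 0.217, 0.217, 0.217, 0.217, 2.09, 0.217, 0.32)
#' euler_step(par, 0.4, c(0.1, 1))
#' @export
euler_step <- function(params, eta, s) {
  check_params(params); eta <- check_eta(eta); s <- as_state(s)
  out <- s + eta * continuous_rhs(params, s)
  names(out) <- c("p", "z")
  attr(out, "clean") <- all(is.finite(out)) && all(out >= 0)
  out
}

#' One step of the nonstandard finite difference (Mickens) discretization
#'
#' The loss terms are placed in denominators,
#' \deqn{p' = (1+\eta r) p / (1 + \eta(r p/k + \alpha z/(a+p) + m p)),}
#' \deqn{z' = (1 + \eta\beta p/(a+p)) z / (1 + \eta(\delta + \rho p/(a+p))),}
#' so that positive states map to positive states and the equilibria of the
#' continuous system are preserved exactly.
#'
#' @inheritParams euler_step
#' @return Next state (always non-negative for valid inputs).
#' @examples
#' par <- plankton_params(2.4917, 0.217, 0.217, 0.217, 0.217, 2.09, 0.217, 0.32)
#' nsfd_step(par, 0.4, c(0.1, 1))
#' @export
nsfd_step <- function(params, eta, s) {
  check_params(params); eta <- check_eta(eta); s <- as_state(s)
  p <- s[["p"]]; z <- s[["z"]]
  hold <- p / (params$a + p)
  pn <- (1 + eta * params$r) * p /
    (1 + eta * (params$r * p / params$k + params$alpha * z / (params$a + p) +
                  params$m * p))
  zn <- (1 + eta * params$beta * hold) * z /
    (1 + eta * (params$delta + params$rho * hold))
  c(p = pn, z = zn)
}

#' One step of the hybrid-controlled Euler map
#'
#' Generalized hybrid control (state feedback combined with parameter
#' perturbation) with gain \eqn{\Theta^3}, \eqn{\Theta \in (0,1]}:
#' \eqn{s' = \Theta^3\,\mathrm{euler}(s) + (1-\Theta^3)\,s}. At
#' \code{theta = 1} it coincides with \code{\link{euler_step}}; as
#' \code{theta -> 0} the state freezes.
#'
#' @inheritParams euler_step
#' @param theta control parameter in (0, 1].
#' @return Next state with the same \code{clean} attribute as
#'   \code{\link{euler_step}}.
#' @export
hybrid_step <- function(params, eta, theta, s) {
  theta <- check_theta(theta)
  es <- euler_step(params, eta, s)
  out <- theta^3 * as.numeric(es) + (1 - theta^3) * as_state(s)
  names(out) <- c("p", "z")
  attr(out, "clean") <- all(is.finite(out)) && all(out >= 0)
  out
}

# internal: single step dispatch
step_fun <- function(map_kind, params, eta, theta = NULL) {
  switch(map_kind,
         euler = function(s) euler_step(params, eta, s),
         nsfd = function(s) nsfd_step(params, eta, s),
         hybrid = {
           if (is.null(theta)) stop("theta required for the hybrid map", call. = FALSE)
           function(s) hybrid_step(params, eta, theta, s)
         },
         stop("unknown map kind: ", map_kind, call. = FALSE))
}

#' Fixed points of the plankton maps
#'
#' All three discrete maps share the equilibria of the continuous system:
#' extinction \eqn{(0,0)}, the zooplankton-free boundary point
#' \eqn{(kr/(km+r), 0)}, and -- when \eqn{\beta > \delta + \rho} and
#' \eqn{kr(\beta-\delta-\rho) > a\delta(km+r)} -- a coexistence (interior)
#' point \eqn{p^* = a\delta/(\beta-\delta-\rho)} with the matching
#' zooplankton level. The interior \eqn{z^*} is evaluated both by the closed
#' form and by the phytoplankton nullcline
#' \eqn{z = (a+p)(r(1-p/k) - m p)/\alpha}; their relative mismatch is stored in
#' \code{interior_consistency}.
#'
#' @inheritParams continuous_rhs
#' @return A list of class \code{fixed_point_set} with elements
#'   \code{trivial}, \code{boundary}, \code{interior} (or \code{NULL}),
#'   \code{interior_exists}, \code{existence_margins} (the signed quantities
#'   \eqn{\beta-\delta-\rho} and \eqn{kr(\beta-\delta-\rho)-a\delta(km+r)})
#'   and \code{interior_consistency}.
#' @examples
#' par <- plankton_params(2.4917, 0.217, 0.217, 0.217, 0.217, 2.09, 0.217, 0.32)
#' fixed_points(par)$interior
#' @export
fixed_points <- function(params) {
  check_params(params)
  r <- params$r; k <- params$k; al <- params$alpha; a <- params$a
  m <- params$m; be <- params$beta; rho <- params$rho; de <- params$delta
  margin1 <- be - de - rho
  margin2 <- k * r * (be - de - rho) - a * de * (k * m + r)
  boundary <- c(p = k * r / (k * m + r), z = 0)
  interior <- NULL
  mismatch <- NA_real_
  if (margin1 > 0 && margin2 > 0) {
    pstar <- a * de / margin1
    zstar <- a * (be - rho) *
      ((k * r * margin1 - a * k * m * de) - a * r * de) /
      (k * al * margin1^2)
    z_null <- (a + pstar) * (r * (1 - pstar / k) - m * pstar) / al
    mismatch <- abs(zstar - z_null) / max(abs(zstar), .Machine$double.eps)
    interior <- c(p = pstar, z = zstar)
  }
  structure(list(trivial = c(p = 0, z = 0),
                 boundary = boundary,
                 interior = interior,
                 interior_exists = !is.null(interior),
                 existence_margins = c(margin1 = margin1, margin2 = margin2),
                 interior_consistency = mismatch),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat("<fixed_point_set>\n")
  cat("  trivial : (0, 0)\n")
  cat(sprintf("  boundary: (%.7g, 0)\n", x$boundary[["p"]]))
  if (x$interior_exists)
    cat(sprintf("  interior: (%.7g, %.7g)\n",
                x$interior[["p"]], x$interior[["z"]]))
  else
    cat("  interior: absent (existence margins not both positive)\n")
  invisible(x)
}

#' Boundedness box for positive NSFD orbits
#'
#' Under \eqn{\beta > \rho + \delta} and
#' \eqn{kr(\beta-\delta-\rho) > a\delta(km+r)}, positive solutions of the
#' NSFD map are eventually confined to
#' \eqn{[0, kr/(km+r)] \times [0, (kr(\beta-\delta-\rho)-a\delta(km+r))/(\rho(km+r))]}.
#'
#' @inheritParams continuous_rhs
#' @return \code{c(p_max =, z_max =)} or \code{NULL} when the hypotheses fail.
#' @export
boundedness_box <- function(params) {
  check_params(params)
  r <- params$r; k <- params$k; a <- params$a; m <- params$m
  be <- params$beta; rho <- params$rho; de <- params$delta
  if (!(be > rho + de)) return(NULL)
  z_max <- (k * r * (be - de - rho) - a * de * (k * m + r)) / (rho * (k * m + r))
  if (z_max <= 0) return(NULL)
  c(p_max = k * r / (k * m + r), z_max = z_max)
}
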