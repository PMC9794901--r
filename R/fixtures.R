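# Worked-example fixtures: four published parameter sets, the published
# normal-form polynomials for the Euler-map Neimark-Sacker example, and the
# published xi values and Lyapunov quantity. Digit strings are kept exactly
# as printed in the source study.

#' Worked-example parameter sets
#'
#' Four parameter sets used throughout the package's worked examples:
#' \describe{
#'   \item{\code{"nsfd_ns"}}{NSFD map Neimark-Sacker example (printed
#'     critical step size 0.4115075).}
#'   \item{\code{"euler_ns"}}{Euler map Neimark-Sacker example (critical
#'     step size 0.4681150757612096).}
#'   \item{\code{"euler_pd"}}{Euler map period-doubling example. Documented
#'     as non-reproducible: its parameters violate the interior-existence
#'     condition (beta - delta - rho < 0) and its printed Jacobian does not
#'     follow from its printed parameters; shipped for reference only and
#'     excluded from assertions.}
#'   \item{\code{"hybrid_ctrl"}}{hybrid-control example (printed critical
#'     gains not recovered from the closed-form polynomial; reference only).}
#' }
#'
#' @param name one of the four fixture names.
#' @return List with \code{params} (a \code{\link{plankton_params}}),
#'   \code{p0}, \code{z0}, optional \code{eta}, \code{eta_printed},
#'   \code{theta_printed}, and \code{reproducible} flag.
#' @export
worked_example <- function(name = c("nsfd_ns", "euler_ns", "euler_pd",
                                    "hybrid_ctrl")) {
  name <- match.arg(name)
  switch(name,
    nsfd_ns = list(
      params = suppressWarnings(plankton_params(
        r = 2.4917, k = 0.217, alpha = 0.217, a = 0.217,
        m = 0.217, beta = 2.09, rho = 0.217, delta = 0.32)),
      p0 = 0.0442580082377936, z0 = 2.3740415103508146,
      eta_printed = 0.4115075, reproducible = TRUE),
    euler_ns = list(
      params = suppressWarnings(plankton_params(
        r = 3.0609, k = 1.258, alpha = 3.499, a = 0.8559,
        m = 0.9, beta = 4.8959, rho = 2.9, delta = 0.47122)),
      p0 = 0.26452580082377936, z0 = 0.7740415103508146,
      eta_printed = 0.4681150757612096, reproducible = TRUE),
    euler_pd = list(
      params = suppressWarnings(plankton_params(
        r = 2.9609, k = 1.258, alpha = 3.499, a = 0.9559,
        m = 0.33, beta = 3.08959, rho = 2.7, delta = 0.57122)),
      p0 = 1.26452580082377936, z0 = 0.07740415103508146,
      eta_printed = 0.73681150757612096,
      jacobian_printed = matrix(c(197.876, -45.7371, -4.30368, 1),
                                2, 2, byrow = TRUE),
      reproducible = FALSE),
    hybrid_ctrl = list(
      params = suppressWarnings(plankton_params(
        r = 3.0609, k = 1.258, alpha = 3.7799, a = 0.8559,
        m = 0.9, beta = 4.8959, rho = 2.9, delta = 0.47122)),
      p0 = 0.26452580082377936, z0 = 0.7740415103508146,
      eta = 0.4681150757612096,
      theta_printed = 0.7740415103508146,
      reproducible = FALSE))
}

#' Published normal-form polynomials and xi values for the Euler NS example
#'
#' The published transformed polynomials \eqn{\tilde X(u,v)},
#' \eqn{\tilde Y(u,v)} (expanded into coefficient matrices), the published
#' critical multiplier, the published \eqn{\xi} values and the published
#' Lyapunov quantity, exactly as printed. Feeding \code{Ft}, \code{Gt} to
#' \code{\link{xi_coefficients}} reproduces the printed \eqn{\xi}'s; feeding
#' those to \code{\link{lyapunov_quantity}} reproduces \code{F_printed}.
#'
#' @return List with \code{Ft}, \code{Gt} (4x4 coefficient matrices),
#'   \code{rho1}, \code{xi_printed} (named complex vector), \code{F_printed},
#'   \code{jacobian_printed}, \code{trace_printed}.
#' @export
ns_example_polynomials <- function() {
  # w = w_u * u + w_v * v appears as a factor in the printed polynomials
  w_u <- 0.1710819135; w_v <- -0.4055967942
  expand_poly <- function(c_u2, c_u1w, c_u3, c_u2w) {
    cm <- matrix(0, 4, 4)
    cm[3, 1] <- c_u2 + c_u1w * w_u          # u^2
    cm[2, 2] <- c_u1w * w_v                 # u v
    cm[4, 1] <- c_u3 + c_u2w * w_u          # u^3
    cm[3, 2] <- c_u2w * w_v                 # u^2 v
    cm
  }
  Ft <- expand_poly(0.2551272408, 0.3451424723, 0.03182434464, 0.1191233262)
  Gt <- expand_poly(0.2698683381, 0.7529267725, 0.06942466666, 0.2598670076)
  list(Ft = Ft, Gt = Gt,
       rho1 = complex(real = 0.9140520995474326, imaginary = 0.4055967942),
       xi_printed = c(xi20 = complex(real = 0.00219755, imaginary = 0.134667),
                      xi11 = complex(real = 0.157087, imaginary = 0.19934),
                      xi02 = complex(real = 0.15489, imaginary = 0.064673),
                      xi21 = complex(real = 0.00640142, imaginary = 0.0487457)),
       F_printed = -0.11264980623299635,
       jacobian_printed = matrix(c(0.828104, -0.386707, 0.444512, 1),
                                 2, 2, byrow = TRUE),
       trace_printed = 1.8281041990948645)
}
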