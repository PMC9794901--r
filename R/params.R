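#' Model parameters for the toxin-modified plankton system
#'
#' Bundles the eight positive rate/capacity constants of the continuous
#' phytoplankton-zooplankton model with Holling type-II grazing and an
#' external-toxin mortality term acting on the phytoplankton.
#'
#' @param r intrinsic phytoplankton growth rate (per unit time).
#' @param k environmental carrying capacity (biomass).
#' @param alpha maximal zooplankton capture (grazing) rate (per unit time).
#' @param a half-saturation constant of the Holling type-II response (biomass).
#' @param m external-toxin mortality coefficient (per biomass per time); the
#'   quadratic loss \code{m p^2} models accelerating toxin uptake.
#' @param beta phytoplankton-to-zooplankton conversion rate (per unit time).
#'   Biologically \code{beta < alpha}; a non-fatal warning is emitted otherwise.
#' @param rho toxin release rate per unit phytoplankton biomass (per unit time).
#' @param delta zooplankton death rate (per unit time).
#'
#' @return An object of class \code{plankton_params}: a named list with the
#'   eight fields above.
#' @examples
#' par <- plankton_params(r = 2.4917, k = 0.217, alpha = 0.217, a = 0.217,
#'                        m = 0.217, beta = 2.09, rho = 0.217, delta = 0.32)
#' par$r
#' @export
plankton_params <- function(r, k, alpha, a, m, beta, rho, delta) {
  vals <- c(r = r, k = k, alpha = alpha, a = a, m = m,
            beta = beta, rho = rho, delta = delta)
  if (any(!is.finite(vals)))
    stop("all model parameters must be finite numbers", call. = FALSE)
  if (any(vals <= 0)) {
    bad <- names(vals)[vals <= 0]
    stop("model parameters must be strictly positive; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (beta >= alpha)
    warning("conversion rate beta >= capture rate alpha; ",
            "the biological model assumes beta < alpha", call. = FALSE)
  structure(as.list(vals), class = "plankton_params")
}

#' @export
print.plankton_params <- function(x, ...) {
  cat("<plankton_params>\n")
  print(unlist(x))
  invisible(x)
}

#' A (phytoplankton, zooplankton) state
#'
#' @param p phytoplankton density (biomass, >= 0).
#' @param z zooplankton density (biomass, >= 0).
#' @return Named numeric vector \code{c(p =, z =)}.
#' @examples
#' plankton_state(0.1, 1)
#' @export
plankton_state <- function(p, z) {
  if (!is.finite(p) || !is.finite(z))
    stop("state components must be finite", call. = FALSE)
  if (p < 0 || z < 0)
    stop("state components must be non-negative", call. = FALSE)
  c(p = unname(p), z = unname(z))
}

# internal: coerce and validate a state-like input
as_state <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 2L || any(!is.finite(s)))
    stop("a state must be two finite numbers (p, z)", call. = FALSE)
  if (any(s < 0))
    stop("state components must be non-negative", call. = FALSE)
  c(p = s[1L], z = s[2L])
}

check_eta <- function(eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("step size eta must be a single positive number", call. = FALSE)
  eta
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0 || theta > 1)
    stop("control parameter theta must lie in (0, 1]", call. = FALSE)
  theta
}

check_params <- function(params) {
  if (!inherits(params, "plankton_params"))
    stop("`params` must be created with plankton_params()", call. = FALSE)
  params
}
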