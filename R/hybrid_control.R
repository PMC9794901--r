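# Hybrid chaos-control layer: stability region in the gain Theta and
# critical-gain detection for both bifurcation types.

#' Scan the control gain for the hybrid-controlled map
#'
#' Classifies the controlled map's interior fixed point over a grid of gains
#' \eqn{\Theta \in (0, 1]}: characteristic polynomial, multiplier moduli,
#' closed-form stability verdict and Jury class per grid value. Gains at
#' which the leading modulus crosses 1 between neighbouring grid points are
#' refined by bisection to \code{1e-10} and labelled \code{"ns"} (complex
#' pair, determinant through 1) or \code{"flip"} (\eqn{F(-1)} through 0).
#'
#' @inheritParams U_values
#' @param theta_grid increasing gains in (0, 1].
#' @return Object of class \code{control_scan}: \code{table} (data frame with
#'   columns theta, T, D, mod1, mod2, lemma_stable, class) and
#'   \code{critical_thetas} (data frame theta, kind).
#' @export
control_scan <- function(params, eta,
                         theta_grid = seq(0.01, 1, length.out = 500)) {
  check_params(params); eta <- check_eta(eta)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  pt <- fps$interior
  rows <- lapply(theta_grid, function(th) {
    cp <- char_poly(map_jacobian("hybrid", params, eta, pt, theta = th))
    jc <- jury_classify(cp)
    lm <- hybrid_interior_stable(params, eta, th)
    data.frame(theta = th, T = cp$T, D = cp$D,
               mod1 = jc$moduli[1], mod2 = jc$moduli[2],
               lemma_stable = lm$stable, class = jc$class,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  maxmod <- pmax(tab$mod1, tab$mod2) - 1
  crit <- list()
  for (i in seq_len(nrow(tab) - 1)) {
    if (maxmod[i] == 0 || maxmod[i] * maxmod[i + 1] > 0) next
    f <- function(th) {
      cp <- char_poly(map_jacobian("hybrid", params, eta, pt, theta = th))
      max(Mod(char_roots(cp$T, cp$D))) - 1
    }
    root <- stats::uniroot(f, c(tab$theta[i], tab$theta[i + 1]),
                           tol = 1e-10)$root
    cp <- char_poly(map_jacobian("hybrid", params, eta, pt, theta = root))
    kind <- if (cp$T^2 - 4 * cp$D < 0) "ns" else "flip"
    crit[[length(crit) + 1]] <- data.frame(theta = root, kind = kind,
                                           stringsAsFactors = FALSE)
  }
  structure(list(table = tab,
                 critical_thetas = if (length(crit)) do.call(rbind, crit)
                 else data.frame(theta = numeric(), kind = character())),
            class = "control_scan")
}

#' @export
print.control_scan <- function(x, ...) {
  cat(sprintf("<control_scan> %d gains in [%.4g, %.4g]\n",
              nrow(x$table), min(x$table$theta), max(x$table$theta)))
  print(table(x$table$class))
  if (nrow(x$critical_thetas))
    cat("critical gains:",
        paste(sprintf("%.8g (%s)", x$critical_thetas$theta,
                      x$critical_thetas$kind), collapse = ", "), "\n")
  invisible(x)
}

#' Critical control gain for a selected bifurcation type
#'
#' Bisection root of \eqn{D(\Theta) = 1} (\code{kind = "ns"}) or
#' \eqn{F(-1)(\Theta) = 0} (\code{kind = "flip"}) over the interior of
#' (0, 1], using the Jacobian of the controlled map directly. Returns
#' \code{NA} when the target quantity does not change sign (no loss of
#' stability within the gain range).
#'
#' @inheritParams U_values
#' @param kind \code{"ns"} or \code{"flip"}.
#' @param bracket search interval within (0, 1].
#' @return The critical gain, or \code{NA}.
#' @export
critical_theta <- function(params, eta, kind = c("ns", "flip"),
                           bracket = c(0.01, 1 - 1e-9)) {
  kind <- match.arg(kind)
  check_params(params); eta <- check_eta(eta)
  fps <- fixed_points(params)
  if (!fps$interior_exists)
    stop("interior fixed point does not exist for these parameters", call. = FALSE)
  pt <- fps$interior
  f <- function(th) {
    cp <- char_poly(map_jacobian("hybrid", params, eta, pt, theta = th))
    if (kind == "ns") cp$D - 1 else 1 + cp$T + cp$D
  }
  if (f(bracket[1]) * f(bracket[2]) > 0) return(NA_real_)
  stats::uniroot(f, bracket, tol = 1e-12)$root
}
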