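# Symbolic map expressions and Taylor expansion through total degree 3.
#
# Taylor coefficients are exact: each map component is an elementary rational
# expression in (p, z), differentiated symbolically with stats::D and
# evaluated at the base point.

map_component_expr <- function(map_kind, component) {
  e_p <- quote(p + eta * (r * p * (1 - p / k) - alpha * p * z / (a + p) - m * p^2))
  e_z <- quote(z + eta * ((beta - rho) * p * z / (a + p) - delta * z))
  n_p <- quote((1 + eta * r) * p /
                 (1 + eta * (r * p / k + alpha * z / (a + p) + m * p)))
  n_z <- quote((1 + eta * beta * p / (a + p)) * z /
                 (1 + eta * (delta + rho * p / (a + p))))
  switch(map_kind,
         euler = if (component == "p") e_p else e_z,
         nsfd = if (component == "p") n_p else n_z,
         hybrid = {
           base <- if (component == "p") e_p else e_z
           lin <- if (component == "p") quote(p) else quote(z)
           bquote(theta^3 * .(base) + (1 - theta^3) * .(lin))
         },
         stop("unknown map kind: ", map_kind, call. = FALSE))
}

# cache of derivative expressions: key "<map>.<comp>.<i>.<j>"
.deriv_cache <- new.env(parent = emptyenv())

map_partial_expr <- function(map_kind, component, i, j) {
  key <- paste(map_kind, component, i, j, sep = ".")
  if (!is.null(.deriv_cache[[key]])) return(.deriv_cache[[key]])
  e <- map_component_expr(map_kind, component)
  if (i > 0) for (q in seq_len(i)) e <- stats::D(e, "p")
  if (j > 0) for (q in seq_len(j)) e <- stats::D(e, "z")
  .deriv_cache[[key]] <- e
  e
}

eval_env <- function(params, eta, theta, p, z) {
  list2env(c(params, list(eta = eta, theta = theta, p = p, z = z)),
           parent = baseenv())
}

#' Taylor expansion of a map about a base point
#'
#' Computes the bivariate Taylor polynomial, complete through total degree 3,
#' of each component of the selected map about \code{point}, in shifted
#' coordinates \eqn{(x, y) = (p - p_0, z - z_0)}. Derivatives are exact
#' (symbolic differentiation of the map's closed-form expression). When the
#' base point is a fixed point, the constant terms vanish and the degree-1
#' block is the Jacobian.
#'
#' @inheritParams map_jacobian
#' @param point base state; must satisfy \eqn{a + p > 0}.
#' @return Object of class \code{map_taylor}: list with \code{map_kind},
#'   \code{base}, \code{eta}, \code{theta}, \code{const} (component values
#'   minus base), and \code{cp}, \code{cz} -- 4x4 matrices whose
#'   \code{[i+1, j+1]} entry is the Taylor coefficient of \eqn{x^i y^j}.
#' @export
taylor_expand <- function(map_kind, params, eta, point, theta = NULL) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd", "hybrid"))
  check_params(params); eta <- check_eta(eta)
  point <- as_state(point)
  if (params$a + point[["p"]] <= 0)
    stop("base point too close to the singular line a + p = 0", call. = FALSE)
  if (map_kind == "hybrid") theta <- check_theta(theta)
  env <- eval_env(params, eta, theta, point[["p"]], point[["z"]])
  coef_mat <- function(component) {
    cm <- matrix(0, 4, 4)
    for (i in 0:3) for (j in 0:(3 - i)) {
      e <- map_partial_expr(map_kind, component, i, j)
      cm[i + 1, j + 1] <- eval(e, env) / (factorial(i) * factorial(j))
    }
    cm
  }
  cp <- coef_mat("p"); cz <- coef_mat("z")
  const <- c(p = cp[1, 1] - point[["p"]], z = cz[1, 1] - point[["z"]])
  cp[1, 1] <- const[["p"]]; cz[1, 1] <- const[["z"]]
  structure(list(map_kind = map_kind, base = point, eta = eta, theta = theta,
                 cp = cp, cz = cz, const = const),
            class = "map_taylor")
}

# ---- bivariate polynomial helpers (coefficient matrices, degree <= 3) ----

# evaluate coefficient matrix at (x, y)
poly_eval <- function(cm, x, y) {
  s <- 0
  for (i in 0:3) for (j in 0:3)
    if (cm[i + 1, j + 1] != 0) s <- s + cm[i + 1, j + 1] * x^i * y^j
  s
}

# substitute x = A[1,1] u + A[1,2] v, y = A[2,1] u + A[2,2] v into the
# polynomial with coefficient matrix cm; result truncated to total degree 3
poly_compose_linear <- function(cm, A) {
  out <- matrix(0, 4, 4)
  for (i in 0:3) for (j in 0:3) {
    co <- cm[i + 1, j + 1]
    if (co == 0 || i + j > 3) next
    for (ii in 0:i) for (jj in 0:j) {
      cc <- co * choose(i, ii) * A[1, 1]^ii * A[1, 2]^(i - ii) *
        choose(j, jj) * A[2, 1]^jj * A[2, 2]^(j - jj)
      du <- ii + jj; dv <- (i - ii) + (j - jj)
      out[du + 1, dv + 1] <- out[du + 1, dv + 1] + cc
    }
  }
  out
}

# partial derivative value at origin from a coefficient matrix
poly_partial <- function(cm, i, j) cm[i + 1, j + 1] * factorial(i) * factorial(j)

# keep only terms of total degree in deg_set
poly_keep_degrees <- function(cm, deg_set) {
  for (i in 0:3) for (j in 0:3)
    if (!((i + j) %in% deg_set)) cm[i + 1, j + 1] <- 0
  cm
}
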