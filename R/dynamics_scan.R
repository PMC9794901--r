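# Orbit iteration, maximal Lyapunov exponent, bifurcation-diagram and
# parameter-region scan tables.

DIVERGE_CAP <- 1e12

#' Iterate a plankton map
#'
#' Applies \code{n} steps of the selected map from \code{s0}. Orbits whose
#' components exceed \code{1e12} in magnitude (or become non-finite) are
#' truncated and flagged \code{diverged} rather than raising an error.
#'
#' @inheritParams map_jacobian
#' @param s0 initial state.
#' @param n number of steps.
#' @return Object of class \code{plankton_orbit}: list with \code{states}
#'   ((n+1) x 2 matrix unless diverged earlier), \code{diverged},
#'   \code{map_kind}, \code{eta}, \code{theta}.
#' @export
iterate_map <- function(map_kind, params, eta, s0, n, theta = NULL) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd", "hybrid"))
  check_params(params); eta <- check_eta(eta)
  s <- as_state(s0)
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  states <- matrix(NA_real_, nrow = n + 1, ncol = 2,
                   dimnames = list(NULL, c("p", "z")))
  states[1, ] <- s
  diverged <- FALSE
  step <- step_fun(map_kind, params, eta, theta)
  if (n > 0) for (i in seq_len(n)) {
    # Euler can leave the positive quadrant: bypass state validation inline
    s_new <- raw_step(map_kind, params, eta, theta, s)
    if (any(!is.finite(s_new)) || any(abs(s_new) > DIVERGE_CAP)) {
      diverged <- TRUE
      states <- states[seq_len(i), , drop = FALSE]
      break
    }
    s <- s_new
    states[i + 1, ] <- s
  }
  structure(list(states = states, diverged = diverged, map_kind = map_kind,
                 params = params, eta = eta, theta = theta),
            class = "plankton_orbit")
}

# internal: one step without non-negativity validation (Euler orbits may
# legitimately leave the positive quadrant before being flagged divergent)
raw_step <- function(map_kind, params, eta, theta, s) {
  p <- s[[1]]; z <- s[[2]]
  r <- params$r; k <- params$k; al <- params$alpha; a <- params$a
  m <- params$m; be <- params$beta; rho <- params$rho; de <- params$delta
  if (map_kind == "nsfd") {
    pn <- (1 + eta * r) * p /
      (1 + eta * (r * p / k + al * z / (a + p) + m * p))
    zn <- (1 + eta * be * p / (a + p)) * z /
      (1 + eta * (de + rho * p / (a + p)))
    return(c(pn, zn))
  }
  dp <- r * p * (1 - p / k) - al * p * z / (a + p) - m * p^2
  dz <- (be - rho) * p * z / (a + p) - de * z
  en <- c(p + eta * dp, z + eta * dz)
  if (map_kind == "euler") return(en)
  theta^3 * en + (1 - theta^3) * c(p, z)
}

#' @export
print.plankton_orbit <- function(x, ...) {
  cat(sprintf("<plankton_orbit> %s map, %d states%s\n", x$map_kind,
              nrow(x$states), if (x$diverged) " (diverged)" else ""))
  invisible(x)
}

#' Maximal Lyapunov exponent of a plankton map orbit
#'
#' Benettin-style tangent-space estimate: the tangent vector is propagated
#' through the map's Jacobian along the orbit and renormalized each step;
#' the exponent is the post-transient average of the log growth factors.
#' Deterministic given \code{s0}, \code{n} and \code{tangent_seed} (which
#' fixes the initial tangent direction).
#'
#' @inheritParams iterate_map
#' @param n total iterations (at least 1000).
#' @param transient iterations excluded from the average.
#' @param tangent_seed integer seed for the initial tangent direction.
#' @return List with \code{mle} (the exponent; \code{Inf} with
#'   \code{diverged = TRUE} when the orbit escapes) and \code{diverged}.
#' @export
mle <- function(map_kind, params, eta, s0, n = 20000, transient = 2000,
                theta = NULL, tangent_seed = 0) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd", "hybrid"))
  check_params(params); eta <- check_eta(eta)
  if (n < 1000) stop("n must be at least 1000 for a stable estimate", call. = FALSE)
  s <- as_state(s0)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(tangent_seed)
  ang <- stats::runif(1, 0, 2 * pi)
  v <- c(cos(ang), sin(ang))
  acc <- 0; cnt <- 0L
  for (i in seq_len(n)) {
    J <- map_jacobian(map_kind, params, eta, pmax(s, 0), theta)
    v <- as.numeric(J %*% v)
    nv <- sqrt(sum(v^2))
    if (nv == 0 || !is.finite(nv)) return(list(mle = Inf, diverged = TRUE))
    if (i > transient) { acc <- acc + log(nv); cnt <- cnt + 1L }
    v <- v / nv
    s <- raw_step(map_kind, params, eta, theta, s)
    if (any(!is.finite(s)) || any(abs(s) > DIVERGE_CAP))
      return(list(mle = Inf, diverged = TRUE))
  }
  list(mle = acc / cnt, diverged = FALSE)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Bifurcation-diagram data over a step-size or gain grid
#'
#' For each grid value of the scan parameter (\code{eta} or \code{theta}),
#' iterates the map, discards a transient and records sampled states in long
#' format. The default initial-state policy is sweep continuation (each grid
#' value starts from the previous value's final state), the usual way
#' bifurcation diagrams are produced; \code{s0_policy = "restart"} restarts
#' from \code{s0} at every value. Divergent grid values contribute zero rows
#' and are listed in the \code{diverged_at} attribute.
#'
#' @inheritParams iterate_map
#' @param scan \code{"eta"} or \code{"theta"}.
#' @param grid increasing scan values in (0, 1].
#' @param n_trans transient length per grid value.
#' @param n_samp samples recorded per grid value.
#' @param s0_policy \code{"continue"} or \code{"restart"}.
#' @return Object of class \code{scan_table}: data frame with columns
#'   \code{scan_value}, \code{sample_index}, \code{p}, \code{z}, plus a
#'   \code{meta} attribute recording the configuration.
#' @export
bifurcation_scan <- function(map_kind, params, scan = c("eta", "theta"),
                             grid, s0, eta = NULL, theta = NULL,
                             n_trans = 2000, n_samp = 200,
                             s0_policy = c("continue", "restart")) {
  scan <- match.arg(scan)
  s0_policy <- match.arg(s0_policy)
  map_kind <- match.arg(map_kind, c("euler", "nsfd", "hybrid"))
  check_params(params)
  if (any(grid <= 0) || any(grid > 1))
    stop("scan grid must lie in (0, 1]", call. = FALSE)
  s_cur <- as_state(s0)
  out <- vector("list", length(grid))
  diverged_at <- numeric()
  for (gi in seq_along(grid)) {
    g <- grid[gi]
    eta_g <- if (scan == "eta") g else eta
    theta_g <- if (scan == "theta") g else theta
    s_start <- if (s0_policy == "continue") s_cur else as_state(s0)
    orb <- iterate_map(map_kind, params, eta_g, s_start,
                       n = n_trans + n_samp, theta = theta_g)
    if (orb$diverged) {
      diverged_at <- c(diverged_at, g)
      s_cur <- as_state(s0)
      next
    }
    samp <- orb$states[(n_trans + 2):(n_trans + n_samp + 1), , drop = FALSE]
    out[[gi]] <- data.frame(scan_value = g, sample_index = seq_len(n_samp),
                            p = samp[, "p"], z = samp[, "z"])
    s_cur <- orb$states[nrow(orb$states), ]
    # continuation needs a valid (non-negative) restart point
    if (any(s_cur < 0)) s_cur <- pmax(s_cur, 0)
  }
  tab <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(tab))
    tab <- data.frame(scan_value = numeric(), sample_index = integer(),
                      p = numeric(), z = numeric())
  rownames(tab) <- NULL
  structure(tab,
            meta = list(map_kind = map_kind, scan = scan,
                        n_trans = n_trans, n_samp = n_samp,
                        s0 = as_state(s0), s0_policy = s0_policy,
                        eta = eta, theta = theta),
            diverged_at = diverged_at,
            class = c("scan_table", "data.frame"))
}

#' Parameter-plane classification map of a fixed point
#'
#' Classifies the chosen fixed point of the selected map over a rectangular
#' grid in two parameter (or step-size) axes. Cells where the point does not
#' exist are labelled \code{"absent"}.
#'
#' @inheritParams classify_fixed_point
#' @param params_base baseline parameter set; the two axis fields are
#'   overridden per cell.
#' @param axis1,axis2 axis names: a parameter field or \code{"eta"}.
#' @param grid1,grid2 numeric grids for the two axes.
#' @param eta baseline step size (used unless an axis is \code{"eta"}).
#' @return Data frame with columns \code{axis1}, \code{axis2}, \code{class}.
#' @export
parameter_region_scan <- function(map_kind, params_base, axis1, axis2,
                                  grid1, grid2, which_point = "boundary",
                                  eta = NULL, theta = NULL) {
  map_kind <- match.arg(map_kind, c("euler", "nsfd", "hybrid"))
  check_params(params_base)
  fields <- c(names(params_base), "eta")
  if (!axis1 %in% fields || !axis2 %in% fields)
    stop("axis names must be parameter fields or 'eta'", call. = FALSE)
  res <- expand.grid(v1 = grid1, v2 = grid2, KEEP.OUT.ATTRS = FALSE)
  cls <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    pl <- unclass(params_base)
    eta_i <- eta
    for (ax in 1:2) {
      nm <- c(axis1, axis2)[ax]; val <- res[i, ax]
      if (nm == "eta") eta_i <- val else pl[[nm]] <- val
    }
    pp <- tryCatch(suppressWarnings(do.call(plankton_params, pl)),
                   error = function(e) NULL)
    if (is.null(pp) || is.null(eta_i)) { cls[i] <- "absent"; next }
    rep_i <- tryCatch(classify_fixed_point(map_kind, pp, eta_i, which_point,
                                           theta = theta),
                      error = function(e) NULL)
    cls[i] <- if (is.null(rep_i)) "absent" else rep_i$class
  }
  names(res) <- c(axis1, axis2)
  res$class <- cls
  res
}
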