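# The reduced nondimensional planar system for (xi, theta), where
# xi = yf/h - 1/2 and time is scaled by h/v0:
#   dxi/dt    = [1 - (pi^2 rho^2 / 12)(3 csc^2(pi(xi + 1/2)) - 1)] sin(theta)
#   dtheta/dt = -(pi^3 rho^2 / 4) cot(pi(xi + 1/2)) csc^2(pi(xi + 1/2)) cos(theta)
#               + 8 alpha xi (cos^2(theta) + kappa)

DEGENERATE_DET_TOL <- 1e-10

check_xi <- function(xi) {
  if (any(abs(xi) >= 0.5)) {
    stop("cross-stream coordinate xi must satisfy -1/2 < xi < 1/2 (walls excluded)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Critical bifurcation parameter
#'
#' The closed-form threshold `beta* = pi^4/32` (about 3.044) above which
#' upstream swimming at the centerline becomes a neutral center and the two
#' off-center upstream equilibria exist.
#'
#' @return `pi^4/32`.
#' @export
beta_star <- function() pi^4 / 32

#' Right-hand side of the planar system
#'
#' @param state numeric `c(xi, theta)` (cross-stream coordinate and heading).
#' @param params a [nondim_params()] (or [model_params()]).
#' @return named numeric `c(dxi, dtheta)`.
#' @examples
#' planar_rhs(c(0, pi), nondim_params(0.1, 0.1, 1)) # equilibrium: c(0, 0)
#' @export
planar_rhs <- function(state, params) {
  params <- as_nondim_any(params)
  stopifnot(is.numeric(state), length(state) == 2L)
  xi <- state[1L]; theta <- state[2L]
  check_xi(xi)
  u <- pi * (xi + 0.5)
  cs2 <- 1 / sin(u)^2
  dxi <- (1 - pi^2 * params$rho^2 / 12 * (3 * cs2 - 1)) * sin(theta)
  dtheta <- -pi^3 * params$rho^2 / 4 * (cos(u) / sin(u)) * cs2 * cos(theta) +
    8 * params$alpha * xi * (cos(theta)^2 + params$kappa)
  c(dxi = dxi, dtheta = dtheta)
}

# left-hand side of the equilibrium transcendental equation:
# f(xi) = (pi^3/32) cot(pi(xi + 1/2)) csc^2(pi(xi + 1/2)); odd in xi,
# f'(0) = -pi^4/32 = -beta*, and f -> -Inf as xi -> 1/2.
transcendental_lhs <- function(xi) {
  u <- pi * (xi + 0.5)
  pi^3 / 32 * (cos(u) / sin(u)) / sin(u)^2
}

#' Linearize the planar system at an equilibrium
#'
#' State matrix `A` of the variational dynamics about an equilibrium with
#' heading 0 or pi. The diagonal vanishes identically (both partials carry a
#' factor `sin(theta)`), so `trace(A) = 0` exactly and stability reduces to
#' the sign of `det(A)`.
#'
#' @param eq_theta equilibrium heading, 0 or pi.
#' @param eq_xi equilibrium cross-stream coordinate.
#' @param params a [nondim_params()] (or [model_params()]).
#' @param check verify that `(eq_xi, eq_theta)` is an equilibrium (default).
#' @return a 2x2 matrix.
#' @export
linearize <- function(eq_theta, eq_xi, params, check = TRUE) {
  params <- as_nondim_any(params)
  check_xi(eq_xi)
  if (!isTRUE(all.equal(abs(sin(eq_theta)), 0, tolerance = 1e-9))) {
    stop("equilibria have heading 0 or pi; got theta = ", eq_theta,
         call. = FALSE)
  }
  if (check) {
    r <- planar_rhs(c(eq_xi, eq_theta), params)
    if (max(abs(r)) > 1e-8) {
      stop(sprintf("(xi = %g, theta = %g) is not an equilibrium: |rhs| = %.3e",
                   eq_xi, eq_theta, max(abs(r))), call. = FALSE)
    }
  }
  ct <- cos(eq_theta)  # +1 or -1
  u <- pi * (eq_xi + 0.5)
  cs2 <- 1 / sin(u)^2
  cot2 <- (cos(u) / sin(u))^2
  a12 <- ct * (1 - pi^2 * params$rho^2 / 12 * (3 * cs2 - 1))
  a21 <- ct * pi^4 * params$rho^2 / 4 * (cs2^2 + 2 * cot2 * cs2) +
    8 * params$alpha * (ct^2 + params$kappa)
  matrix(c(0, a21, a12, 0), 2L, 2L)
}

#' Classify a zero-trace equilibrium from its state matrix
#'
#' With zero trace the eigenvalues are `+/- sqrt(det A)`-conjugates: a saddle
#' (real, opposite signs) for `det < 0` and a neutral center (purely
#' imaginary) for `det > 0`. Determinants within `tol` of zero are reported
#' as `"degenerate"` (the transition `beta = beta*`).
#'
#' @param A a 2x2 matrix with `|trace| < 1e-9`.
#' @param tol degeneracy band on the determinant.
#' @return `"saddle"`, `"neutral_center"` or `"degenerate"`.
#' @export
classify <- function(A, tol = DEGENERATE_DET_TOL) {
  stopifnot(is.matrix(A), all(dim(A) == 2L))
  tr <- A[1L, 1L] + A[2L, 2L]
  if (abs(tr) >= 1e-9) {
    stop(sprintf("classify() expects a zero-trace matrix (model guarantee); trace = %.3e",
                 tr), call. = FALSE)
  }
  d <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  if (d < -tol) "saddle" else if (d > tol) "neutral_center" else "degenerate"
}

make_equilibrium <- function(theta, xi, params) {
  A <- linearize(theta, xi, params, check = FALSE)
  d <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  structure(list(theta = theta, xi = xi, state_matrix = A,
                 trace = A[1L, 1L] + A[2L, 2L], det = d,
                 eigenvalues = eigen(A, only.values = TRUE)$values,
                 classification = classify(A)),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> theta = %s, xi = %.10g: %s (det A = %.6g)\n",
              if (abs(x$theta) < 1e-12) "0" else "pi", x$xi,
              x$classification, x$det))
  invisible(x)
}

#' Equilibria of the planar system
#'
#' Solves the transcendental equilibrium condition
#' `(pi^3/32) cot(pi(xi+1/2)) csc^2(pi(xi+1/2)) = +/- beta xi`
#' (+ for downstream `theta = 0`, - for upstream `theta = pi`).
#' Downstream swimming admits only the centerline equilibrium, a saddle.
#' Upstream swimming admits the centerline equilibrium (neutral center iff
#' `beta > beta*`) and, for `beta > beta*`, a symmetric pair `+/- xi*` of
#' saddles that approaches the walls as `beta -> Inf`. Roots are bracketed
#' on a fine grid in `(0, 1/2)` (the curve is odd and strictly decreasing)
#' and polished with [stats::uniroot()].
#'
#' @param params a [nondim_params()] (or [model_params()]).
#' @param grid_n number of grid points used for bracketing.
#' @return a list of `equilibrium` objects, class `equilibria`.
#' @export
find_equilibria <- function(params, grid_n = 10000L) {
  params <- as_nondim_any(params)
  beta <- params$beta
  eqs <- list(make_equilibrium(0, 0, params),   # downstream centerline
              make_equilibrium(pi, 0, params))  # upstream centerline
  if (beta > beta_star()) {
    # g(xi) = f(xi) + beta*xi has exactly one root in (0, 1/2):
    # g'(0) = beta - beta* > 0 and g -> -Inf at the wall
    g <- function(xi) transcendental_lhs(xi) + beta * xi
    xs <- seq(1 / grid_n, 0.5 - 1e-9, length.out = grid_n)
    gs <- g(xs)
    i <- which(gs[-1L] * gs[-length(gs)] <= 0)
    if (length(i) == 0L) {
      stop(sprintf("root bracketing failed for beta = %g on (0, 1/2) with %d grid points",
                   beta, grid_n), call. = FALSE)
    }
    root <- stats::uniroot(g, c(xs[i[1L]], xs[i[1L] + 1L]),
                           tol = 1e-15)$root
    eqs <- c(eqs, list(make_equilibrium(pi, root, params),
                       make_equilibrium(pi, -root, params)))
  }
  structure(eqs, class = "equilibria", beta = beta)
}

#' @export
print.equilibria <- function(x, ...) {
  cat(sprintf("Planar-system equilibria (beta = %g, beta* = %.6g):\n",
              attr(x, "beta"), beta_star()))
  for (e in x) print(e)
  invisible(x)
}

#' Cross-stream sweeping frequency
#'
#' Small-amplitude radian frequency of the periodic orbits about the stable
#' upstream centerline equilibrium, in nondimensional time units (`h/v0`):
#' `omega0 = sqrt(det A)` at `(theta = pi, xi = 0)`. For `rho << 1` this is
#' approximately `(pi^2/2) rho sqrt(beta/beta* - 1)` (`method =
#' "small_rho"`). Zero at `beta = beta*`, increasing with `sqrt(beta)`.
#'
#' @param params a [nondim_params()] (or [model_params()]).
#' @param method `"exact"` (default) or `"small_rho"`.
#' @return radian frequency per nondimensional time.
#' @export
sweeping_frequency <- function(params, method = c("exact", "small_rho")) {
  params <- as_nondim_any(params)
  method <- match.arg(method)
  if (params$beta < beta_star()) {
    stop(sprintf("beta = %g < beta* = %g: upstream swimming is unstable and there is no sweeping oscillation",
                 params$beta, beta_star()), call. = FALSE)
  }
  if (method == "small_rho") {
    return(pi^2 / 2 * params$rho * sqrt(params$beta / beta_star() - 1))
  }
  A <- linearize(pi, 0, params, check = FALSE)
  d <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  sqrt(max(d, 0))
}

#' Bifurcation sweep of the upstream equilibria
#'
#' Tabulates the upstream (`theta = pi`) equilibrium branches over a grid of
#' `beta` values, holding `rho` and `kappa` fixed and adjusting `alpha`
#' (`alpha = beta rho^2 / (1 + kappa)`). Reproduces the pitchfork-like
#' diagram: one branch below `beta*`, three above.
#'
#' @param params a [nondim_params()] providing `rho` and `kappa`.
#' @param beta_grid positive, ordered values of `beta`.
#' @return a data.frame with columns `beta`, `xi`, `classification`.
#' @export
bifurcation_sweep <- function(params, beta_grid) {
  params <- as_nondim_any(params)
  stopifnot(is.numeric(beta_grid), all(beta_grid >= 0))
  rows <- lapply(beta_grid, function(b) {
    p <- nondim_params(params$rho, b * params$rho^2 / (1 + params$kappa),
                       params$kappa)
    eqs <- find_equilibria(p)
    up <- Filter(function(e) abs(e$theta - pi) < 1e-12, eqs)
    data.frame(beta = b,
               xi = vapply(up, `[[`, numeric(1), "xi"),
               classification = vapply(up, `[[`, character(1), "classification"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Vector field of the planar system on a grid
#'
#' @param params a [nondim_params()] (or [model_params()]).
#' @param xi_range,theta_range grid extents (xi strictly inside (-1/2, 1/2)).
#' @param nxi,ntheta grid resolution.
#' @return a data.frame `xi`, `theta`, `dxi`, `dtheta` with the equilibria
#'   attached as attribute `"equilibria"`.
#' @export
phase_portrait <- function(params, xi_range = c(-0.45, 0.45),
                           theta_range = c(-pi, pi), nxi = 21L, ntheta = 21L) {
  params <- as_nondim_any(params)
  check_xi(xi_range)
  g <- expand.grid(xi = seq(xi_range[1L], xi_range[2L], length.out = nxi),
                   theta = seq(theta_range[1L], theta_range[2L],
                               length.out = ntheta),
                   KEEP.OUT.ATTRS = FALSE)
  d <- t(apply(g, 1L, function(s) planar_rhs(c(s[["xi"]], s[["theta"]]), params)))
  out <- data.frame(xi = g$xi, theta = g$theta, dxi = d[, 1L], dtheta = d[, 2L])
  attr(out, "equilibria") <- find_equilibria(params)
  out
}

#' Curves of the equilibrium transcendental equation
#'
#' Tabulates the odd curve `(pi^3/32) cot(pi(xi+1/2)) csc^2(pi(xi+1/2))`
#' together with straight lines of the requested slopes; equilibria are the
#' intersections with `+beta xi` (downstream) or `-beta xi` (upstream). The
#' curve's slope at the origin is `-beta*`.
#'
#' @param xi_grid interior grid of xi values.
#' @param slopes line slopes to tabulate (default the illustrative set
#'   `c(200, -200, -2)`).
#' @return a data.frame with columns `xi`, `curve`, and one `line_<slope>`
#'   column per slope.
#' @export
transcendental_curves <- function(xi_grid = seq(-0.49, 0.49, length.out = 197L),
                                  slopes = c(200, -200, -2)) {
  check_xi(xi_grid)
  out <- data.frame(xi = xi_grid, curve = transcendental_lhs(xi_grid))
  for (s in slopes) {
    out[[paste0("line_", gsub("-", "m", format(s)))]] <- s * xi_grid
  }
  out
}

#' Simulate the nondimensional planar system
#'
#' Integrates `(xi, theta)` under [planar_rhs()] with the adaptive solver,
#' stopping at the horizon or when `xi` leaves `[-1/2 + delta, 1/2 - delta]`.
#'
#' @param initial numeric `c(xi, theta)`.
#' @param params a [nondim_params()] (or [model_params()]).
#' @param horizon integration horizon (nondimensional time).
#' @param solver a [solver_policy()].
#' @param wall_delta wall-proximity band (fraction of the half-width from
#'   the wall; default 0.01).
#' @return a data.frame of class `planar_trajectory` with columns `time`,
#'   `xi`, `theta` and attributes `termination`, `event_time`.
#' @export
simulate_planar <- function(initial, params, horizon,
                            solver = solver_policy(), wall_delta = 0.01) {
  params <- as_nondim_any(params)
  stopifnot(is.numeric(initial), length(initial) == 2L, horizon > 0)
  check_xi(initial[1L])
  # out-of-domain trial states make the step reject (NaN error norm)
  rhs <- function(t, y) {
    if (!all(is.finite(y)) || abs(y[1L]) >= 0.5) return(c(NaN, NaN))
    unname(planar_rhs(y, params))
  }
  lim <- 0.5 - wall_delta
  event <- function(t, y) lim - abs(y[1L])
  sol <- ode_rk45(rhs, initial, 0, horizon, solver, event)
  structure(data.frame(time = sol$t, xi = sol$y[, 1L], theta = sol$y[, 2L]),
            class = c("planar_trajectory", "data.frame"),
            termination = if (is.null(sol$event)) "horizon" else "wall_event",
            event_time = if (is.null(sol$event)) NA_real_ else sol$event$time)
}

#' Measure the sweeping period of a small-amplitude orbit
#'
#' Integrates the planar system from `(amplitude, pi)` and measures the mean
#' period from successive upward zero crossings of `xi(t)`, located by
#' linear interpolation between accepted solver steps. Serves as the
#' independent oracle for [sweeping_frequency()].
#'
#' @param params a [nondim_params()] with `beta > beta*`.
#' @param amplitude initial cross-stream offset (default 1e-3).
#' @param cycles number of oscillation cycles to average over.
#' @param solver a [solver_policy()].
#' @return the measured period (nondimensional time).
#' @export
orbit_period <- function(params, amplitude = 1e-3, cycles = 10L,
                         solver = solver_policy()) {
  params <- as_nondim_any(params)
  w0 <- sweeping_frequency(params)  # errors if beta < beta*
  if (w0 <= 0) stop("beta = beta*: the orbit period diverges", call. = FALSE)
  horizon <- (cycles + 1.5) * 2 * pi / w0
  tr <- simulate_planar(c(amplitude, pi), params, horizon, solver)
  xi <- tr$xi; tt <- tr$time
  up <- which(xi[-length(xi)] < 0 & xi[-1L] >= 0)
  if (length(up) < 2L) {
    stop("fewer than two upward zero crossings: no bounded oscillation detected",
         call. = FALSE)
  }
  tc <- tt[up] - xi[up] * (tt[up + 1L] - tt[up]) / (xi[up + 1L] - xi[up])
  mean(diff(tc))
}
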