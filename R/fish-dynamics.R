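# Equations of motion of the swimmer. The drift terms use the closed-form
# de-singularized expressions (walls + background evaluated at the swimmer);
# the truncated image series serves only as a test oracle.

#' De-singularized advective velocity at the swimmer
#'
#' Sum of the wall-image and background velocities evaluated at the fish
#' location, with the swimmer's own singularity removed:
#' `U = -(pi^2 v0 rho^2 / 12) * [(1 + 3csc^2(pi yf/h)) cos(theta),
#'  -(1 - 3csc^2(pi yf/h)) sin(theta)] + (ub(yf), 0)`.
#' The walls retard the swimmer increasingly as it approaches either one.
#'
#' @param fish a [fish_state()] strictly inside the channel.
#' @param params a [model_params()].
#' @return named velocity `c(x, y)`.
#' @export
advective_velocity <- function(fish, params) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  check_inside_channel(fish, params)
  cs2 <- 1 / sin(pi * fish$y / params$h)^2
  a <- pi^2 * params$v0 * params$rho^2 / 12
  ub <- params$U0 * (1 - 4 * params$eps * (fish$y / params$h - 0.5)^2)
  c(x = -a * (1 + 3 * cs2) * cos(fish$theta) + ub,
    y =  a * (1 - 3 * cs2) * sin(fish$theta))
}

#' Hydrodynamic turn rate at the swimmer
#'
#' Rotation rate induced on the dipole by the velocity difference across its
#' two vortices (T-dipole rule), in the limit of vanishing dipole length:
#' `Omega = -(pi^3 rho^2 v0 / 4h) cot(pi yf/h) csc^2(pi yf/h) cos(theta)
#'  + (8 U0 eps / h) (yf/h - 1/2) cos^2(theta)`.
#' The wall term turns the swimmer toward the nearest wall; the shear term
#' is counter-clockwise in the upper half of the channel and clockwise in
#' the lower half, irrespective of heading.
#'
#' @inheritParams advective_velocity
#' @return turn rate (rad/time).
#' @export
turn_rate <- function(fish, params) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  check_inside_channel(fish, params)
  u <- pi * fish$y / params$h
  wall <- -pi^3 * params$rho^2 * params$v0 / (4 * params$h) *
    (cos(u) / sin(u)) / sin(u)^2 * cos(fish$theta)
  shear <- 8 * params$U0 * params$eps / params$h *
    (fish$y / params$h - 0.5) * cos(fish$theta)^2
  wall + shear
}

#' Finite-dipole turn rate (series oracle)
#'
#' Turn rate computed from the actual velocity difference between the two
#' constituent vortices at `rf +/- (r0/2) * vperp`, using the image-series
#' wall field plus the background flow:
#' `Omega_fd = ((U(right) - U(left)) / r0) . vhat`.
#' Converges to [turn_rate()] as `r0 -> 0` with an O(r0^2) error; used as
#' the independent finite-dipole oracle for the closed form.
#'
#' @inheritParams advective_velocity
#' @param trunc a [truncation_policy()].
#' @param method passed to [wall_velocity()].
#' @return turn rate (rad/time).
#' @export
turn_rate_finite_dipole <- function(fish, params, trunc = truncation_policy(),
                                    method = c("series", "closed")) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  method <- match.arg(method)
  check_inside_channel(fish, params)
  vhat <- c(cos(fish$theta), sin(fish$theta))
  vperp <- c(-vhat[2L], vhat[1L])  # k x vhat
  left  <- c(fish$x, fish$y) + params$r0 / 2 * vperp
  right <- c(fish$x, fish$y) - params$r0 / 2 * vperp
  if (left[2L] <= 0 || left[2L] >= params$h ||
      right[2L] <= 0 || right[2L] >= params$h) {
    stop("finite-dipole vortex lies outside the channel", call. = FALSE)
  }
  U <- function(p) {
    wall_velocity(p, fish, params, trunc, method) + background_velocity(p, params)
  }
  sum((U(right) - U(left)) / params$r0 * vhat)
}

#' Lateral-line feedback turn rate
#'
#' Linear feedback on the circulation sensed over a rectangle of width `r0`
#' along the body length `l` centered at the fish:
#' `lambda = K * Gamma = K r0 l (8 U0 eps / h) (yf/h - 1/2)`.
#' Because the vorticity is linear in `y`, this closed form equals the exact
#' integral of the vorticity over the sensing rectangle times `K`.
#'
#' @inheritParams advective_velocity
#' @return feedback turn rate (rad/time).
#' @export
lateral_line_feedback <- function(fish, params) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  params$K * params$r0 * params$l * 8 * params$U0 * params$eps / params$h *
    (fish$y / params$h - 0.5)
}

#' Simulate the swimmer's trajectory
#'
#' Integrates the inertialess equations of motion
#' `d(rf)/dt = U + v0 vhat`, `d(theta)/dt = Omega + lambda`
#' with the adaptive Dormand-Prince solver. Integration terminates at the
#' horizon or when `yf/h` leaves `[wall_delta, 1 - wall_delta]` (the closed
#' forms are singular at the walls and the model excludes wall contact).
#' The heading is stored unwrapped (continuous); wrap for reporting with
#' [wrap_angle()].
#'
#' @param initial a [fish_state()] strictly inside the channel.
#' @param params a [model_params()].
#' @param horizon integration horizon (time units).
#' @param solver a [solver_policy()].
#' @param wall_delta wall-proximity band as a fraction of `h` (default 0.01).
#' @return a data.frame of class `fish_trajectory` with columns `time`, `x`,
#'   `y`, `theta`, and attributes `termination` (`"horizon"` or
#'   `"wall_event"`), `event_time` and `params`.
#' @export
simulate_fish <- function(initial, params, horizon,
                          solver = solver_policy(), wall_delta = 0.01) {
  stopifnot(inherits(initial, "fish_state"), inherits(params, "model_params"),
            horizon > 0, wall_delta > 0, wall_delta < 0.5)
  check_inside_channel(initial, params)
  rhs <- function(t, y) {
    if (!all(is.finite(y)) || y[2L] <= 0 || y[2L] >= params$h) {
      return(c(NaN, NaN, NaN))
    }
    st <- list(x = y[1L], y = y[2L], theta = y[3L])
    class(st) <- "fish_state"
    adv <- advective_velocity(st, params)
    c(adv[1L] + params$v0 * cos(y[3L]),
      adv[2L] + params$v0 * sin(y[3L]),
      turn_rate(st, params) + lateral_line_feedback(st, params))
  }
  band <- c(wall_delta, 1 - wall_delta) * params$h
  event <- function(t, y) min(y[2L] - band[1L], band[2L] - y[2L])
  sol <- ode_rk45(rhs, c(initial$x, initial$y, initial$theta), 0, horizon,
                  solver, event)
  out <- data.frame(time = sol$t, x = sol$y[, 1L], y = sol$y[, 2L],
                    theta = sol$y[, 3L])
  structure(out,
            class = c("fish_trajectory", "data.frame"),
            termination = if (is.null(sol$event)) "horizon" else "wall_event",
            event_time = if (is.null(sol$event)) NA_real_ else sol$event$time,
            params = params)
}

#' @export
print.fish_trajectory <- function(x, ...) {
  term <- attr(x, "termination")
  cat(sprintf("<fish_trajectory> %d samples over t in [%g, %g]; termination: %s%s\n",
              nrow(x), x$time[1L], x$time[nrow(x)], term,
              if (term == "wall_event")
                sprintf(" (t = %g)", attr(x, "event_time")) else ""))
  last <- x[nrow(x), ]
  cat(sprintf("  final state: x = %g, y = %g, theta = %g rad (wrapped %g)\n",
              last$x, last$y, last$theta, wrap_angle(last$theta)))
  invisible(x)
}
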