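# Potential flow of the dipole, its wall images, and the background shear.
#
# Internally the field is handled as a complex velocity q = u - i*v at the
# complex position z = x + i*y; the dipole with heading theta at zf has
# complex potential w(z) = -r0^2 v0 e^{i theta} / (z - zf), so that
# q(z) = dw/dz = r0^2 v0 e^{i theta} / (z - zf)^2.

GUARD_FACTOR <- 1e-6  # singularity guard radius, in units of h

as_complex_points <- function(at) {
  if (is.matrix(at)) {
    stopifnot(ncol(at) == 2L)
    complex(real = at[, 1L], imaginary = at[, 2L])
  } else {
    stopifnot(is.numeric(at), length(at) == 2L)
    complex(real = at[1L], imaginary = at[2L])
  }
}

vec2_out <- function(q, at) {
  if (is.matrix(at)) cbind(x = Re(q), y = -Im(q))
  else c(x = Re(q), y = -Im(q))
}

check_singularity <- function(z, zs, h, what = "dipole") {
  d <- outer(z, zs, function(a, b) Mod(a - b))
  bad <- which(d < GUARD_FACTOR * h, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    zb <- z[bad[1L, 1L]]
    stop(sprintf("evaluation point (%g, %g) coincides with a %s singularity (guard radius %g*h)",
                 Re(zb), Im(zb), what, GUARD_FACTOR), call. = FALSE)
  }
  invisible(TRUE)
}

# complex dipole velocity, no guards (internal)
dipole_q <- function(z, zf, theta, v0, r0) {
  r0^2 * v0 * exp(1i * theta) / (z - zf)^2
}

#' Dipole velocity potential
#'
#' Scalar potential of a far-field vortex dipole of length scale `r0`
#' swimming with speed `v0` and heading `theta`:
#' `phi = -r0^2 * ((r - rf) . vf) / ||r - rf||^2`, where
#' `vf = v0*(cos(theta), sin(theta))`.
#'
#' @param at evaluation point: numeric `c(x, y)` or an n-by-2 matrix.
#' @param fish a [fish_state()].
#' @param params a [model_params()].
#' @return potential value(s) (length^2/time).
#' @examples
#' p <- model_params(h = 1, v0 = 1, r0 = 0.1)
#' dipole_potential(c(1, 0), fish_state(0, 0.5, 0), p) # for a fish at y=0.5
#' @export
dipole_potential <- function(at, fish, params) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  z <- as_complex_points(at)
  zf <- complex(real = fish$x, imaginary = fish$y)
  check_singularity(z, zf, params$h)
  d <- z - zf
  # (d . v) / |d|^2 = Re(conj(d) e^{i theta}) / |d|^2
  -params$r0^2 * params$v0 * Re(Conj(d) * exp(1i * fish$theta)) / Mod(d)^2
}

#' Dipole velocity field
#'
#' Analytic gradient of [dipole_potential()], returned as components
#' `(ux, uy)`.
#'
#' @inheritParams dipole_potential
#' @return velocity: named numeric `c(x, y)` or an n-by-2 matrix matching
#'   the shape of `at`.
#' @export
dipole_velocity <- function(at, fish, params) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  z <- as_complex_points(at)
  zf <- complex(real = fish$x, imaginary = fish$y)
  check_singularity(z, zf, params$h)
  vec2_out(dipole_q(z, zf, fish$theta, params$v0, params$r0), at)
}

#' Image poses of the swimmer
#'
#' The n-th set of the four wall images of a swimmer at `(xf, yf)` with
#' heading `theta`: below the lower wall at `yf - 2(n+1)h` (heading `+theta`)
#' and `-yf - 2nh` (heading `-theta`), and above the upper wall at
#' `yf + 2(n+1)h` (heading `+theta`) and `-yf + 2(n+1)h` (heading `-theta`).
#'
#' @param fish a [fish_state()].
#' @param params a [model_params()].
#' @param n non-negative integer index of the image set.
#' @return a list of four `fish_state` objects, named
#'   `below_same`, `below_opposite`, `above_same`, `above_opposite`.
#' @export
image_states <- function(fish, params, n) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    stop("image set index n must be a non-negative integer", call. = FALSE)
  }
  h <- params$h
  list(
    below_same     = fish_state(fish$x,  fish$y - 2 * (n + 1) * h,  fish$theta),
    below_opposite = fish_state(fish$x, -fish$y - 2 * n * h,       -fish$theta),
    above_same     = fish_state(fish$x,  fish$y + 2 * (n + 1) * h,  fish$theta),
    above_opposite = fish_state(fish$x, -fish$y + 2 * (n + 1) * h, -fish$theta)
  )
}

# The four image families as lattices 1/(a + b*n)^2, n = 0, 1, 2, ...
# (complex a per evaluation point, constant b), used for both the raw sum
# and the analytic Euler-Maclaurin tail.
image_families <- function(z, zf, theta, h) {
  list(
    list(phase =  theta, a = z - zf + 2i * h,       b =  2i * h), # yf - 2(n+1)h
    list(phase = -theta, a = z - Conj(zf),          b =  2i * h), # -yf - 2nh
    list(phase =  theta, a = z - zf - 2i * h,       b = -2i * h), # yf + 2(n+1)h
    list(phase = -theta, a = z - Conj(zf) - 2i * h, b = -2i * h)  # -yf + 2(n+1)h
  )
}

# complex wall velocity via truncated image series (vectorized over z)
wall_q_series <- function(z, zf, theta, v0, r0, h, trunc) {
  N <- trunc$max_sets
  fam <- image_families(z, zf, theta, h)
  tot <- rep(0 + 0i, length(z))
  for (f in fam) {
    n <- seq.int(0L, N - 1L)
    # sum over n of 1/(a + b n)^2 for each z
    terms <- vapply(seq_along(z), function(i) sum(1 / (f$a[i] + f$b * n)^2),
                    complex(1))
    tot <- tot + exp(1i * f$phase) * terms
  }
  err_est <- 0
  if (trunc$tail_correction) {
    tail <- rep(0 + 0i, length(z))
    for (f in fam) {
      s <- f$a + f$b * N
      integral <- 1 / (f$b * s)       # int_N^Inf dn / (a + b n)^2
      f0 <- 1 / s^2
      f1 <- -2 * f$b / s^3
      f3 <- -24 * f$b^3 / s^5
      tail <- tail + exp(1i * f$phase) * (integral + f0 / 2 - f1 / 12 + f3 / 720)
      # next Euler-Maclaurin term (f^(5)/30240) bounds the residual
      err_est <- err_est + max(Mod(-720 * f$b^5 / s^7)) / 30240
    }
    tot <- tot + tail
  } else {
    # raw truncation: the absolutely-convergent tail is O(1/N)
    err_est <- 4 / ((2 * h)^2 * max(N - 1, 1))
  }
  list(q = r0^2 * v0 * tot, err = r0^2 * v0 * err_est)
}

# closed form by cotangent-lattice summation:
#   sum_{m in Z} 1/(zeta - 2ihm)^2 = (pi/(2h))^2 csch^2(pi zeta / (2h))
wall_q_closed <- function(z, zf, theta, v0, r0, h) {
  S <- function(zeta) (pi / (2 * h))^2 / sinh(pi * zeta / (2 * h))^2
  d <- z - zf
  same <- ifelse(Mod(d) == 0,
                 complex(real = -pi^2 / (12 * h^2)),  # removable limit
                 S(d) - 1 / d^2)
  r0^2 * v0 * (exp(1i * theta) * same + exp(-1i * theta) * S(z - Conj(zf)))
}

# all image singularity positions near enough to matter for guarding:
# y in {yf + 2mh} u {-yf + 2mh} at x = xf, excluding the fish itself.
check_image_singularity <- function(z, fish, h) {
  near_x <- abs(Re(z) - fish$x) < GUARD_FACTOR * h
  if (!any(near_x)) return(invisible(TRUE))
  y <- Im(z)[near_x]
  d_same <- abs((y - fish$y) / (2 * h) - round((y - fish$y) / (2 * h))) * 2 * h
  d_opp  <- abs((y + fish$y) / (2 * h) - round((y + fish$y) / (2 * h))) * 2 * h
  self <- abs(y - fish$y) < GUARD_FACTOR * h  # fish itself is not an image
  hit <- (pmin(d_same, d_opp) < GUARD_FACTOR * h) & !self
  if (any(hit)) {
    yb <- y[which(hit)[1L]]
    stop(sprintf("evaluation point (%g, %g) coincides with an image singularity (guard radius %g*h)",
                 fish$x, yb, GUARD_FACTOR), call. = FALSE)
  }
  invisible(TRUE)
}

#' Wall-induced velocity (method of images)
#'
#' Velocity at `at` due to the infinite lattice of image dipoles that
#' enforces no-penetration at both channel walls. The reference route is
#' the truncated series with an analytic Euler-Maclaurin tail correction
#' (see [truncation_policy()]); `method = "closed"` evaluates an equivalent
#' closed form obtained by cotangent-lattice summation and is used as an
#' independent cross-check.
#'
#' @inheritParams dipole_potential
#' @param trunc a [truncation_policy()]; ignored for `method = "closed"`.
#' @param method `"series"` (reference) or `"closed"`.
#' @return velocity, shaped like `at`.
#' @export
wall_velocity <- function(at, fish, params, trunc = truncation_policy(),
                          method = c("series", "closed")) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  method <- match.arg(method)
  check_inside_channel(fish, params)
  z <- as_complex_points(at)
  check_image_singularity(z, fish, params$h)
  zf <- complex(real = fish$x, imaginary = fish$y)
  if (method == "closed") {
    q <- wall_q_closed(z, zf, fish$theta, params$v0, params$r0, params$h)
  } else {
    stopifnot(inherits(trunc, "truncation_policy"))
    res <- wall_q_series(z, zf, fish$theta, params$v0, params$r0, params$h, trunc)
    if (trunc$check && res$err >= trunc$tol * params$v0) {
      stop(sprintf("image series not converged: truncation error estimate %.3e exceeds %.3e (= tol * v0) after %d sets; increase max_sets or enable tail_correction",
                   res$err, trunc$tol * params$v0, trunc$max_sets), call. = FALSE)
    }
    q <- res$q
  }
  vec2_out(q, at)
}

#' Partial sums of the wall-image series
#'
#' Diagnostic: the cumulative raw per-set contributions of the image series
#' at a single point, without tail correction. Used to characterize the
#' O(1/N) convergence of plain truncation.
#'
#' @inheritParams wall_velocity
#' @param max_sets number of sets to tabulate.
#' @return a data.frame with columns `n`, `ux`, `uy` (partial sums through
#'   set `n`) and `increment` (modulus of the n-th set's contribution).
#' @export
wall_series_partial_sums <- function(at, fish, params, max_sets = 200L) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  z <- as_complex_points(at)
  stopifnot(length(z) == 1L)
  zf <- complex(real = fish$x, imaginary = fish$y)
  fam <- image_families(z, zf, fish$theta, params$h)
  n <- seq.int(0L, max_sets - 1L)
  per_set <- rep(0 + 0i, max_sets)
  for (f in fam) {
    per_set <- per_set + exp(1i * f$phase) / (f$a + f$b * n)^2
  }
  per_set <- params$r0^2 * params$v0 * per_set
  q <- cumsum(per_set)
  data.frame(n = n, ux = Re(q), uy = -Im(q), increment = Mod(per_set))
}

#' Background channel flow
#'
#' Weakly rotational streamwise profile
#' `ub = U0 * (1 - 4*eps*(y/h - 1/2)^2)` in the x direction: speed `U0` at
#' the centerline, `U0*(1-eps)` at the walls; irrotational and uniform for
#' `eps = 0`.
#'
#' @inheritParams dipole_potential
#' @return velocity, shaped like `at`.
#' @export
background_velocity <- function(at, params) {
  stopifnot(inherits(params, "model_params"))
  z <- as_complex_points(at)
  y <- Im(z)
  ux <- params$U0 * (1 - 4 * params$eps * (y / params$h - 0.5)^2)
  vec2_out(complex(real = ux, imaginary = 0), at)
}

#' Local vorticity of the channel flow
#'
#' Only the background shear is rotational; the dipole and its images are
#' potential flow and contribute nothing. The vorticity is linear in the
#' cross-stream coordinate: `omega = (8*U0*eps/h) * (y/h - 1/2)`.
#'
#' @inheritParams background_velocity
#' @return vorticity value(s) (1/time).
#' @export
vorticity <- function(at, params) {
  stopifnot(inherits(params, "model_params"))
  z <- as_complex_points(at)
  y <- Im(z)
  8 * params$U0 * params$eps / params$h * (y / params$h - 0.5)
}

#' Total fluid velocity in the channel
#'
#' Superposition of dipole, wall-image and background contributions.
#'
#' @inheritParams wall_velocity
#' @return velocity, shaped like `at`.
#' @export
total_velocity <- function(at, fish, params, trunc = truncation_policy(),
                           method = c("series", "closed")) {
  dipole_velocity(at, fish, params) +
    wall_velocity(at, fish, params, trunc, method) +
    background_velocity(at, params)
}

#' Circulation over a rectangular sensing region
#'
#' Integral of the vorticity over a rectangle of width `width` (across the
#' body) and length `length` (along the body) centered at `center` with the
#' long axis at angle `heading`. Because the vorticity is linear in `y`, the
#' integral is exactly `area * vorticity(centroid)`; with the rectangle
#' centered at the fish and `width = r0`, `length = l`, the product
#' `K * Gamma` reproduces the lateral-line feedback term.
#'
#' @param center rectangle centroid, numeric `c(x, y)`.
#' @param heading orientation of the long axis (radians).
#' @param width across-body extent (length units).
#' @param length along-body extent (length units).
#' @param params a [model_params()].
#' @return circulation (length^2/time).
#' @export
circulation_rectangle <- function(center, heading, width, length, params) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(center), base::length(center) == 2L,
            width > 0, length > 0)
  # rectangle corners in channel coordinates
  c_ <- cos(heading); s_ <- sin(heading)
  half <- rbind(c( length / 2,  width / 2), c( length / 2, -width / 2),
                c(-length / 2,  width / 2), c(-length / 2, -width / 2))
  corners_y <- center[2L] + half[, 1L] * s_ + half[, 2L] * c_
  if (any(corners_y < 0) || any(corners_y > params$h)) {
    stop("sensing rectangle extends outside the channel", call. = FALSE)
  }
  width * length * vorticity(center, params)
}

#' Evaluate the flow field on a grid
#'
#' Tabulates the total velocity and vorticity on a regular grid, excluding a
#' disk of radius `exclude_radius` around the swimmer where the far-field
#' dipole model is invalid (values there are `NA`).
#'
#' @inheritParams wall_velocity
#' @param xlim,ylim grid extents; `ylim` defaults to the open channel.
#' @param nx,ny number of grid points in each direction.
#' @param exclude_radius exclusion radius around the fish (default `r0`).
#' @return a data.frame with columns `x`, `y`, `ux`, `uy`, `vorticity`.
#' @export
field_table <- function(fish, params, xlim = fish$x + c(-2, 2) * params$h,
                        ylim = c(0, params$h), nx = 41L, ny = 21L,
                        trunc = truncation_policy(),
                        exclude_radius = params$r0) {
  stopifnot(inherits(fish, "fish_state"), inherits(params, "model_params"))
  xs <- seq(xlim[1L], xlim[2L], length.out = nx)
  ys <- seq(ylim[1L], ylim[2L], length.out = ny)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  pts <- as.matrix(g)
  keep <- sqrt((g$x - fish$x)^2 + (g$y - fish$y)^2) > max(exclude_radius,
                                                          GUARD_FACTOR * params$h)
  u <- matrix(NA_real_, nrow(g), 2L)
  if (any(keep)) {
    u[keep, ] <- total_velocity(pts[keep, , drop = FALSE], fish, params, trunc)
  }
  data.frame(x = g$x, y = g$y, ux = u[, 1L], uy = u[, 2L],
             vorticity = vorticity(pts, params))
}
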