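#' Wrap an angle to (-pi, pi]
#'
#' @param theta angle(s) in radians.
#' @return angle(s) wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(3 * pi / 2)
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

#' Swimmer pose
#'
#' Dimensional pose of the swimmer: streamwise position `x`, cross-stream
#' position `y` (walls at `y = 0` and `y = h`) and heading `theta` in radians,
#' positive counter-clockwise from the +x axis. The heading is wrapped to
#' (-pi, pi] at construction.
#'
#' @param x streamwise position (length units).
#' @param y cross-stream position (length units); must satisfy `0 < y < h`
#'   for the channel of any [model_params()] it is used with (checked at the
#'   point of use, since the state itself does not know `h`).
#' @param theta heading angle in radians.
#' @return an object of class `fish_state`.
#' @examples
#' fish_state(0, 0.5, pi)
#' @export
fish_state <- function(x, y, theta) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(theta),
            length(x) == 1L, length(y) == 1L, length(theta) == 1L,
            is.finite(x), is.finite(y), is.finite(theta))
  structure(list(x = x, y = y, theta = wrap_angle(theta)),
            class = "fish_state")
}

#' @export
print.fish_state <- function(x, ...) {
  cat(sprintf("<fish_state> x = %g, y = %g, theta = %g rad\n",
              x$x, x$y, x$theta))
  invisible(x)
}

# shared validation of a pose against a channel
check_inside_channel <- function(fish, params, what = "fish") {
  if (fish$y <= 0 || fish$y >= params$h) {
    stop(sprintf("%s cross-stream position y = %g lies on or outside the channel walls (0, %g); the model is singular at the walls",
                 what, fish$y, params$h), call. = FALSE)
  }
  invisible(TRUE)
}

#' Dimensional model parameters
#'
#' Physical constants of the channel-dipole model, with the derived
#' nondimensional groups attached:
#' `rho = r0/h` (dipole-to-channel size ratio), `alpha = U0*eps/v0`
#' (shear-to-swimming speed ratio), `kappa = K*r0*l` (lateral-line feedback
#' gain) and `beta = alpha*(1+kappa)/rho^2` (bifurcation parameter).
#'
#' The far-field construction of the dipole assumes `rho << 1`; values of
#' `rho` at or above 0.5 are rejected, and values above 0.2 trigger a
#' warning.
#'
#' @param h channel width (length).
#' @param U0 centerline background speed (velocity).
#' @param eps dimensionless shear parameter of the background profile
#'   (`>= 0`; the profile speed is `U0` at the centerline and `U0*(1-eps)`
#'   at the walls).
#' @param v0 self-propulsion speed of the swimmer (velocity, `> 0`).
#' @param r0 dipole length scale, of the order of the tail-beat amplitude
#'   (length, `> 0`).
#' @param l body length (length, `> 0`).
#' @param K lateral-line feedback gain (`>= 0`), with units such that
#'   `K*r0*l` is dimensionless.
#' @return an object of class `model_params`: a list with the seven inputs
#'   plus `rho`, `alpha`, `kappa`, `beta`.
#' @seealso [nondim_params()], [nondimensionalize()]
#' @examples
#' p <- model_params(h = 1, U0 = 0.5, eps = 0.1, v0 = 1, r0 = 0.05, l = 0.25, K = 0)
#' p$beta
#' @export
model_params <- function(h, U0 = 0, eps = 0, v0, r0, l = 5 * r0, K = 0) {
  stopifnot(is.numeric(h), is.numeric(U0), is.numeric(eps), is.numeric(v0),
            is.numeric(r0), is.numeric(l), is.numeric(K))
  if (h <= 0) stop("channel width h must be positive", call. = FALSE)
  if (v0 <= 0) stop("swimming speed v0 must be positive", call. = FALSE)
  if (r0 <= 0) stop("dipole length r0 must be positive", call. = FALSE)
  if (l <= 0) stop("body length l must be positive", call. = FALSE)
  if (eps < 0) stop("shear parameter eps must be non-negative", call. = FALSE)
  if (K < 0) stop("feedback gain K must be non-negative", call. = FALSE)
  if (U0 < 0) stop("background speed U0 must be non-negative", call. = FALSE)
  rho <- r0 / h
  if (rho >= 0.5) {
    stop(sprintf("rho = r0/h = %g violates the far-field assumption rho << 1 (limit 0.5)",
                 rho), call. = FALSE)
  }
  if (rho > 0.2) {
    warning(sprintf("rho = r0/h = %g is large for the far-field dipole model (recommended rho <= 0.2)",
                    rho), call. = FALSE)
  }
  alpha <- U0 * eps / v0
  kappa <- K * r0 * l
  structure(list(h = h, U0 = U0, eps = eps, v0 = v0, r0 = r0, l = l, K = K,
                 rho = rho, alpha = alpha, kappa = kappa,
                 beta = alpha * (1 + kappa) / rho^2),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  h = %g, U0 = %g, eps = %g, v0 = %g, r0 = %g, l = %g, K = %g\n",
              x$h, x$U0, x$eps, x$v0, x$r0, x$l, x$K))
  cat(sprintf("  rho = %g, alpha = %g, kappa = %g, beta = %g\n",
              x$rho, x$alpha, x$kappa, x$beta))
  invisible(x)
}

#' Nondimensional parameters of the planar system
#'
#' The reduced cross-stream/heading dynamics depends on the triple
#' `(rho, alpha, kappa)` only; the bifurcation parameter
#' `beta = alpha*(1+kappa)/rho^2` is derived. Upstream swimming at the
#' centerline is stable iff `beta > beta_star() = pi^4/32`.
#'
#' @param rho dipole-to-channel size ratio `r0/h` (`> 0`).
#' @param alpha shear-to-swimming ratio `U0*eps/v0` (`>= 0`).
#' @param kappa lateral-line feedback gain `K*r0*l` (`>= 0`).
#' @return an object of class `nondim_params` with fields `rho`, `alpha`,
#'   `kappa`, `beta`.
#' @examples
#' nondim_params(rho = 0.1, alpha = 0.1, kappa = 1)$beta # 20
#' @export
nondim_params <- function(rho, alpha, kappa = 0) {
  stopifnot(is.numeric(rho), is.numeric(alpha), is.numeric(kappa),
            length(rho) == 1L, length(alpha) == 1L, length(kappa) == 1L)
  if (rho == 0) {
    stop("rho = 0 is not admissible: as rho -> 0 the walls recede and beta -> Inf (upstream swimming is then always stable); use a small positive rho instead",
         call. = FALSE)
  }
  if (rho < 0) stop("rho must be positive", call. = FALSE)
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  structure(list(rho = rho, alpha = alpha, kappa = kappa,
                 beta = alpha * (1 + kappa) / rho^2),
            class = "nondim_params")
}

#' @export
print.nondim_params <- function(x, ...) {
  cat(sprintf("<nondim_params> rho = %g, alpha = %g, kappa = %g, beta = %g (beta* = %.6g)\n",
              x$rho, x$alpha, x$kappa, x$beta, beta_star()))
  invisible(x)
}

#' Extract the nondimensional triple from dimensional parameters
#'
#' @param params a [model_params()] object.
#' @return the corresponding [nondim_params()] object.
#' @export
as_nondim <- function(params) {
  stopifnot(inherits(params, "model_params"))
  nondim_params(rho = params$rho, alpha = params$alpha, kappa = params$kappa)
}

# accept either params class where only (rho, alpha, kappa) are needed
as_nondim_any <- function(params) {
  if (inherits(params, "nondim_params")) params
  else if (inherits(params, "model_params")) as_nondim(params)
  else stop("expected model_params or nondim_params", call. = FALSE)
}

#' Image-series truncation policy
#'
#' Controls the evaluation of the wall-image series. The series is summed
#' over `max_sets` sets of four images each; with `tail_correction = TRUE`
#' (the default) the remaining tail is added in closed form via
#' Euler-Maclaurin summation of the four image lattices, after which the
#' truncation error estimate is checked against `tol * v0` (absolute
#' velocity). Raw summation (`tail_correction = FALSE`) converges only like
#' 1/N and is provided for diagnostics.
#'
#' @param max_sets number of image sets (n = 0, ..., max_sets - 1); `>= 1`.
#' @param tol absolute tail tolerance in units of `v0`.
#' @param tail_correction logical; add the analytic Euler-Maclaurin tail.
#' @param check logical; if `TRUE`, signal an error when the truncation error
#'   estimate exceeds `tol * v0`.
#' @return an object of class `truncation_policy`.
#' @export
truncation_policy <- function(max_sets = 200L, tol = 1e-10,
                              tail_correction = TRUE, check = TRUE) {
  stopifnot(is.numeric(max_sets), max_sets >= 1, is.numeric(tol), tol >= 0)
  structure(list(max_sets = as.integer(max_sets), tol = tol,
                 tail_correction = isTRUE(tail_correction),
                 check = isTRUE(check)),
            class = "truncation_policy")
}
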