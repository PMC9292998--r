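# Shared fixtures and independent numerical oracles.

std_params <- function(h = 1, U0 = 0.5, eps = 0.2, v0 = 1, r0 = 0.05,
                       l = 0.25, K = 2) {
  model_params(h = h, U0 = U0, eps = eps, v0 = v0, r0 = r0, l = l, K = K)
}

# central finite-difference gradient of a scalar field f(c(x, y))
fd_grad <- function(f, at, step) {
  c((f(at + c(step, 0)) - f(at - c(step, 0))) / (2 * step),
    (f(at + c(0, step)) - f(at - c(0, step))) / (2 * step))
}

# divergence and curl of a vector field u(c(x, y)) -> c(ux, uy)
fd_div <- function(u, at, step) {
  unname((u(at + c(step, 0))[1L] - u(at - c(step, 0))[1L]) / (2 * step) +
           (u(at + c(0, step))[2L] - u(at - c(0, step))[2L]) / (2 * step))
}
fd_curl <- function(u, at, step) {
  unname((u(at + c(step, 0))[2L] - u(at - c(step, 0))[2L]) / (2 * step) -
           (u(at + c(0, step))[1L] - u(at - c(0, step))[1L]) / (2 * step))
}

# finite-difference Jacobian of the planar rhs
fd_jacobian <- function(params, xi, theta, step = 1e-6) {
  f <- function(s) unname(planar_rhs(s, params))
  unname(cbind((f(c(xi + step, theta)) - f(c(xi - step, theta))) / (2 * step),
               (f(c(xi, theta + step)) - f(c(xi, theta - step))) / (2 * step)))
}

# midpoint-rule quadrature of the vorticity over a rotated rectangle
# (independent oracle for circulation_rectangle)
quad_circulation <- function(center, heading, width, len, params, n = 41L) {
  us <- (seq_len(n) - 0.5) / n - 0.5  # midpoints in [-1/2, 1/2]
  g <- expand.grid(a = us * len, b = us * width)
  x <- center[1L] + g$a * cos(heading) - g$b * sin(heading)
  y <- center[2L] + g$a * sin(heading) + g$b * cos(heading)
  mean(vorticity(cbind(x, y), params)) * width * len
}

# random interior poses under a fixed seed
random_poses <- function(n, params, seed = 42L, margin = 0.05) {
  withr::with_seed(seed, {
    data.frame(x = stats::runif(n, -params$h, params$h),
               y = stats::runif(n, margin * params$h, (1 - margin) * params$h),
               theta = stats::runif(n, -pi, pi))
  })
}
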