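# Adaptive explicit Dormand-Prince 5(4) integrator with event localization.
# No ODE-solver package is assumed; the systems integrated here are small and
# smooth, so an embedded RK pair with PI step control is adequate.

DP_A <- rbind(
  c(0, 0, 0, 0, 0, 0),
  c(1/5, 0, 0, 0, 0, 0),
  c(3/40, 9/40, 0, 0, 0, 0),
  c(44/45, -56/15, 32/9, 0, 0, 0),
  c(19372/6561, -25360/2187, 64448/6561, -212/729, 0, 0),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656, 0)
)
DP_C <- c(0, 1/5, 3/10, 4/5, 8/9, 1)
DP_B5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)      # 5th order
DP_B4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200,
           187/2100, 1/40)                                        # 4th order

#' Solver policy for trajectory integration
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance.
#' @param max_steps cap on accepted steps.
#' @param h_init initial step size (`NA` = automatic).
#' @return an object of class `solver_policy`.
#' @export
solver_policy <- function(rtol = 1e-8, atol = 1e-10, max_steps = 200000L,
                          h_init = NA_real_) {
  stopifnot(rtol > 0, atol > 0, max_steps >= 10)
  structure(list(rtol = rtol, atol = atol, max_steps = as.integer(max_steps),
                 h_init = h_init),
            class = "solver_policy")
}

# single Dormand-Prince step from (t, y) with step size h;
# returns y5 (solution), err (scaled error norm uses caller's tolerances), k1..k7
dp_step <- function(f, t, y, h, k1 = NULL) {
  k <- matrix(0, 7L, length(y))
  k[1L, ] <- if (is.null(k1)) f(t, y) else k1
  for (i in 2:6) {
    k[i, ] <- f(t + DP_C[i] * h, y + h * colSums(DP_A[i, 1:(i - 1)] * k[1:(i - 1), , drop = FALSE]))
  }
  y5 <- y + h * colSums(DP_B5 * k[1:6, , drop = FALSE])
  k[7L, ] <- f(t + h, y5)  # FSAL
  y4 <- y + h * colSums(DP_B4 * k)
  list(y5 = y5, y4 = y4, k7 = k[7L, ])
}

# Integrate dy/dt = f(t, y) from t0 to t1. Optional scalar event g(t, y):
# integration stops when g changes sign; the crossing is localized by
# bisection on the step size. Returns times/states at accepted steps.
ode_rk45 <- function(f, y0, t0, t1, policy = solver_policy(), event = NULL) {
  stopifnot(t1 > t0)
  rtol <- policy$rtol; atol <- policy$atol
  n <- length(y0)
  cap <- policy$max_steps
  ts <- numeric(cap + 1L); ys <- matrix(0, cap + 1L, n)
  ts[1L] <- t0; ys[1L, ] <- y0
  t <- t0; y <- y0; m <- 1L
  k1 <- f(t, y)
  h <- if (is.finite(policy$h_init)) policy$h_init else {
    sc <- atol + rtol * abs(y0)
    d0 <- sqrt(mean((y0 / sc)^2)); d1 <- sqrt(mean((k1 / sc)^2))
    h0 <- min(if (d1 > 1e-10) 0.01 * d0 / d1 else 1e-6, (t1 - t0) / 50)
    if (!is.finite(h0) || h0 <= 0) h0 <- (t1 - t0) * 1e-6
    h0
  }
  g_prev <- if (!is.null(event)) event(t, y) else NA_real_
  terminated <- NULL
  while (t < t1) {
    h <- min(h, t1 - t)
    st <- dp_step(f, t, y, h, k1)
    sc <- atol + rtol * pmax(abs(y), abs(st$y5))
    err <- sqrt(mean(((st$y5 - st$y4) / sc)^2))
    if (is.finite(err) && err <= 1) {
      t_new <- t + h; y_new <- st$y5
      if (!is.null(event)) {
        g_new <- event(t_new, y_new)
        if (is.finite(g_prev) && is.finite(g_new) &&
            sign(g_new) != sign(g_prev) && g_prev != 0) {
          # localize crossing: bisection on sub-step size from (t, y)
          lo <- 0; hi <- h
          for (it in 1:60) {
            mid <- (lo + hi) / 2
            ymid <- dp_step(f, t, y, mid, k1)$y5
            if (sign(event(t + mid, ymid)) == sign(g_prev)) lo <- mid else hi <- mid
            if (hi - lo < 1e-12 * max(1, abs(t))) break
          }
          t_new <- t + hi
          y_new <- dp_step(f, t, y, hi, k1)$y5
          terminated <- list(time = t_new, state = y_new)
        }
        g_prev <- if (is.null(terminated)) g_new else g_prev
      }
      t <- t_new; y <- y_new; k1 <- st$k7
      m <- m + 1L
      if (m > cap) stop("ode_rk45: max_steps exceeded at t = ", t, call. = FALSE)
      ts[m] <- t; ys[m, ] <- y
      if (!is.null(terminated)) break
      h <- h * min(5, max(0.2, 0.9 * err^-0.2))
    } else {
      h <- h * max(0.1, 0.9 * if (is.finite(err)) err^-0.2 else 0.1)
      if (h < 1e-14 * max(1, abs(t))) {
        stop(sprintf("ode_rk45: step size underflow at t = %g (last state: %s)",
                     t, paste(signif(y, 6), collapse = ", ")), call. = FALSE)
      }
    }
  }
  list(t = ts[1:m], y = ys[1:m, , drop = FALSE], event = terminated)
}
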