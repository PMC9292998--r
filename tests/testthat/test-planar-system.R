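test_that("planar right-hand side matches the reduced equations", {
  p <- nondim_params(0.1, 0.1, 1)
  # upstream centerline is an equilibrium
  expect_equal(unname(planar_rhs(c(0, pi), p)), c(0, 0), tolerance = 1e-15)
  # cross-channel heading at the centerline: dxi = 1 - pi^2 rho^2 / 6
  r <- planar_rhs(c(0, pi / 2), p)
  expect_equal(unname(r[1L]), 1 - pi^2 * 0.01 / 6)
  expect_equal(unname(r[2L]), 0)
  # reflection symmetry: both components flip under (xi, theta) -> (-xi, -theta)
  states <- withr::with_seed(21, cbind(stats::runif(25, -0.45, 0.45),
                                       stats::runif(25, -pi, pi)))
  for (i in seq_len(nrow(states))) {
    r1 <- planar_rhs(states[i, ], p)
    r2 <- planar_rhs(-states[i, ], p)
    expect_equal(unname(r2), -unname(r1), tolerance = 1e-13)
  }
  expect_error(planar_rhs(c(0.5, 0), p), "xi")
})

test_that("beta and beta* are computed in closed form", {
  expect_equal(nondim_params(rho = 0.1, alpha = 0.1, kappa = 1)$beta, 20)
  expect_equal(beta_star(), pi^4 / 32)
  expect_equal(round(beta_star(), 4), 3.0440)
  expect_equal(nondim_params(rho = 0.3, alpha = 0.09, kappa = 0)$beta, 1)
  expect_error(nondim_params(rho = 0, alpha = 0.1), "beta -> Inf")
})

test_that("equilibrium structure changes at beta*", {
  cls <- function(eqs) vapply(eqs, `[[`, character(1), "classification")
  ths <- function(eqs) vapply(eqs, `[[`, numeric(1), "theta")
  xis <- function(eqs) vapply(eqs, `[[`, numeric(1), "xi")

  e20 <- find_equilibria(nondim_params(0.1, 0.1, 1))   # beta = 20
  up <- abs(ths(e20) - pi) < 1e-12
  expect_equal(sum(up), 3L)
  expect_identical(cls(e20)[!up], "saddle")            # downstream
  expect_identical(cls(e20)[up & xis(e20) == 0], "neutral_center")
  expect_identical(unname(cls(e20)[up & xis(e20) != 0]), rep("saddle", 2L))
  expect_equal(sort(xis(e20)[up & xis(e20) != 0]),
               c(-1, 1) * 0.3328744694, tolerance = 1e-8)

  e2 <- find_equilibria(nondim_params(0.1, 0.01, 1))   # beta = 2 < beta*
  expect_length(e2, 2L)
  expect_identical(unname(cls(e2)), c("saddle", "saddle"))

  # roots approach the walls as beta grows: 1/2 - xi* ~ (16 beta)^(-1/3)
  e4 <- find_equilibria(nondim_params(0.1, 100, 0))    # beta = 1e4
  s <- 0.5 - max(xis(e4))
  expect_equal(max(xis(e4)), 0.4813448919, tolerance = 1e-8)
  expect_equal(s / (16 * 1e4)^(-1 / 3), 1, tolerance = 0.05)
})

test_that("equilibrium count is 1 below and 3 above beta* across decades", {
  p0 <- nondim_params(0.05, 1, 0)
  for (b in 10^seq(-1, 3, length.out = 17)) {
    p <- nondim_params(0.05, b * 0.05^2, 0)
    eqs <- find_equilibria(p)
    n_up <- sum(vapply(eqs, function(e) abs(e$theta - pi) < 1e-12, NA))
    expect_identical(n_up, if (b > beta_star()) 3L else 1L)
    # zero trace at machine precision, everywhere
    for (e in eqs) expect_lt(abs(e$trace), 1e-12)
    # residuals of the transcendental equation at the reported roots
    for (e in eqs) {
      expect_lt(max(abs(planar_rhs(c(e$xi, e$theta), p))), 1e-10)
    }
  }
})

test_that("linearization reproduces the printed state matrices", {
  p <- nondim_params(0.1, 0.1, 1)
  rho2 <- p$rho^2
  A_down <- linearize(0, 0, p)
  expect_equal(A_down, matrix(c(0, 8 * (1 + p$kappa) * p$alpha + pi^4 * rho2 / 4,
                                1 - pi^2 * rho2 / 6, 0), 2, 2))
  A_up <- linearize(pi, 0, p)
  expect_equal(A_up, matrix(c(0, 8 * (1 + p$kappa) * p$alpha - pi^4 * rho2 / 4,
                              -1 + pi^2 * rho2 / 6, 0), 2, 2))
  # off-center matrix, against the printed sec/cos form
  xi_s <- Filter(function(e) e$xi > 0, find_equilibria(p))[[1L]]$xi
  A_off <- linearize(pi, xi_s, p)
  expect_equal(A_off[1, 2],
               -1 - pi^2 * rho2 / 12 + pi^2 * rho2 / 4 / cos(pi * xi_s)^2)
  expect_equal(A_off[2, 1],
               8 * (1 + p$kappa) * p$alpha -
                 pi^4 * rho2 / 4 * (2 - cos(2 * pi * xi_s)) / cos(pi * xi_s)^4)
  # finite-difference Jacobian oracle at all three equilibria
  for (eq in list(c(0, 0), c(pi, 0), c(pi, xi_s), c(pi, -xi_s))) {
    A <- linearize(eq[1L], eq[2L], p)
    expect_equal(A, fd_jacobian(p, eq[2L], eq[1L]), tolerance = 1e-6)
  }
  # contract violations
  expect_error(linearize(pi, 0.3, p), "not an equilibrium")
  expect_error(linearize(1.2, 0, p), "heading 0 or pi")
})

test_that("classification follows the determinant of a zero-trace matrix", {
  expect_identical(classify(matrix(c(0, 1, 1, 0), 2, 2)), "saddle")
  expect_identical(classify(matrix(c(0, 1, -1, 0), 2, 2)), "neutral_center")
  expect_identical(classify(matrix(c(0, 1e-12, 1e-12, 0), 2, 2)), "degenerate")
  expect_error(classify(matrix(c(1, 0, 0, 1), 2, 2)), "zero-trace")
  # off-center upstream equilibria are saddles for every beta > beta*
  for (b in c(3.1, 5, 20, 100, 1000)) {
    p <- nondim_params(0.05, b * 0.05^2, 0)
    off <- Filter(function(e) e$xi != 0, find_equilibria(p))
    expect_length(off, 2L)
    for (e in off) expect_identical(e$classification, "saddle")
  }
})

test_that("determinant at the upstream centerline changes sign at beta*", {
  rho <- 0.1
  det_up <- function(b) {
    A <- linearize(pi, 0, nondim_params(rho, b * rho^2, 0), check = FALSE)
    -A[1, 2] * A[2, 1]
  }
  lo <- 1; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (det_up(mid) < 0) lo <- mid else hi <- mid
  }
  expect_lt(abs((lo + hi) / 2 - beta_star()), 1e-10)
})

test_that("sweeping frequency follows the square-root law", {
  rho <- 0.1
  at_beta <- function(b, kappa = 0) nondim_params(rho, b * rho^2 / (1 + kappa),
                                                  kappa)
  expect_error(sweeping_frequency(at_beta(2)), "beta")
  expect_equal(sweeping_frequency(at_beta(beta_star())), 0, tolerance = 1e-12)
  # closed-form small-rho approximation at beta = 2 beta*
  expect_equal(sweeping_frequency(at_beta(2 * beta_star()), "small_rho"),
               pi^2 / 20)
  # monotone increasing in beta
  ws <- vapply(seq(3.1, 60, length.out = 12),
               function(b) sweeping_frequency(at_beta(b)), 1)
  expect_true(all(diff(ws) > 0))
  # kappa only enters through beta: same beta, same frequency
  expect_equal(sweeping_frequency(at_beta(10, kappa = 0)),
               sweeping_frequency(at_beta(10, kappa = 3)), tolerance = 1e-14)
})

test_that("small-amplitude orbits close with period 2 pi / sqrt(det A)", {
  p <- nondim_params(0.1, 2 * beta_star() * 0.01, 0)  # beta = 2 beta*
  w_exact <- sweeping_frequency(p)
  period <- orbit_period(p, amplitude = 1e-3, cycles = 10L)
  expect_equal(period, 2 * pi / w_exact, tolerance = 1e-4)
  # bounded (no spiraling) over 50 periods
  tr <- simulate_planar(c(1e-3, pi), p, 50 * 2 * pi / w_exact)
  expect_identical(attr(tr, "termination"), "horizon")
  expect_lt(max(abs(tr$xi)), 1e-3 * 1.01)
  expect_gt(max(abs(tr$xi)), 1e-3 * 0.99)
})

test_that("bifurcation sweep reproduces the pitchfork diagram", {
  p <- nondim_params(0.05, 1, 0)
  grid <- exp(seq(log(0.5), log(50), length.out = 25))
  tab <- bifurcation_sweep(p, grid)
  counts <- table(tab$beta)
  expect_true(all(counts[as.numeric(names(counts)) < beta_star()] == 1))
  expect_true(all(counts[as.numeric(names(counts)) > beta_star()] == 3))
  # the outer branch moves monotonically toward the wall
  outer <- tab[tab$xi > 0, ]
  expect_true(all(diff(outer$xi[order(outer$beta)]) > 0))
  # feedback broadens the stable region: threshold alpha falls with kappa
  alpha_crit <- function(kappa) beta_star() * 0.05^2 / (1 + kappa)
  a_mid <- sqrt(alpha_crit(0) * alpha_crit(1))
  eq_k0 <- find_equilibria(nondim_params(0.05, a_mid, 0))
  eq_k1 <- find_equilibria(nondim_params(0.05, a_mid, 1))
  up0 <- Filter(function(e) abs(e$theta - pi) < 1e-12 && e$xi == 0, eq_k0)[[1]]
  up1 <- Filter(function(e) abs(e$theta - pi) < 1e-12 && e$xi == 0, eq_k1)[[1]]
  expect_identical(up0$classification, "saddle")
  expect_identical(up1$classification, "neutral_center")
})

test_that("phase portrait grid respects the reflection symmetry", {
  p <- nondim_params(0.1, 0.1, 1)
  tab <- phase_portrait(p, nxi = 11L, ntheta = 11L)
  eqs <- attr(tab, "equilibria")
  expect_s3_class(eqs, "equilibria")
  key <- function(xi, th) paste(round(xi, 10), round(th, 10))
  idx <- match(key(-tab$xi, -tab$theta), key(tab$xi, tab$theta))
  expect_false(anyNA(idx))
  expect_lt(max(abs(tab$dxi[idx] + tab$dxi)), 1e-12)
  expect_lt(max(abs(tab$dtheta[idx] + tab$dtheta)), 1e-12)
})

test_that("transcendental curves have the printed slope structure", {
  tab <- transcendental_curves(seq(-0.49, 0.49, length.out = 393))
  expect_named(tab, c("xi", "curve", "line_200", "line_m200", "line_m2"))
  # odd curve
  expect_equal(rev(tab$curve), -tab$curve, tolerance = 1e-10)
  # slope at the origin equals -beta* (finite differences on a fine grid)
  d <- 1e-6
  slope0 <- (transcendental_curves(c(-d, d))$curve |> diff()) / (2 * d)
  expect_equal(slope0, -beta_star(), tolerance = 1e-9)
  # the slope -2 line meets the curve only at the origin:
  # curve + 2 xi has the sign of -xi everywhere off the origin
  g <- tab$curve + 2 * tab$xi
  expect_true(all(g[tab$xi > 1e-9] < 0))
  expect_true(all(g[tab$xi < -1e-9] > 0))
})
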