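# Optional base-graphics figures; never required by tests.

#' Plot the planar-system vector field with its equilibria
#'
#' Arrows of the planar right-hand side on a grid, with equilibria marked
#' red (unstable saddles) or green (stable neutral centers).
#'
#' @param params a [nondim_params()] (or [model_params()]).
#' @param file optional PDF path; if `NULL`, draws on the active device.
#' @param nxi,ntheta grid resolution.
#' @return invisibly, the portrait data.frame.
#' @export
plot_phase_portrait <- function(params, file = NULL, nxi = 21L, ntheta = 21L) {
  tab <- phase_portrait(params, nxi = nxi, ntheta = ntheta)
  eqs <- attr(tab, "equilibria")
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  sc <- 0.35 * min(diff(range(tab$xi)) / nxi, diff(range(tab$theta)) / ntheta)
  m <- sqrt(tab$dxi^2 + tab$dtheta^2)
  m[m == 0] <- 1
  plot(NA, xlim = range(tab$theta), ylim = range(tab$xi),
       xlab = expression(theta[f]), ylab = expression(xi),
       main = "Planar system vector field")
  graphics::arrows(tab$theta, tab$xi,
                   tab$theta + sc * tab$dtheta / m, tab$xi + sc * tab$dxi / m,
                   length = 0.03, col = "grey40")
  for (e in eqs) {
    graphics::points(e$theta, e$xi, pch = 19, cex = 1.4,
                     col = if (e$classification == "neutral_center")
                       "forestgreen" else "red")
  }
  invisible(tab)
}

#' Plot an exported flow field as a vector/speed map
#'
#' @param tab a data.frame from [field_table()].
#' @param fish the [fish_state()] used to generate it (marked on the plot).
#' @param file optional PDF path.
#' @return invisibly, `tab`.
#' @export
plot_field <- function(tab, fish = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 4)
    on.exit(grDevices::dev.off())
  }
  ok <- is.finite(tab$ux)
  sp <- sqrt(tab$ux^2 + tab$uy^2)
  plot(tab$x[ok], tab$y[ok], pch = 15, cex = 0.8,
       col = grDevices::hcl.colors(64, "Blue-Red")[
         cut(sp[ok], 64, labels = FALSE)],
       xlab = "x", ylab = "y", main = "Channel flow field (speed)")
  sc <- 0.4 * min(diff(sort(unique(tab$x))[1:2]), diff(sort(unique(tab$y))[1:2]))
  graphics::arrows(tab$x[ok], tab$y[ok],
                   tab$x[ok] + sc * tab$ux[ok] / pmax(sp[ok], 1e-12),
                   tab$y[ok] + sc * tab$uy[ok] / pmax(sp[ok], 1e-12),
                   length = 0.02, col = "grey30")
  if (!is.null(fish)) graphics::points(fish$x, fish$y, pch = 17, cex = 1.5)
  invisible(tab)
}
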