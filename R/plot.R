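#' Plot the temporal dynamics of a trajectory
#'
#' Cooperator frequency (solid blue) and risk level (dashed red) against time.
#'
#' @param x a `"crsd_trajectory"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.crsd_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = c(1, 2),
                    col = c("blue", "red"), xlab = "time",
                    ylab = "fraction / level", ylim = c(0, 1), ...)
  graphics::legend("topright", c("cooperation x", "risk r"),
                   lty = c(1, 2), col = c("blue", "red"), bty = "n")
  invisible(x)
}

#' Phase portrait of a coupled system
#'
#' Draws the vector-field direction on a coarse grid over the unit square,
#' marks the catalogued fixed points (filled = stable, open = unstable or
#' degenerate), and optionally overlays integrated trajectories.
#'
#' @param x a [crsd_system()].
#' @param inits optional matrix/data frame of initial conditions (columns
#'   `x0`, `r0`) from which trajectories are integrated and drawn.
#' @param t_max horizon for the overlaid trajectories.
#' @param arrow_grid arrow grid resolution per axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot.crsd_system <- function(x, inits = NULL, t_max = 500, arrow_grid = 15, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "cooperation x", ylab = "risk r", ...)
  g <- seq(0.03, 0.97, length.out = arrow_grid)
  for (xi in g) for (ri in g) {
    v <- rhs_raw(xi, ri, x)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) {
      v <- v / nv * 0.02
      graphics::arrows(xi, ri, xi + v[1], ri + v[2], length = 0.03,
                       col = "grey60")
    }
  }
  if (!is.null(inits)) {
    inits <- as.matrix(inits)
    for (i in seq_len(nrow(inits))) {
      tr <- integrate_system(x, inits[i, 1], inits[i, 2], t_max = t_max,
                             rtol = 1e-8, atol = 1e-8, n_out = 4001L)
      graphics::lines(tr$states[, 1], tr$states[, 2], col = "steelblue")
    }
  }
  if (x$feedback$variant != "custom") {
    fp <- enumerate_fixed_points(x)
    stable <- fp$stability == "stable"
    graphics::points(fp$x[stable], fp$r[stable], pch = 19, cex = 1.3)
    graphics::points(fp$x[!stable], fp$r[!stable], pch = 1, cex = 1.3)
  }
  invisible(x)
}

#' Plot a basin-of-attraction map
#'
#' Colours the grid of initial conditions by attractor label.
#'
#' @param x a `"crsd_basin"` from [basin_map()].
#' @param ... passed to [graphics::image()].
#' @export
plot.crsd_basin <- function(x, ...) {
  xs <- sort(unique(x$x0)); rs <- sort(unique(x$r0))
  labs <- sort(unique(x$label))
  z <- matrix(match(x$label, labs), nrow = length(xs))
  cols <- grDevices::hcl.colors(max(length(labs), 2), "Set 2")
  graphics::image(xs, rs, z, col = cols[seq_along(labs)],
                  xlab = "x0", ylab = "r0", ...)
  graphics::legend("topright", legend = labs, fill = cols[seq_along(labs)],
                   bg = "white", cex = 0.8)
  invisible(x)
}
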