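#' Detect the long-run attractor of a trajectory
#'
#' Inspects the tail of an integrated trajectory and reports where it ended
#' up. A **fixed point** is declared when the terminal drift
#' `||(dx/dt, dr/dt)||` is below `drift_tol`; if a catalogue of fixed points
#' is available the terminal state must additionally sit within `match_tol`
#' of one of them, and that catalogued point is reported. A **limit cycle**
#' is declared from the last quarter of the run when the `x` oscillation
#' amplitude exceeds `amp_floor`, at least `min_peaks` local maxima are found
#' (separated by a refractory window of 1% of the analysis span), and the
#' coefficient of variation of successive peak heights is below `cv_tol`; the
#' period is the mean inter-peak interval. Anything else is **undetermined**,
#' with a diagnostic.
#'
#' @param traj a `"crsd_trajectory"`.
#' @param known_points optional `"crsd_equilibria"` catalogue; defaults to
#'   [enumerate_fixed_points()] of the trajectory's system when the feedback
#'   law is analytic.
#' @param drift_tol terminal drift bound for fixed-point calls.
#' @param match_tol distance bound to a catalogued point.
#' @param amp_floor minimum sustained `x` amplitude for a cycle.
#' @param cv_tol maximum coefficient of variation of peak heights.
#' @param min_peaks minimum number of peaks to declare a cycle.
#' @return list of class `"crsd_attractor"`: `kind` (`fixed_point`,
#'   `limit_cycle`, `undetermined`), `location`, `period`, `x_amplitude`,
#'   `r_amplitude`, `matched` (row index into the catalogue or `NA`),
#'   `diagnostic`.
#' @export
detect_attractor <- function(traj, known_points = NULL,
                             drift_tol = 1e-8, match_tol = 1e-4,
                             amp_floor = 1e-3, cv_tol = 0.05, min_peaks = 5) {
  if (!inherits(traj, "crsd_trajectory")) stop("traj must be a crsd_trajectory")
  if (is.null(known_points) && traj$system$feedback$variant != "custom")
    known_points <- enumerate_fixed_points(traj$system)
  n <- length(traj$times)
  terminal <- traj$states[n, ]
  drift <- sqrt(sum(rhs_raw(terminal[1], terminal[2], traj$system)^2))
  res <- list(kind = "undetermined", location = c(x = NA_real_, r = NA_real_),
              period = NA_real_, x_amplitude = NA_real_, r_amplitude = NA_real_,
              matched = NA_integer_, diagnostic = "")
  class(res) <- "crsd_attractor"
  if (drift < drift_tol) {
    if (!is.null(known_points)) {
      d <- sqrt((known_points$x - terminal[1])^2 + (known_points$r - terminal[2])^2)
      i <- which.min(d)
      if (d[i] < match_tol) {
        res$kind <- "fixed_point"
        res$location <- c(x = known_points$x[i], r = known_points$r[i])
        res$matched <- i
        return(res)
      }
      res$diagnostic <- sprintf(
        "terminal drift %.3g below tolerance but state (%.6g, %.6g) matches no catalogued point",
        drift, terminal[1], terminal[2])
      return(res)
    }
    res$kind <- "fixed_point"
    res$location <- c(x = terminal[1], r = terminal[2])
    return(res)
  }
  # cycle analysis on the last quarter of the run
  w <- traj$times >= traj$times[n] * 0.75
  span <- traj$times[n] - traj$times[n] * 0.75
  if (span < 100) {
    res$diagnostic <- sprintf(
      "analysis window of %.3g time units is too short (need >= 100)", span)
    return(res)
  }
  tx <- traj$times[w]; xx <- traj$states[w, 1]; rr <- traj$states[w, 2]
  amp <- diff(range(xx))
  peaks <- find_peaks(tx, xx, refractory = 0.01 * span)
  if (amp > amp_floor && length(peaks) >= min_peaks) {
    heights <- xx[peaks]
    cv <- stats::sd(heights) / mean(heights)
    if (is.finite(cv) && cv < cv_tol) {
      res$kind <- "limit_cycle"
      res$period <- mean(diff(tx[peaks]))
      res$x_amplitude <- amp
      res$r_amplitude <- diff(range(rr))
      return(res)
    }
    res$diagnostic <- sprintf(
      "oscillation found but peak heights vary too much (cv = %.3g)", cv)
    return(res)
  }
  res$diagnostic <- sprintf(
    "neither converged (terminal drift %.3g) nor oscillating (amplitude %.3g, %d peaks)",
    drift, amp, length(peaks))
  res
}

# indices of local maxima separated by at least `refractory` time units
find_peaks <- function(t, x, refractory) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    if (t[i] - last_t >= refractory) {
      keep <- c(keep, i)
      last_t <- t[i]
    }
  }
  keep
}

#' @export
print.crsd_attractor <- function(x, ...) {
  switch(x$kind,
    fixed_point = cat(sprintf("Attractor: fixed point at (x, r) = (%.6g, %.6g)\n",
                              x$location[1], x$location[2])),
    limit_cycle = cat(sprintf(
      "Attractor: limit cycle, period %.4g, x amplitude %.4g, r amplitude %.4g\n",
      x$period, x$x_amplitude, x$r_amplitude)),
    cat(sprintf("Attractor: undetermined (%s)\n", x$diagnostic)))
  invisible(x)
}

#' Map basins of attraction on a grid of initial conditions
#'
#' Integrates the system from every point of a uniform grid strictly inside
#' the open unit square (offsets `k/(R+1)`, `k = 1..R` — the boundaries are
#' invariant sets) and labels each start by its detected attractor. Fully
#' deterministic.
#'
#' @param system a [crsd_system()].
#' @param grid_resolution grid points per axis, at least 2.
#' @param t_max,rtol,atol integration settings; defaults are lighter than for
#'   single-trajectory work because only the attractor identity is needed.
#' @return data frame of class `"crsd_basin"` with columns `x0`, `r0`,
#'   `label` (`"fp(x,r)"` with the catalogued coordinates, `"limit_cycle"`,
#'   or `"undetermined"`).
#' @export
basin_map <- function(system, grid_resolution, t_max = 1000,
                      rtol = 1e-8, atol = 1e-8) {
  if (!inherits(system, "crsd_system")) stop("system must be a crsd_system object")
  if (grid_resolution < 2) stop("grid_resolution must be >= 2")
  known <- enumerate_fixed_points(system)
  offs <- seq_len(grid_resolution) / (grid_resolution + 1)
  grid <- expand.grid(x0 = offs, r0 = offs, KEEP.OUT.ATTRS = FALSE)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    tr <- integrate_system(system, grid$x0[i], grid$r0[i], t_max = t_max,
                           rtol = rtol, atol = atol, n_out = 2001L)
    att <- detect_attractor(tr, known)
    switch(att$kind,
      fixed_point = sprintf("fp(%.6g,%.6g)", att$location[1], att$location[2]),
      limit_cycle = "limit_cycle",
      "undetermined")
  }, character(1))
  class(grid) <- c("crsd_basin", "data.frame")
  attr(grid, "system") <- system
  grid
}
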