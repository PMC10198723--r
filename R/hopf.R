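#' Hopf bifurcation threshold
#'
#' The interior fixed point loses stability when the Jacobian trace — which at
#' an interior point reduces to `x(1-x) Gamma'(x) r* b / eps` — changes sign,
#' i.e. when the interior `x` coordinate crosses the mode of the selection
#' kernel at `(M-1)/(N-1)`. For the linear family the interior point sits at
#' `x = u/(1+u)`, giving the critical rate `u = (M-1)/(N-M)`; for the
#' exponential family it sits at `x = T`, giving `T = (M-1)/(N-1)`.
#'
#' @param params a [crsd_game()].
#' @param family `"linear"` or `"exponential"`.
#' @return the critical feedback parameter (`u` resp. `T`).
#' @seealso [hopf_threshold_numeric()] for the independent trace-zero search.
#' @export
hopf_threshold <- function(params, family = c("linear", "exponential")) {
  if (!inherits(params, "crsd_game")) stop("params must be a crsd_game object")
  family <- match.arg(family)
  if (family == "linear") (params$M - 1) / (params$N - params$M)
  else (params$M - 1) / (params$N - 1)
}

# Jacobian trace at the (formal) interior fixed point as a function of its x
# coordinate; r* b = c / Gamma(x) cancels b, and eps only scales the trace
interior_trace <- function(x, params, eps = 1) {
  x * (1 - x) * gamma_kernel_deriv(x, params) * params$c /
    (gamma_kernel(x, params) * eps)
}

#' Numerical Hopf threshold via trace-zero root finding
#'
#' Locates the bifurcation parameter at which the Jacobian trace at the
#' interior fixed point crosses zero, by bisection/Brent on the trace as the
#' feedback parameter varies. Independent of the closed-form expression in
#' [hopf_threshold()]; the two agree to about 1e-12.
#'
#' @param params a [crsd_game()].
#' @param family `"linear"` or `"exponential"`.
#' @param eps strategy-update speed (scales the trace, not its root).
#' @return the critical feedback parameter found numerically.
#' @export
hopf_threshold_numeric <- function(params, family = c("linear", "exponential"),
                                   eps = 0.1) {
  if (!inherits(params, "crsd_game")) stop("params must be a crsd_game object")
  family <- match.arg(family)
  if (family == "linear") {
    tr <- function(u) interior_trace(u / (1 + u), params, eps)
    stats::uniroot(tr, c(1e-4, 1e4), tol = 1e-14, maxiter = 2000)$root
  } else {
    tr <- function(T) interior_trace(T, params, eps)
    stats::uniroot(tr, c(1e-6, 1 - 1e-6), tol = 1e-14, maxiter = 2000)$root
  }
}

# tensor-product central finite-difference stencils, 4th-order accurate,
# for partial derivatives up to third order
fd_stencil <- function(order, h) {
  switch(as.character(order),
    "0" = list(off = 0, w = 1),
    "1" = list(off = c(-2, -1, 1, 2), w = c(1, -8, 8, -1) / (12 * h)),
    "2" = list(off = c(-2, -1, 0, 1, 2), w = c(-1, 16, -30, 16, -1) / (12 * h^2)),
    "3" = list(off = c(-3, -2, -1, 1, 2, 3),
               w = c(1, -8, 13, -13, 8, -1) / (8 * h^3)),
    stop("unsupported derivative order"))
}

fd_partial <- function(fun, ix, iy, h = 1e-2) {
  sx <- fd_stencil(ix, h); sy <- fd_stencil(iy, h)
  acc <- 0
  for (i in seq_along(sx$off))
    for (j in seq_along(sy$off))
      acc <- acc + sx$w[i] * sy$w[j] * fun(sx$off[i] * h, sy$off[j] * h)
  acc
}

#' First Lyapunov coefficient at a Hopf point
#'
#' Computes the first Lyapunov coefficient `l1` of the interior fixed point
#' when its eigenvalues are purely imaginary. The vector field is shifted to
#' the fixed point and linearly transformed so the Jacobian takes the normal
#' rotation form `[[0, -w], [w, 0]]`; the second- and third-order partial
#' derivatives of the transformed field are obtained by fourth-order central
#' finite differences and combined by the standard planar normal-form
#' formula. The formula is evaluated at steps `h` and `h/2` and Richardson-
#' extrapolated, which removes the leading truncation error; without this the
#' residual error can masquerade as a small nonzero coefficient.
#'
#' A negative sign means the bifurcation is supercritical (the emerging limit
#' cycle is stable), a positive sign subcritical. A value indistinguishable
#' from zero (roughly `|l1| < 1e-8` here) means the bifurcation is degenerate
#' at third order: the cubic normal form carries no information and the local
#' dynamics at threshold are center-like. The linear and sigmoid feedback
#' systems of this package land exactly in that degenerate case — see the
#' methods vignette — so only the magnitude's smallness, not its sign, is
#' meaningful for them. Only the sign (or its absence) is contractual; the
#' magnitude depends on the eigenbasis normalisation.
#'
#' @param system a [crsd_system()] parameterised exactly at its Hopf
#'   threshold (Jacobian trace at the interior point below `1e-8` in absolute
#'   value, otherwise an error is raised).
#' @param h base finite-difference step.
#' @return the extrapolated coefficient `l1` (numeric scalar), with attribute
#'   `"estimates"` carrying the raw values at `h` and `h/2`.
#' @export
first_lyapunov_coefficient <- function(system, h = 1e-2) {
  raw <- c(l1_fd(system, h), l1_fd(system, h / 2))
  structure((16 * raw[2] - raw[1]) / 15, estimates = raw)
}

l1_fd <- function(system, h) {
  if (!inherits(system, "crsd_system")) stop("system must be a crsd_system object")
  ip <- interior_point(system)
  if (is.null(ip)) stop("system has no interior fixed point")
  J <- system_jacobian(system, ip)
  tr <- J[1, 1] + J[2, 2]
  if (abs(tr) > 1e-8)
    stop("first_lyapunov_coefficient called off the Hopf threshold (|trace| = ",
         format(abs(tr)), ")")
  d <- det(J)
  if (d <= 0) stop("interior point is not of focus type (det <= 0)")
  omega <- sqrt(d)
  a12 <- J[1, 2]
  s <- -omega / a12   # (dx, dr) = (X, s Y) maps J to [[0, -w], [w, 0]]
  x0 <- ip[["x"]]; r0 <- ip[["r"]]
  fX <- function(dX, dY) rhs_raw(x0 + dX, r0 + s * dY, system)[1]
  gY <- function(dX, dY) rhs_raw(x0 + dX, r0 + s * dY, system)[2] / s
  f_xxx <- fd_partial(fX, 3, 0, h); f_xyy <- fd_partial(fX, 1, 2, h)
  g_xxy <- fd_partial(gY, 2, 1, h); g_yyy <- fd_partial(gY, 0, 3, h)
  f_xx <- fd_partial(fX, 2, 0, h); f_yy <- fd_partial(fX, 0, 2, h)
  f_xy <- fd_partial(fX, 1, 1, h)
  g_xx <- fd_partial(gY, 2, 0, h); g_yy <- fd_partial(gY, 0, 2, h)
  g_xy <- fd_partial(gY, 1, 1, h)
  (f_xxx + f_xyy + g_xxy + g_yyy) / 16 +
    (f_xy * (f_xx + f_yy) - g_xy * (g_xx + g_yy) - f_xx * g_xx + f_yy * g_yy) /
      (16 * omega)
}
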