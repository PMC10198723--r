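#' Roots of Gamma(x) b = c on the high-risk boundary
#'
#' The boundary line `r = 1` carries fixed points wherever the selection
#' kernel balances the cost, `Gamma(x) = c / b`. Since `Gamma` is unimodal
#' with mode at `(M-1)/(N-1)`, there are two roots `x1* < mode < x2*` when
#' `c/b` is below the peak, one double root at tangency, and none above it.
#' Roots are located by `uniroot` on each monotone branch to near machine
#' precision.
#'
#' @param params a [crsd_game()].
#' @return numeric vector of roots, sorted increasing: length 0, 1 (double
#'   root) or 2.
#' @export
find_threshold_roots <- function(params) {
  if (!inherits(params, "crsd_game")) stop("params must be a crsd_game object")
  mode_x <- (params$M - 1) / (params$N - 1)
  target <- params$c / params$b
  peak <- gamma_kernel(mode_x, params)
  if (target > peak) return(numeric(0))
  if (abs(target - peak) < 1e-14) return(mode_x)
  f <- function(x) gamma_kernel(x, params) - target
  r1 <- stats::uniroot(f, c(0, mode_x), tol = 1e-15, maxiter = 2000)$root
  r2 <- stats::uniroot(f, c(mode_x, 1), tol = 1e-15, maxiter = 2000)$root
  c(r1, r2)
}

# interior fixed point of the analytic variants, or NULL if it does not exist
# (r* must be strictly below 1; equality collapses onto a boundary root)
interior_point <- function(system) {
  g <- system$game; fb <- system$feedback
  xs <- switch(fb$variant,
    linear = fb$u / (1 + fb$u),
    exponential = fb$T,
    return(NULL))
  gk <- gamma_kernel(xs, g)
  if (gk <= 0) return(NULL)
  rs <- g$c / (gk * g$b)
  if (rs >= 1) return(NULL)
  c(x = xs, r = rs)
}

#' Jacobian of the coupled system
#'
#' Analytic partial derivatives of the vector field at a point `(x, r)`:
#' \deqn{J_{11} = [(1-2x)(\Gamma r b - c) + x(1-x)\Gamma'(x) r b]/\epsilon,
#'       \quad J_{12} = x(1-x)\Gamma(x) b/\epsilon,}
#' \deqn{J_{21} = r(1-r) K'(x), \quad J_{22} = (1-2r) K(x).}
#' At an interior fixed point `K = 0` and `Gamma r b = c`, so `J22 = 0` and
#' the trace reduces to `x(1-x) Gamma'(x) r b / eps`. For a custom feedback
#' law the risk row is obtained by central finite differences.
#'
#' @param system a [crsd_system()].
#' @param point numeric `c(x, r)` in the unit square.
#' @return a 2 x 2 numeric matrix.
#' @export
system_jacobian <- function(system, point) {
  if (!inherits(system, "crsd_system")) stop("system must be a crsd_system object")
  x <- point[[1]]; r <- point[[2]]
  check_unit(x, "x"); check_unit(r, "r")
  g <- system$game; fb <- system$feedback; eps <- system$eps
  gk <- gamma_kernel(x, g)
  gkd <- gamma_kernel_deriv(x, g)
  J11 <- ((1 - 2 * x) * (gk * r * g$b - g$c) + x * (1 - x) * gkd * r * g$b) / eps
  J12 <- x * (1 - x) * gk * g$b / eps
  if (fb$variant == "custom") {
    h <- 1e-6
    J21 <- (fb$rate(x + h, r) - fb$rate(x - h, r)) / (2 * h)
    J22 <- (fb$rate(x, r + h) - fb$rate(x, r - h)) / (2 * h)
  } else {
    J21 <- r * (1 - r) * risk_kernel_deriv(x, fb)
    J22 <- (1 - 2 * r) * risk_kernel(x, fb)
  }
  matrix(c(J11, J21, J12, J22), 2, 2,
         dimnames = list(c("dx", "dr"), c("x", "r")))
}

#' Stability label from Jacobian eigenvalues
#'
#' Classifies a fixed point from the real parts of the Jacobian eigenvalues,
#' with tolerance `tol` for "zero": both strictly negative -> `stable`; both
#' strictly positive, or a complex pair with positive real part -> `unstable`;
#' real eigenvalues of opposite sign -> `saddle`; a purely imaginary conjugate
#' pair -> `center_hopf`; exactly one (numerically) zero eigenvalue ->
#' `marginal_degenerate`. Degenerate cases are reported as such, never forced
#' to stable/unstable; resolving them needs center-manifold analysis or
#' simulation.
#'
#' @param system a [crsd_system()].
#' @param point numeric `c(x, r)`, a fixed point of the system.
#' @param tol zero tolerance on eigenvalue real parts.
#' @return a character label.
#' @export
classify_stability <- function(system, point, tol = 1e-9) {
  ev <- eigen(system_jacobian(system, point), only.values = TRUE)$values
  label_eigenvalues(ev, tol)
}

label_eigenvalues <- function(ev, tol = 1e-9) {
  re <- Re(ev); im <- Im(ev)
  nzero <- sum(abs(re) <= tol)
  if (nzero == 2L) {
    if (any(abs(im) > tol)) return("center_hopf")
    return("marginal_degenerate")
  }
  if (nzero == 1L) return("marginal_degenerate")
  if (all(re < -tol)) return("stable")
  if (all(re > tol)) return("unstable")
  "saddle"
}

#' Enumerate all fixed points of the coupled system
#'
#' Catalogues every equilibrium of the linear or exponential system
#' analytically: the four corners of the unit square, the high-risk boundary
#' points `(x1*, 1)` and `(x2*, 1)` when `Gamma(x) b = c` has roots, and the
#' interior point — `(u/(1+u), r*)` for the linear law, `(T, rbar)` for the
#' sigmoid law, with `r* = c / (Gamma(x) b)` evaluated at the respective `x`,
#' included only while `r* < 1` strictly. Each point is classified by its
#' Jacobian eigenvalues.
#'
#' @param system a [crsd_system()] with linear or exponential feedback.
#' @return a data frame of class `"crsd_equilibria"` with columns `x`, `r`,
#'   `kind` (`corner`, `boundary_root`, `interior`), complex `lambda1`,
#'   `lambda2`, and `stability`.
#' @export
enumerate_fixed_points <- function(system) {
  if (!inherits(system, "crsd_system")) stop("system must be a crsd_system object")
  if (system$feedback$variant == "custom")
    stop("analytic fixed-point enumeration is unsupported for custom feedback")
  pts <- data.frame(x = c(0, 0, 1, 1), r = c(0, 1, 0, 1),
                    kind = "corner", stringsAsFactors = FALSE)
  roots <- find_threshold_roots(system$game)
  if (length(roots))
    pts <- rbind(pts, data.frame(x = roots, r = 1, kind = "boundary_root"))
  ip <- interior_point(system)
  if (!is.null(ip))
    pts <- rbind(pts, data.frame(x = ip[["x"]], r = ip[["r"]], kind = "interior"))
  ev <- lapply(seq_len(nrow(pts)), function(i)
    eigen(system_jacobian(system, c(pts$x[i], pts$r[i])), only.values = TRUE)$values)
  pts$lambda1 <- vapply(ev, function(e) as.complex(e[1]), complex(1))
  pts$lambda2 <- vapply(ev, function(e) as.complex(e[2]), complex(1))
  pts$stability <- vapply(ev, label_eigenvalues, character(1))
  class(pts) <- c("crsd_equilibria", "data.frame")
  pts
}

#' @export
print.crsd_equilibria <- function(x, ...) {
  cat(sprintf("%d fixed points (%d stable)\n", nrow(x),
              sum(x$stability == "stable")))
  df <- data.frame(x = signif(x$x, 6), r = signif(x$r, 6),
                   kind = x$kind,
                   re1 = signif(Re(x$lambda1), 4), im1 = signif(Im(x$lambda1), 4),
                   re2 = signif(Re(x$lambda2), 4), im2 = signif(Im(x$lambda2), 4),
                   stability = x$stability)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarise a coupled system: equilibria, region, Hopf threshold
#'
#' Runs the full analytic work-up: fixed-point enumeration with stability,
#' the parameter-region label, and the Hopf threshold of the system's family.
#'
#' @param object a [crsd_system()].
#' @param ... unused.
#' @return a list of class `"summary.crsd_system"`.
#' @export
summary.crsd_system <- function(object, ...) {
  fp <- enumerate_fixed_points(object)
  structure(list(
    system = object,
    fixed_points = fp,
    region = classify_region(object$game, object$feedback),
    hopf = hopf_threshold(object$game, object$feedback$variant)
  ), class = "summary.crsd_system")
}

#' @export
print.summary.crsd_system <- function(x, ...) {
  print(x$system)
  cat("\n")
  print(x$fixed_points)
  cat(sprintf("\nRegion: %s\n", x$region$label))
  cat(sprintf("Hopf threshold (%s family): %s = %.10g\n",
              x$system$feedback$variant,
              if (x$system$feedback$variant == "linear") "u" else "T", x$hopf))
  invisible(x)
}
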