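#' Strategy-to-risk feedback laws
#'
#' The risk of collective failure is a dynamical variable driven by the
#' population strategy profile through `dr/dt = r (1 - r) K(x)`, where the
#' logistic factor confines `r` to `[0, 1]` and the kernel `K` encodes how the
#' cooperation level moves the risk:
#'
#' * **linear**: `K(x) = u (1 - x) - x` — defectors raise the risk at rate
#'   `u`, cooperators lower it at relative rate one. The kernel balances at
#'   `x = u / (1 + u)`.
#' * **exponential** (sigmoid): `K(x) = B(x - T)` with
#'   `B(xi) = 1/(1 + exp(beta * xi)) - 1/(1 + exp(-beta * xi))`, so the risk
#'   falls when the cooperator frequency exceeds the threshold `T` and rises
#'   below it, with steepness `beta` (steplike as `beta -> Inf`).
#' * **custom**: any user-supplied kernel `function(x, r)` returning `dr/dt`
#'   directly; no analytic equilibrium support.
#'
#' @param u positive risk-enhancement rate of defection (linear law).
#' @param T cooperation threshold in `(0, 1)` (sigmoid law).
#' @param beta nonnegative steepness (sigmoid law). `beta = 0` is allowed but
#'   makes the risk static (strategies have no effect on the risk level); a
#'   warning flags it.
#' @param rate function of `(x, r)` returning `dr/dt` (custom law).
#' @return An object of class `"crsd_feedback"`.
#' @examples
#' linear_feedback(u = 2)
#' exponential_feedback(T = 0.5, beta = 10)
#' @name feedback
NULL

#' @rdname feedback
#' @export
linear_feedback <- function(u) {
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u <= 0)
    stop("linear feedback requires u > 0")
  structure(list(variant = "linear", u = u), class = "crsd_feedback")
}

#' @rdname feedback
#' @export
exponential_feedback <- function(T, beta = 10) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0 || T >= 1)
    stop("exponential feedback requires 0 < T < 1")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("exponential feedback requires beta >= 0")
  if (beta == 0)
    warning("beta = 0: strategies have no effect on the risk level")
  structure(list(variant = "exponential", T = T, beta = beta),
            class = "crsd_feedback")
}

#' @rdname feedback
#' @export
custom_feedback <- function(rate) {
  if (!is.function(rate) || length(formals(rate)) < 2L)
    stop("custom feedback requires a function(x, r) returning dr/dt")
  structure(list(variant = "custom", rate = rate), class = "crsd_feedback")
}

#' @export
print.crsd_feedback <- function(x, ...) {
  switch(x$variant,
    linear = cat(sprintf("Linear risk feedback: dr/dt = r(1-r)[u(1-x) - x], u = %g\n", x$u)),
    exponential = cat(sprintf(
      "Sigmoid risk feedback: dr/dt = r(1-r) B(x - T), T = %g, beta = %g\n", x$T, x$beta)),
    custom = cat("Custom risk feedback: dr/dt = rate(x, r)\n"))
  invisible(x)
}

#' Sigmoid feedback response B(xi)
#'
#' `B(xi) = 1/(1 + exp(beta * xi)) - 1/(1 + exp(-beta * xi))`, the odd,
#' decreasing response of the risk rate to the offset `xi = x - T`.
#' Evaluated internally as `-tanh(beta * xi / 2)` — an algebraic identity —
#' so it is overflow-safe for arbitrarily large `beta * xi`, covering the
#' steplike regime.
#'
#' @param xi numeric offset `x - T` (vectorised).
#' @param beta nonnegative steepness.
#' @return values in `[-1, 1]`.
#' @export
sigmoid_B <- function(xi, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("beta must be a single nonnegative number")
  -tanh(beta * xi / 2)
}

# derivative dB/dxi, needed by the analytic Jacobian
sigmoid_B_deriv <- function(xi, beta) {
  -(beta / 2) / cosh(beta * xi / 2)^2
}

# kernel K(x) with dr/dt = r(1-r) K(x); analytic variants only
risk_kernel <- function(x, feedback) {
  switch(feedback$variant,
    linear = feedback$u * (1 - x) - x,
    exponential = sigmoid_B(x - feedback$T, feedback$beta),
    stop("no analytic risk kernel for the custom feedback variant"))
}

risk_kernel_deriv <- function(x, feedback) {
  switch(feedback$variant,
    linear = rep_len(-(feedback$u + 1), length(x)),
    exponential = sigmoid_B_deriv(x - feedback$T, feedback$beta),
    stop("no analytic risk kernel for the custom feedback variant"))
}

#' Risk growth rate dr/dt
#'
#' Evaluates the risk equation for a feedback law. Both boundaries `r = 0`
#' and `r = 1` are absorbing for the analytic variants (the logistic factor
#' vanishes), so the risk stays a probability.
#'
#' @param x cooperator frequency in `[0, 1]`.
#' @param r risk in `[0, 1]`.
#' @param feedback a `"crsd_feedback"` object.
#' @return `dr/dt` (vectorised over `x` and `r`).
#' @export
risk_rate <- function(x, r, feedback) {
  check_unit(x, "x"); check_unit(r, "r")
  if (feedback$variant == "custom") {
    val <- feedback$rate(x, r)
    if (any(!is.finite(val))) stop("custom feedback rate returned a non-finite value")
    return(val)
  }
  r * (1 - r) * risk_kernel(x, feedback)
}
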