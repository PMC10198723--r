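#' Couple a game to a risk feedback law
#'
#' Builds the planar dynamical system on the unit square
#' \deqn{\epsilon \dot x = x (1 - x) [\Gamma(x)\, r\, b - c], \qquad
#'       \dot r = r (1 - r) K(x),}
#' where `x` is the cooperator frequency, `r` the risk of collective failure,
#' and `eps` the relative speed of strategy updating (small `eps` means
#' strategies evolve much faster than the risk). Time units are those of the
#' risk equation; `eps` divides the strategy equation only, so the fixed-point
#' set does not depend on it.
#'
#' @param game a [crsd_game()].
#' @param feedback a feedback law from [linear_feedback()],
#'   [exponential_feedback()] or [custom_feedback()].
#' @param eps positive relative strategy-update speed.
#' @return An object of class `"crsd_system"`.
#' @examples
#' sys <- crsd_system(crsd_game(6, 3, 1, 0.1), linear_feedback(u = 2), eps = 0.1)
#' system_rhs(2 / 3, 0.1 / gamma_kernel(2 / 3, sys$game), sys)  # interior fixed point
#' @export
crsd_system <- function(game, feedback, eps = 0.1) {
  if (!inherits(game, "crsd_game")) stop("game must be a crsd_game object")
  if (!inherits(feedback, "crsd_feedback")) stop("feedback must be a crsd_feedback object")
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must satisfy eps > 0")
  structure(list(game = game, feedback = feedback, eps = eps),
            class = "crsd_system")
}

# unchecked vector field, usable slightly outside [0,1]^2 (finite differences,
# adaptive solver trial steps); the exported wrapper validates the domain
rhs_raw <- function(x, r, system) {
  g <- system$game
  dx <- x * (1 - x) * (gamma_kernel_unchecked(x, g) * r * g$b - g$c) / system$eps
  fb <- system$feedback
  dr <- if (fb$variant == "custom") fb$rate(x, r)
        else r * (1 - r) * risk_kernel(x, fb)
  c(dx, dr)
}

# gamma without the [0,1] domain check (finite-difference stencils may poke
# marginally outside; the polynomial extends analytically)
gamma_kernel_unchecked <- function(x, params) {
  choose(params$N - 1, params$M - 1) * x^(params$M - 1) * (1 - x)^(params$N - params$M)
}

#' Coupled vector field
#'
#' Right-hand side of the strategy-risk system at a state `(x, r)`.
#'
#' @param x cooperator frequency in `[0, 1]`.
#' @param r risk in `[0, 1]`.
#' @param system a [crsd_system()].
#' @return numeric vector `c(dx = dx/dt, dr = dr/dt)`.
#' @export
system_rhs <- function(x, r, system) {
  if (!inherits(system, "crsd_system")) stop("system must be a crsd_system object")
  check_unit(x, "x"); check_unit(r, "r")
  out <- rhs_raw(x, r, system)
  names(out) <- c("dx", "dr")
  out
}

#' @export
print.crsd_system <- function(x, ...) {
  cat("Coupled strategy-risk system\n")
  print(x$game)
  print(x$feedback)
  cat(sprintf("  strategy-update speed eps = %g\n", x$eps))
  if (!is.null(attr(x, "preset")))
    cat(sprintf("  preset: %s\n", attr(x, "preset")))
  invisible(x)
}

#' @export
coef.crsd_system <- function(object, ...) {
  g <- object$game; fb <- object$feedback
  out <- c(N = g$N, M = g$M, b = g$b, c = g$c, eps = object$eps)
  if (fb$variant == "linear") out <- c(out, u = fb$u)
  if (fb$variant == "exponential") out <- c(out, T = fb$T, beta = fb$beta)
  out
}
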