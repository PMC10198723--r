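#' Define a collective-risk social dilemma game
#'
#' Constructs the static game: groups of `N` players each hold an endowment
#' `b`; cooperators pay a contribution `c` into a common pool. If at least `M`
#' group members cooperate the collective target is met and every player keeps
#' their remaining endowment; otherwise all players lose their remaining
#' endowment with probability `r` (the risk of collective failure, a state
#' variable of the coupled dynamics, not a game parameter).
#'
#' @param N integer group size, at least 3.
#' @param M integer cooperator threshold, strictly between 1 and `N`.
#'   Fractional values are rejected, not floored.
#' @param b endowment, must be positive.
#' @param c contribution cost, must satisfy `0 < c < b`: a genuine but
#'   non-dominating sacrifice. With `c >= b` cooperation is strictly dominated
#'   at every composition and the construction is refused.
#'
#' @return An object of class `"crsd_game"`: a list with elements `N`, `M`,
#'   `b`, `c`.
#' @examples
#' g <- crsd_game(N = 6, M = 3, b = 1, c = 0.1)
#' payoff_difference(0.4, r = 1, g)
#' @export
crsd_game <- function(N, M, b, c) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N != round(N))
    stop("N must be a single integer")
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M))
    stop("M must be a single number")
  if (M != round(M))
    stop("M must be integral; got M = ", M)
  if (N < 2) stop("N must satisfy N >= 2")
  if (!(M > 1 && M < N))
    stop("M must satisfy 1 < M < N; got M = ", M, ", N = ", N)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("b must be a positive number")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0 || c >= b)
    stop("c must satisfy 0 < c < b (c >= b makes cooperation strictly dominated)")
  structure(list(N = as.integer(N), M = as.integer(M), b = b, c = c),
            class = "crsd_game")
}

#' @export
print.crsd_game <- function(x, ...) {
  cat("Collective-risk social dilemma game\n")
  cat(sprintf("  group size N = %d, threshold M = %d\n", x$N, x$M))
  cat(sprintf("  endowment b = %g, cost c = %g (c/b = %g)\n", x$b, x$c, x$c / x$b))
  cat(sprintf("  pivotal composition at x = (M-1)/(N-1) = %g, max Gamma = %g\n",
              (x$M - 1) / (x$N - 1), gamma_kernel((x$M - 1) / (x$N - 1), x)))
  invisible(x)
}

#' Heaviside step function
#'
#' The threshold indicator used in the payoff definitions: 0 for negative
#' arguments, 1 otherwise (in particular `heaviside(0) == 1`, so a group that
#' exactly meets the target succeeds).
#'
#' @param z numeric vector of finite values.
#' @return 0/1 vector of the same length.
#' @export
heaviside <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) stop("heaviside requires finite numeric input")
  as.numeric(z >= 0)
}

check_jc <- function(jC, params) {
  if (any(jC != round(jC)) || any(jC < 0) || any(jC > params$N - 1))
    stop("jC must be an integer count in [0, N-1]")
}

check_unit <- function(v, name) {
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop(name, " must lie in [0, 1]")
}

#' Payoff of a cooperator in a group
#'
#' A focal cooperator with `jC` cooperating co-players receives `b - c` when
#' the group meets the target (`jC + 1 >= M`) and `(1 - r) * b - c` otherwise:
#' the contribution is sunk either way, and a missed target forfeits the
#' remaining endowment with probability `r`.
#'
#' @param jC integer count of cooperating co-players, in `[0, N-1]`.
#' @param r risk of collective failure in `[0, 1]`.
#' @param params a [crsd_game()].
#' @return expected payoff (vectorised over `jC`).
#' @export
payoff_cooperator <- function(jC, r, params) {
  check_jc(jC, params)
  check_unit(r, "r")
  met <- heaviside(jC + 1 - params$M)
  params$b * met + (1 - r) * params$b * (1 - met) - params$c
}

#' Payoff of a defector in a group
#'
#' A focal defector with `jC` cooperating co-players keeps `b` when the group
#' meets the target without them (`jC >= M`) and expects `(1 - r) * b`
#' otherwise.
#'
#' @inheritParams payoff_cooperator
#' @return expected payoff (vectorised over `jC`).
#' @export
payoff_defector <- function(jC, r, params) {
  check_jc(jC, params)
  check_unit(r, "r")
  met <- heaviside(jC - params$M)
  params$b * met + (1 - r) * params$b * (1 - met)
}

#' Gradient-of-selection kernel Gamma(x)
#'
#' `Gamma(x) = choose(N-1, M-1) x^(M-1) (1-x)^(N-M)`: the probability that a
#' focal player is pivotal, i.e. finds exactly `M - 1` cooperators among its
#' `N - 1` co-players. Unimodal on `[0, 1]` with maximum at
#' `x = (M-1)/(N-1)`; this kernel scales the benefit of cooperating in the
#' closed-form payoff difference.
#'
#' @param x cooperator frequency in `[0, 1]` (vectorised).
#' @param params a [crsd_game()].
#' @return nonnegative numeric vector.
#' @export
gamma_kernel <- function(x, params) {
  check_unit(x, "x")
  N <- params$N; M <- params$M
  if (N > 50) {
    # log-space to avoid overflow of the binomial coefficient at large N
    out <- numeric(length(x))
    inner <- x > 0 & x < 1
    out[inner] <- exp(lchoose(N - 1, M - 1) +
                        (M - 1) * log(x[inner]) + (N - M) * log1p(-x[inner]))
    out
  } else {
    choose(N - 1, M - 1) * x^(M - 1) * (1 - x)^(N - M)
  }
}

#' Derivative of the selection kernel
#'
#' Analytic `Gamma'(x) = choose(N-1,M-1) x^(M-2) (1-x)^(N-M-1)
#' [(M-1)(1-x) - (N-M)x]`, used by the Jacobian and the Hopf trace condition.
#'
#' @inheritParams gamma_kernel
#' @return numeric vector.
#' @export
gamma_kernel_deriv <- function(x, params) {
  check_unit(x, "x")
  N <- params$N; M <- params$M
  # exponents M-2 and N-M-1 can be 0 at the boundary; 0^0 = 1 is the right limit
  choose(N - 1, M - 1) * x^(M - 2) * (1 - x)^(N - M - 1) *
    ((M - 1) * (1 - x) - (N - M) * x)
}

#' Closed-form payoff difference fC - fD
#'
#' Averaged over the binomial group composition, the payoff advantage of
#' cooperation reduces to `Gamma(x) * r * b - c`: cooperating only pays off in
#' the pivotal composition (exactly `M - 1` cooperating co-players), where it
#' converts a risked endowment `r * b` at cost `c`.
#'
#' @param x cooperator frequency in `[0, 1]`.
#' @param r risk in `[0, 1]`.
#' @param params a [crsd_game()].
#' @return numeric payoff difference.
#' @seealso [average_payoffs()] for the explicit binomial expectation.
#' @export
payoff_difference <- function(x, r, params) {
  check_unit(x, "x"); check_unit(r, "r")
  gamma_kernel(x, params) * r * params$b - params$c
}

#' Exact binomial average payoffs
#'
#' Expectations of the cooperator and defector payoffs over the group
#' composition `jC ~ Binomial(N - 1, x)`. This is the brute-force enumeration
#' that the closed form [payoff_difference()] must reproduce exactly; it is
#' kept as an independent oracle.
#'
#' @inheritParams payoff_difference
#' @return named numeric vector `c(fC = ..., fD = ...)`.
#' @export
average_payoffs <- function(x, r, params) {
  check_unit(x, "x"); check_unit(r, "r")
  jC <- 0:(params$N - 1)
  w <- stats::dbinom(jC, params$N - 1, x)
  c(fC = sum(w * payoff_cooperator(jC, r, params)),
    fD = sum(w * payoff_defector(jC, r, params)))
}
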