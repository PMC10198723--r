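#' Classify the long-run regime of a parameter combination
#'
#' Places a (game, feedback) pair in the phase diagram of stable evolutionary
#' outcomes. Writing `xb` for the balance point of the feedback kernel
#' (`u/(1+u)` for the linear law, `T` for the sigmoid law) and `u_c`/`T_c` for
#' the Hopf threshold of the family:
#'
#' * interior point exists (`Gamma(xb) b > c`) and the feedback parameter is
#'   above threshold -> `bistable_interior`: the tragedy point `(0, 1)` and
#'   the interior point `(xb, r*)` are both stable;
#' * at the threshold (within `tol`) -> `hopf_line`: only `(0, 1)` is stable
#'   among fixed points, with a stable limit cycle around the interior point;
#' * below threshold -> `defection_only`: `(0, 1)` is the global attractor;
#' * no interior point but two boundary roots with `x2* < xb` ->
#'   `bistable_boundary`: `(0, 1)` and the high-cooperation boundary point
#'   `(x2*, 1)` are stable;
#' * otherwise -> `defection_only`.
#'
#' @param params a [crsd_game()].
#' @param feedback a linear or exponential `"crsd_feedback"`.
#' @param tol tolerance for sitting exactly on the Hopf line.
#' @return a list of class `"crsd_region"` with elements `label`,
#'   `stable_set` (data frame of stable fixed points) and `limit_cycle`
#'   (logical).
#' @export
classify_region <- function(params, feedback, tol = 1e-9) {
  if (!inherits(params, "crsd_game")) stop("params must be a crsd_game object")
  if (!inherits(feedback, "crsd_feedback") || feedback$variant == "custom")
    stop("region classification needs a linear or exponential feedback law")
  linear <- feedback$variant == "linear"
  par_val <- if (linear) feedback$u else feedback$T
  xb <- if (linear) feedback$u / (1 + feedback$u) else feedback$T
  thr <- hopf_threshold(params, feedback$variant)
  tragedy <- data.frame(x = 0, r = 1)
  gk <- gamma_kernel(xb, params)
  if (gk * params$b > params$c) {
    rstar <- params$c / (gk * params$b)
    if (abs(par_val - thr) <= tol) {
      out <- list(label = "hopf_line", stable_set = tragedy, limit_cycle = TRUE)
    } else if (par_val > thr) {
      out <- list(label = "bistable_interior",
                  stable_set = rbind(tragedy, data.frame(x = xb, r = rstar)),
                  limit_cycle = FALSE)
    } else {
      out <- list(label = "defection_only", stable_set = tragedy,
                  limit_cycle = FALSE)
    }
  } else {
    roots <- find_threshold_roots(params)
    if (length(roots) == 2L && roots[2] < xb) {
      out <- list(label = "bistable_boundary",
                  stable_set = rbind(tragedy, data.frame(x = roots[2], r = 1)),
                  limit_cycle = FALSE)
    } else {
      out <- list(label = "defection_only", stable_set = tragedy,
                  limit_cycle = FALSE)
    }
  }
  class(out) <- "crsd_region"
  out
}

#' @export
print.crsd_region <- function(x, ...) {
  cat(sprintf("Region: %s\n", x$label))
  cat("Stable set:\n")
  print(x$stable_set, row.names = FALSE)
  if (x$limit_cycle) cat("plus a stable limit cycle around the interior point\n")
  invisible(x)
}

#' Sweep the parameter plane of stable outcomes
#'
#' Classifies a grid over (feedback parameter, cost-to-endowment ratio) into
#' regimes, reproducing the phase-diagram partition of the parameter plane
#' `(u, c/b)` or `(T, c/b)`.
#'
#' @param N,M,b game parameters held fixed across the sweep.
#' @param family `"linear"` or `"exponential"`.
#' @param param_vals grid of `u` (linear) or `T` (exponential) values.
#' @param cb_vals grid of `c/b` ratios, each in (0, 1).
#' @param beta sigmoid steepness (exponential family only).
#' @return data frame with columns `u_or_T`, `c_over_b`, `label`.
#' @export
region_sweep <- function(N, M, b = 1, family = c("linear", "exponential"),
                         param_vals, cb_vals, beta = 10) {
  family <- match.arg(family)
  grid <- expand.grid(u_or_T = param_vals, c_over_b = cb_vals,
                      KEEP.OUT.ATTRS = FALSE)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    g <- crsd_game(N, M, b, grid$c_over_b[i] * b)
    fb <- if (family == "linear") linear_feedback(grid$u_or_T[i])
          else exponential_feedback(grid$u_or_T[i], beta)
    classify_region(g, fb)$label
  }, character(1))
  grid
}
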