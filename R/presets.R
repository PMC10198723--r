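.presets <- list(
  "linear-bistable"   = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "linear", u = 2),
  "linear-hopf"       = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "linear", u = 2 / 3),
  "linear-defection"  = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "linear", u = 0.5),
  "linear-boundary"   = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "linear", u = 4),
  "sigmoid-bistable"  = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "exponential", T = 0.5, beta = 10),
  "sigmoid-hopf"      = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "exponential", T = 0.4, beta = 10),
  "sigmoid-defection" = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "exponential", T = 0.2, beta = 10),
  "sigmoid-boundary"  = list(N = 6, M = 3, b = 1, c = 0.1, eps = 0.1,
                             variant = "exponential", T = 0.8, beta = 10)
)

#' Named parameter presets
#'
#' Ready-made coupled systems covering the characteristic regimes of both
#' feedback families at the reference game (N = 6, M = 3, b = 1, c = 0.1,
#' eps = 0.1): bistable coexistence with an interior point, the Hopf line
#' with its limit cycle, the defection-only regime, and the bistable
#' high-risk-boundary regime (u = 2, 2/3, 0.5, 4 for the linear family;
#' T = 0.5, 0.4, 0.2, 0.8 with beta = 10 for the sigmoid family).
#'
#' @param name one of [preset_names()].
#' @return a [crsd_system()] with attribute `"preset"`.
#' @examples
#' summary(crsd_preset("linear-bistable"))
#' @export
crsd_preset <- function(name) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.presets), collapse = ", "))
  p <- .presets[[name]]
  fb <- if (p$variant == "linear") linear_feedback(p$u)
        else exponential_feedback(p$T, p$beta)
  sys <- crsd_system(crsd_game(p$N, p$M, p$b, p$c), fb, p$eps)
  attr(sys, "preset") <- name
  sys
}

#' @rdname crsd_preset
#' @export
preset_names <- function() names(.presets)
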