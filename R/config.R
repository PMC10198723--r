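config_defaults <- function() {
  list(
    init = list(x0 = 0.4, r0 = 0.3),
    eps = 0.1,
    t_max = 2000,
    rtol = 1e-10,
    atol = 1e-10,
    grid_resolution = 21,
    sweep = list(param_min = 0.1, param_max = 5, n_param = 25,
                 cb_min = 0.02, cb_max = 0.4, n_cb = 20),
    out_dir = ".",
    quiet = FALSE
  )
}

allowed_config_keys <- list(
  top = c("preset", "game", "feedback", "eps", "init", "t_max", "rtol",
          "atol", "grid_resolution", "sweep", "out_dir", "quiet"),
  game = c("N", "M", "b", "c"),
  feedback = c("variant", "u", "T", "beta"),
  init = c("x0", "r0"),
  sweep = c("param_min", "param_max", "n_param", "cb_min", "cb_max", "n_cb")
)

check_keys <- function(block, where) {
  bad <- setdiff(names(block), allowed_config_keys[[where]])
  if (length(bad)) {
    if (where == "game" && any(bad %in% c("TRUE", "FALSE")))
      stop("YAML parsed a bare key as a boolean (N/Y/n/y are YAML booleans); ",
           "quote it, e.g. 'N': 6")
    stop("unknown configuration key", if (length(bad) > 1) "s", " in ", where,
         ": ", paste(bad, collapse = ", "))
  }
}

# "a.b=3" style overrides applied onto a nested list; values parsed as
# numeric/logical when they look like it
apply_override <- function(cfg, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v)) {
    v <- if (identical(value, "true")) TRUE
         else if (identical(value, "false")) FALSE
         else value
  }
  cfg[[path]] <- v
  cfg
}

#' Load and validate a run configuration
#'
#' Assembles a configuration from (in increasing precedence) package
#' defaults, a named preset, a YAML or JSON file, and explicit overrides.
#' All game/feedback/system invariants are validated here, before any
#' computation; unknown keys are rejected by name.
#'
#' @param path optional path to a YAML (`.yml`/`.yaml`) or JSON (`.json`)
#'   configuration file; the file may itself name a `preset`.
#' @param preset optional preset name, see [preset_names()].
#' @param overrides named character vector or list of dotted-path overrides,
#'   e.g. `c("feedback.u" = "3", "t_max" = "500")`.
#' @return a list of class `"crsd_config"` carrying the validated blocks and
#'   a constructed `system` ([crsd_system()]).
#' @export
load_config <- function(path = NULL, preset = NULL, overrides = NULL) {
  cfg <- config_defaults()
  file_cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
    check_keys(file_cfg, "top")
  }
  if (is.null(preset) && !is.null(file_cfg$preset)) preset <- file_cfg$preset
  if (!is.null(preset)) {
    p <- .presets[[preset]]
    if (is.null(p)) stop("unknown preset '", preset, "'")
    cfg$game <- p[c("N", "M", "b", "c")]
    cfg$feedback <- p[intersect(names(p), allowed_config_keys$feedback)]
    cfg$eps <- p$eps
    cfg$preset <- preset
  }
  for (k in setdiff(names(file_cfg), "preset")) {
    if (k %in% c("game", "feedback", "init", "sweep")) {
      check_keys(file_cfg[[k]], k)
      cfg[[k]] <- utils::modifyList(if (is.null(cfg[[k]])) list() else cfg[[k]],
                                    file_cfg[[k]])
    } else {
      cfg[[k]] <- file_cfg[[k]]
    }
  }
  if (!is.null(overrides) && length(overrides)) {
    ov <- as.list(overrides)
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("overrides must be named, e.g. c('feedback.u' = '3')")
    for (k in names(ov)) cfg <- apply_override(cfg, k, as.character(ov[[k]]))
    check_keys(cfg, "top")
    for (blk in c("game", "feedback", "init", "sweep"))
      if (!is.null(cfg[[blk]])) check_keys(cfg[[blk]], blk)
  }
  if (is.null(cfg$game))
    stop("configuration must supply a game block (N, M, b, c) or a preset")
  if (is.null(cfg$feedback) || is.null(cfg$feedback$variant))
    stop("configuration must supply a feedback block with a variant")
  game <- do.call(crsd_game, cfg$game)
  fb <- switch(cfg$feedback$variant,
    linear = {
      if (is.null(cfg$feedback$u))
        stop("linear feedback requires u")
      linear_feedback(cfg$feedback$u)
    },
    exponential = {
      if (is.null(cfg$feedback$T))
        stop("exponential feedback requires the threshold T")
      exponential_feedback(cfg$feedback$T,
                           if (is.null(cfg$feedback$beta)) 10 else cfg$feedback$beta)
    },
    stop("feedback variant must be 'linear' or 'exponential' in a configuration"))
  cfg$system <- crsd_system(game, fb, cfg$eps)
  check_unit(cfg$init$x0, "init x0"); check_unit(cfg$init$r0, "init r0")
  class(cfg) <- "crsd_config"
  cfg
}
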