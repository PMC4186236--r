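#' Default run configuration
#'
#' A nested list of every tunable parameter with its default. Protocol
#' runners and [load_config()] merge user values over these defaults;
#' unknown keys are rejected.
#'
#' @return nested named list.
#' @export
dac_default_config <- function() {
  list(
    world = list(
      n_rays = 8L,          # percept sectors
      sensor_range = 10,    # landmark visibility, arena units
      noise_sd = 0.1,       # motor noise sd (both encodings)
      v_max = 0.5,          # speed ceiling, units/step
      refractory = 10L,     # outcome-site silent period, steps
      sense_floor = 1e-3    # affordance values below this read as 0
    ),
    rl = list(
      kappa = 0.5,          # drive -> desired-value coupling
      n_probe = 8L,         # gradient probe headings
      probe_r = 0.5,        # probe distance
      gain = 0.15           # default BS gain
    ),
    al = list(
      K = 64L,              # prototype slots
      alpha = 0.1,          # prototype learning rate
      eta = 0.1,            # valence (delta-rule) learning rate
      lambda = 0.1,         # error-average smoothing
      theta_cr = 0.1,       # CR emission threshold
      eps_bar0 = 0.5,       # initial error average
      init_tol = 0.4        # novelty (vigilance) radius for slot recruitment
    ),
    cl = list(
      L = 30L,              # STM ring capacity
      W = 10L,              # agency window, steps
      sigma_e = 0.6,        # evidence bandwidth
      phi = 0.2,            # WM trigger decay
      gamma = 0.9,          # priming gain
      rho_C = 0.1,          # chaining learning rate
      theta_gate = 0.2,     # sub-threshold gate
      tau_c = 0.5,          # contributor threshold (fraction of max)
      tau_act = 0.9,        # evidence-activation threshold (fraction of best match)
      c_act = 0.5,          # priming-activation threshold (trigger value)
      c0 = 0.2,             # baseline chaining term
      e_min = 0.15,         # evidence floor: weaker matches contribute nothing
      lookahead = 1,        # pure-pursuit waypoint radius, arena units
      mode = "allocentric", # CL action encoding
      max_seq = 10L,        # LTM sequence cap
      enabled = TRUE
    ),
    needs = list(
      hunger = list(level0 = 0.6, set_point = 1, decay = 0.01,
                    replenish_food = 0.3)
    )
  )
}

# Recursive merge of user values over defaults; unknown keys error with
# their dotted path.
merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) stop("load_config: unknown key '", here, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stop("load_config: '", here, "' must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_range <- function(cfg, key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  v <- cfg
  for (p in parts) v <- v[[p]]
  bad <- if (lo_open) v <= lo else v < lo
  bad <- bad || if (hi_open) v >= hi else v > hi
  if (isTRUE(bad)) {
    stop("load_config: '", key, "' = ", v, " out of range ",
         if (lo_open) "(" else "[", lo, ", ", hi, if (hi_open) ")" else "]")
  }
}

validate_config <- function(cfg) {
  check_range(cfg, "al.alpha", 0, 1, lo_open = TRUE)
  check_range(cfg, "al.eta", 0, 1, lo_open = TRUE)
  check_range(cfg, "al.lambda", 0, 1, lo_open = TRUE)
  check_range(cfg, "cl.phi", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_range(cfg, "cl.gamma", 0, 1, lo_open = TRUE)
  check_range(cfg, "cl.rho_C", 0, 1, lo_open = TRUE)
  check_range(cfg, "cl.tau_c", 0, 1)
  if (cfg$al$K < 1) stop("load_config: 'al.K' must be >= 1")
  if (cfg$world$n_rays < 4) stop("load_config: 'world.n_rays' must be >= 4")
  if (cfg$world$noise_sd < 0) stop("load_config: 'world.noise_sd' must be >= 0")
  if (cfg$world$v_max <= 0) stop("load_config: 'world.v_max' must be > 0")
  if (cfg$rl$n_probe < 3) stop("load_config: 'rl.n_probe' must be >= 3")
  if (cfg$rl$probe_r <= 0) stop("load_config: 'rl.probe_r' must be > 0")
  if (cfg$cl$sigma_e <= 0) stop("load_config: 'cl.sigma_e' must be > 0")
  if (!cfg$cl$mode %in% c("allocentric", "egocentric")) {
    stop("load_config: 'cl.mode' must be 'allocentric' or 'egocentric'")
  }
  cfg
}

#' Load a run configuration from a YAML file
#'
#' User values are merged over [dac_default_config()]; unknown keys and
#' out-of-range values raise errors naming the offending key. An empty or
#' missing-content file yields all defaults.
#'
#' @param path YAML file path.
#' @return the fully resolved configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_config(dac_default_config(), user))
}

#' Write a resolved configuration to YAML
#' @param cfg configuration list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Override a configuration key by dotted path
#'
#' @param cfg configuration list.
#' @param key dotted path, e.g. \code{"al.eta"}.
#' @param value replacement value (coerced to the type of the default).
#' @return the updated configuration.
#' @export
config_set <- function(cfg, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (p in parts) {
    if (!p %in% names(node)) stop("config_set: unknown key '", key, "'")
    node <- node[[p]]
  }
  if (is.numeric(node)) value <- as.numeric(value)
  if (is.integer(node)) value <- as.integer(value)
  if (is.logical(node)) value <- as.logical(value)
  expr <- paste0("cfg", paste0("[['", parts, "']]", collapse = ""), " <- value")
  eval(parse(text = expr))
  validate_config(cfg)
}
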