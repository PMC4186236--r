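#' Construct a 2D arena
#'
#' The arena is the task space: a continuous \code{width x height} rectangle
#' with origin at the bottom-left, optional interior walls, visually distinct
#' landmarks, localized cue sites, outcome (goal) sites and named affordance
#' fields over which the reactive layer's behaviour systems operate.
#'
#' @param width,height arena extent in arena units (positive reals).
#' @param walls list of numeric length-4 vectors \code{c(x1, y1, x2, y2)}.
#' @param landmarks list of \code{list(id, pos = c(x, y), features)}; all
#'   feature vectors must share one length.
#' @param cues list of \code{list(id, pos, radius, channel)}; channels are
#'   consecutive integers starting at 1.
#' @param outcome_sites list of \code{list(id, pos, outcome_id, radius)}.
#' @param fields named list of [affordance_field()] objects.
#' @return an object of class \code{dac_arena}.
#' @export
arena <- function(width, height, walls = list(), landmarks = list(),
                  cues = list(), outcome_sites = list(), fields = list()) {
  a <- structure(list(width = width, height = height, walls = walls,
                      landmarks = landmarks, cues = cues,
                      outcome_sites = outcome_sites, fields = fields),
                 class = "dac_arena")
  validate_arena(a)
  a
}

#' Validate arena invariants
#'
#' Checks that all positions are inside bounds, that landmark/cue/outcome ids
#' are unique, that landmark feature vectors share a common length and that
#' every field source has positive width.
#'
#' @param a a \code{dac_arena}.
#' @return \code{a}, invisibly; errors on violation.
#' @export
validate_arena <- function(a) {
  stopifnot(a$width > 0, a$height > 0)
  inside <- function(p) p[1] >= 0 && p[1] <= a$width && p[2] >= 0 && p[2] <= a$height
  for (grp in c("landmarks", "cues", "outcome_sites")) {
    ids <- vapply(a[[grp]], function(x) as.character(x$id), "")
    if (anyDuplicated(ids)) stop("duplicate ids in ", grp)
    for (x in a[[grp]]) if (!inside(x$pos)) stop("position outside arena in ", grp, ": ", x$id)
  }
  fl <- unique(vapply(a$landmarks, function(l) length(l$features), 0L))
  if (length(fl) > 1L) stop("landmark feature vectors must share one length")
  for (f in a$fields) {
    for (s in f$sources) {
      if (s$sigma <= 0) stop("field source sigma must be > 0")
      if (!inside(s$center)) stop("field source center outside arena")
    }
  }
  invisible(a)
}

#' Construct an affordance field
#'
#' An affordance field is the spatial distribution of a behaviour system's
#' attractive (or repellant) force over the task space, modelled as a sum of
#' isotropic Gaussian source kernels.
#'
#' @param field_id character id.
#' @param sources list of \code{list(center = c(x, y), amplitude, sigma)}.
#' @return an object of class \code{affordance_field}.
#' @export
affordance_field <- function(field_id, sources) {
  structure(list(field_id = field_id, sources = sources),
            class = "affordance_field")
}

#' Sample an affordance field at a position
#'
#' Returns \eqn{\sum_s A_s \exp(-\|p - c_s\|^2 / (2\sigma_s^2))}. The field is
#' veridical: the agent senses the environmental value at its own position.
#'
#' @param field an [affordance_field()].
#' @param pos numeric length-2 position.
#' @param arena optionally, the arena; if supplied, out-of-bounds positions
#'   raise an error.
#' @return scalar field value.
#' @export
sample_field <- function(field, pos, arena = NULL) {
  if (!is.null(arena) &&
      (pos[1] < 0 || pos[1] > arena$width || pos[2] < 0 || pos[2] > arena$height)) {
    stop("sample_field: position outside arena")
  }
  v <- 0
  for (s in field$sources) {
    d2 <- (pos[1] - s$center[1])^2 + (pos[2] - s$center[2])^2
    v <- v + s$amplitude * exp(-d2 / (2 * s$sigma^2))
  }
  v
}

# Field value at many positions (n x 2 matrix) at once; inner-loop helper.
sample_field_many <- function(field, P) {
  v <- numeric(nrow(P))
  for (s in field$sources) {
    d2 <- (P[, 1] - s$center[1])^2 + (P[, 2] - s$center[2])^2
    v <- v + s$amplitude * exp(-d2 / (2 * s$sigma^2))
  }
  v
}

# Attainable maximum of a field, approximated as the largest sampled value
# over all source centers (exact for well-separated sources).
field_cap <- function(field) {
  if (!length(field$sources)) return(0)
  max(vapply(field$sources, function(s) sample_field(field, s$center), 0))
}

#' Construct an agent pose
#' @param x,y position in arena units.
#' @param heading heading in radians; wrapped to \code{[-pi, pi)}.
#' @return an object of class \code{agent_pose}.
#' @export
agent_pose <- function(x, y, heading = 0) {
  structure(list(position = c(x, y), heading = wrap_angle(heading)),
            class = "agent_pose")
}

#' Construct an action
#'
#' Egocentric actions are (turn, forward speed) pairs; allocentric actions
#' are movement vectors in arena coordinates pointing from the agent's
#' current position toward a target location.
#'
#' @param mode \code{"egocentric"} or \code{"allocentric"}.
#' @param turn turn angle in radians (egocentric).
#' @param speed forward speed, >= 0 (egocentric).
#' @param vec numeric length-2 movement vector (allocentric).
#' @return an object of class \code{dac_action}.
#' @export
action <- function(mode = c("egocentric", "allocentric"),
                   turn = 0, speed = 0, vec = c(0, 0)) {
  mode <- match.arg(mode)
  structure(list(mode = mode, turn = turn, speed = speed, vec = vec),
            class = "dac_action")
}

#' The null action (no movement)
#' @return an egocentric [action()] with zero turn and speed.
#' @export
null_action <- function() action("egocentric", 0, 0)

is_null_action <- function(a) {
  if (a$mode == "egocentric") a$speed == 0 && a$turn == 0 else all(a$vec == 0)
}

#' Apply an action to a pose with motor noise
#'
#' Motor noise is additive Gaussian with one shared standard deviation on
#' both egocentric components (turn and speed) and on both coordinates of an
#' allocentric vector, so comparisons between the two encodings share one
#' noise budget. Wall collisions stop motion at the wall face.
#'
#' @param pose an [agent_pose()].
#' @param act a [action()].
#' @param noise_sd motor noise standard deviation; 0 gives deterministic motion.
#' @param stream an [rng_stream()] (may be \code{NULL} when \code{noise_sd = 0}).
#' @param arena the arena (for collision handling).
#' @param v_max speed / vector-norm ceiling.
#' @return the new [agent_pose()].
#' @export
apply_action <- function(pose, act, noise_sd, stream, arena, v_max = Inf) {
  p <- pose$position
  if (act$mode == "egocentric") {
    eps <- if (noise_sd > 0) stream_rnorm(stream, 2, noise_sd) else c(0, 0)
    heading <- wrap_angle(pose$heading + act$turn + eps[1])
    v <- min(max(act$speed + eps[2], 0), v_max)
    target <- p + v * c(cos(heading), sin(heading))
    newp <- clip_move(arena, p, target)
    structure(list(position = newp, heading = heading), class = "agent_pose")
  } else {
    vec <- act$vec
    nv <- vnorm(vec)
    if (nv > v_max) vec <- vec * (v_max / nv)
    eps <- if (noise_sd > 0) stream_rnorm(stream, 2, noise_sd) else c(0, 0)
    target <- p + vec + eps
    newp <- clip_move(arena, p, target)
    structure(list(position = newp, heading = pose$heading), class = "agent_pose")
  }
}

#' Construct an essential variable
#'
#' Essential variables are the homeostatic levels of the somatic level
#' (energy, security, ...). A variable decays each step and is replenished by
#' consuming outcomes; its drive is the shortfall below its set point.
#'
#' @param name variable name.
#' @param level initial level in [0, 1].
#' @param set_point target level in [0, 1].
#' @param decay_rate loss per step, >= 0.
#' @param replenish named numeric vector, outcome_id -> amount.
#' @return an object of class \code{essential_variable}.
#' @export
essential_variable <- function(name, level = 1, set_point = 1,
                               decay_rate = 0, replenish = c()) {
  stopifnot(level >= 0, level <= 1, set_point >= 0, set_point <= 1,
            decay_rate >= 0)
  structure(list(name = name, level = level, set_point = set_point,
                 decay_rate = decay_rate, replenish = replenish),
            class = "essential_variable")
}

#' Advance essential-variable dynamics for one step
#'
#' Each level decays by its decay rate, gains the replenishment of any
#' consumed outcome, and is clipped to [0, 1].
#'
#' @param vars list of [essential_variable()]s.
#' @param consumed character vector of outcome ids consumed this step.
#' @return the updated list of variables.
#' @export
update_needs <- function(vars, consumed = character()) {
  for (o in consumed) {
    known <- any(vapply(vars, function(v) o %in% names(v$replenish), TRUE))
    if (!known) stop("update_needs: unknown outcome_id '", o, "'")
  }
  lapply(vars, function(v) {
    gain <- sum(v$replenish[consumed[consumed %in% names(v$replenish)]])
    v$level <- min(max(v$level - v$decay_rate + gain, 0), 1)
    v
  })
}

#' Current drives of a set of essential variables
#'
#' The drive of a variable is \code{max(0, set_point - level)}: zero when the
#' variable is at or above its set point.
#'
#' @param vars list of [essential_variable()]s.
#' @return named numeric vector of drives.
#' @export
need_drives <- function(vars) {
  d <- vapply(vars, function(v) max(0, v$set_point - v$level), 0)
  names(d) <- vapply(vars, function(v) v$name, "")
  d
}

#' Exosensing: ray-quantized distal percept
#'
#' The percept is a fixed-length vector: for each of \code{n_rays} equally
#' spaced headings relative to the agent's heading, the distance-attenuated
#' feature vector of the nearest landmark assigned to that ray (zeros when
#' none is within \code{range}), followed by one binary channel per cue (1
#' when the agent is inside the cue's radius). A landmark is assigned
#' fractionally to the two rays adjacent to its bearing (bilinear split),
#' so the percept varies continuously with heading and position; rotating
#' the agent by exactly \code{2*pi/n_rays} cyclically shifts the ray
#' blocks by one. Attenuation is linear: \code{1 - d/range}. Walls do not
#' occlude.
#'
#' @param arena the arena.
#' @param pose the agent pose.
#' @param n_rays number of sectors, >= 4.
#' @param range sensor range in arena units.
#' @param n_channels number of cue channels in the percept (defaults to the
#'   highest channel index used by the arena's cues).
#' @return numeric percept vector of length \code{n_rays * f + n_channels}.
#' @export
sense_exo <- function(arena, pose, n_rays = 8, range = 10, n_channels = NULL) {
  stopifnot(n_rays >= 4)
  f <- if (length(arena$landmarks)) length(arena$landmarks[[1]]$features) else 0L
  if (is.null(n_channels)) {
    n_channels <- if (length(arena$cues)) {
      max(vapply(arena$cues, function(c) as.integer(c$channel), 0L))
    } else 0L
  }
  out <- numeric(n_rays * f + n_channels)
  if (f > 0L && length(arena$landmarks)) {
    best_d <- rep(Inf, n_rays)
    best_i <- rep(0L, n_rays)
    best_w <- rep(0, n_rays)
    sector <- 2 * pi / n_rays
    for (i in seq_along(arena$landmarks)) {
      l <- arena$landmarks[[i]]
      dv <- l$pos - pose$position
      d <- vnorm(dv)
      if (d > range || d == 0) next
      rel <- wrap_angle(atan2(dv[2], dv[1]) - pose$heading)
      u <- (rel / sector) %% n_rays     # continuous ray coordinate
      r0 <- (floor(u) %% n_rays) + 1L
      r1 <- (r0 %% n_rays) + 1L
      frac <- u - floor(u)
      for (rw in list(c(r0, 1 - frac), c(r1, frac))) {
        r <- rw[1]
        if (rw[2] > 0 && d < best_d[r]) {
          best_d[r] <- d
          best_i[r] <- i
          best_w[r] <- rw[2]
        }
      }
    }
    for (r in seq_len(n_rays)) {
      if (best_i[r] > 0L) {
        att <- (1 - best_d[r] / range) * best_w[r]
        out[((r - 1L) * f + 1L):(r * f)] <- arena$landmarks[[best_i[r]]]$features * att
      }
    }
  }
  for (cu in arena$cues) {
    if (vnorm(cu$pos - pose$position) <= cu$radius) {
      out[n_rays * f + cu$channel] <- 1
    }
  }
  out
}

#' Construct an outcome table
#'
#' The outcome table stores, for each outcome id, its current (mutable)
#' valence and the essential variable it serves. It is read at decision time
#' by the contextual layer's valence factor; [devalue_outcome()] edits it.
#'
#' @param ... named lists \code{list(valence, need_id)}, one per outcome id.
#' @return an object of class \code{outcome_table}.
#' @export
outcome_table <- function(...) {
  structure(list(...), class = "outcome_table")
}

#' Change the current valence of an outcome
#'
#' Models outcome devaluation (e.g. pairing a food reward with nausea): the
#' table entry's valence is replaced and every downstream read — outcome
#' events and the contextual layer's goal re-evaluation — sees the new value
#' immediately, without re-learning.
#'
#' @param outcomes an [outcome_table()].
#' @param outcome_id id to edit.
#' @param new_valence signed real replacement valence.
#' @return the edited table.
#' @export
devalue_outcome <- function(outcomes, outcome_id, new_valence) {
  if (is.null(outcomes[[outcome_id]])) {
    stop("devalue_outcome: unknown outcome_id '", outcome_id, "'")
  }
  outcomes[[outcome_id]]$valence <- new_valence
  outcomes
}

#' Check outcome sites and fire an outcome event
#'
#' An event fires iff the agent is within the consumption radius of a site
#' that is currently armed (per the protocol's arming rule) and not in its
#' refractory period. The event carries the outcome's current valence from
#' the table.
#'
#' @param arena the arena.
#' @param pose the agent pose.
#' @param outcomes an [outcome_table()].
#' @param site_state list per site: \code{list(armed, armed_by_agent,
#'   refractory_until)}; names match site ids.
#' @param step current step index.
#' @param refractory number of steps a site stays silent after firing.
#' @return \code{list(event, site_state)} where \code{event} is \code{NULL}
#'   or \code{list(outcome_id, site_id, valence, need_id, armed_by_agent)}.
#' @export
trigger_outcome <- function(arena, pose, outcomes, site_state, step,
                            refractory = 10) {
  for (s in arena$outcome_sites) {
    st <- site_state[[s$id]]
    if (is.null(st) || !isTRUE(st$armed)) next
    if (step < st$refractory_until) next
    if (vnorm(s$pos - pose$position) <= s$radius) {
      entry <- outcomes[[s$outcome_id]]
      if (is.null(entry)) stop("trigger_outcome: site references unknown outcome '", s$outcome_id, "'")
      site_state[[s$id]]$refractory_until <- step + refractory
      ev <- list(outcome_id = s$outcome_id, site_id = s$id,
                 valence = entry$valence, need_id = entry$need_id,
                 armed_by_agent = isTRUE(st$armed_by_agent))
      return(list(event = ev, site_state = site_state))
    }
  }
  list(event = NULL, site_state = site_state)
}
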