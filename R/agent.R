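#' Construct a simulation state
#'
#' Bundles everything one embodied agent needs: the arena, the outcome
#' table, essential variables, reactive behaviour systems, the adaptive- and
#' contextual-layer states, the agent pose, per-site arming state and
#' lesion flags.
#'
#' @param config resolved configuration (see [dac_default_config()]).
#' @param arena a [arena()].
#' @param outcomes an [outcome_table()].
#' @param vars list of [essential_variable()]s.
#' @param systems list of [behaviour_system()]s.
#' @param pose initial [agent_pose()].
#' @param arming named list per outcome-site id:
#'   \code{list(armed, armed_by_agent)}; defaults to contact-armed
#'   (agent presses by entering the site radius).
#' @param lesion list of flags \code{disable_cl}, \code{disable_al}.
#' @param n_channels cue channels in the percept; set explicitly when the
#'   protocol will move the agent between arenas with different cue sets,
#'   so the percept dimension stays fixed.
#' @return an object of class \code{dac_sim}.
#' @export
dac_sim <- function(config, arena, outcomes, vars, systems, pose,
                    arming = NULL, lesion = list(), n_channels = NULL) {
  f <- if (length(arena$landmarks)) length(arena$landmarks[[1]]$features) else 0L
  n_ch <- if (!is.null(n_channels)) {
    as.integer(n_channels)
  } else if (length(arena$cues)) {
    max(vapply(arena$cues, function(c) as.integer(c$channel), 0L))
  } else 0L
  m <- config$world$n_rays * f + n_ch
  site_state <- list()
  for (s in arena$outcome_sites) {
    st <- if (!is.null(arming)) arming[[s$id]] else NULL
    if (is.null(st)) st <- list(armed = TRUE, armed_by_agent = TRUE)
    st$refractory_until <- -Inf
    site_state[[s$id]] <- st
  }
  structure(list(
    config = config, arena = arena, outcomes = outcomes,
    site_state = site_state, vars = vars, systems = systems, pose = pose,
    al = al_state(config$al$K, m, config$al$alpha, config$al$eta,
                  config$al$lambda, config$al$theta_cr, config$al$eps_bar0),
    stm = stm_new(config$cl$L),
    ltm = ltm_new(m, config$cl$max_seq),
    wm = wm_new(config$cl$phi, config$cl$gamma, config$cl$rho_C),
    prev_contributors = integer(0),
    step = 0L, m = m, n_channels = n_ch,
    lesion = list(disable_cl = isTRUE(lesion$disable_cl),
                  disable_al = isTRUE(lesion$disable_al))
  ), class = "dac_sim")
}

# Bearing (relative to heading) of the conditioned stimulus, read from the
# active prototype itself: the dominant ray block of the valued prototype
# says where the stimulus sits in the body frame. NA when the prototype
# carries no landmark signal.
stimulus_bearing <- function(mu, n_rays, f) {
  if (f == 0L) return(NA_real_)
  B <- matrix(mu[seq_len(n_rays * f)], nrow = n_rays, byrow = TRUE)
  norms <- sqrt(rowSums(B^2))
  if (max(norms) < 0.05) return(NA_real_)
  wrap_angle(2 * pi * (which.max(norms) - 1L) / n_rays)
}

#' Advance the simulation by one step
#'
#' Runs the full layered control cycle: need decay and allostatic
#' modulation; reactive gradient-ascent proposals and winner-take-all;
#' adaptive perception, prototype/value learning and conditioned-response
#' shaping; sub-threshold gating of the contextual layer with four-factor
#' action selection, priming and chain learning; motor execution with
#' noise; STM acquisition; and outcome triggering with agency-gated
#' consolidation. Exactly one layer's action is executed per step.
#'
#' @param sim a [dac_sim()].
#' @param reg an [rng_registry()]; motor noise draws from stream
#'   \code{"world"}.
#' @param deliver when \code{FALSE}, outcome contact is logged as a press
#'   but nothing is delivered (extinction test): the adaptive layer takes an
#'   unreinforced (CS-alone) value step and no consolidation occurs.
#' @param consume when \code{FALSE}, a delivered outcome carries its valence
#'   (US) but does not replenish the essential variable (e.g. baseline
#'   probes under deprivation, nausea-paired meals).
#' @return \code{list(sim, rec)} where \code{rec} is the step's log record.
#' @export
dac_step <- function(sim, reg, deliver = TRUE, consume = TRUE) {
  cfg <- sim$config
  sim$step <- sim$step + 1L
  step <- sim$step

  # --- somatic: need decay, exosensing -------------------------------------
  sim$vars <- update_needs(sim$vars)
  drives <- need_drives(sim$vars)
  x <- sense_exo(sim$arena, sim$pose, cfg$world$n_rays,
                 cfg$world$sensor_range, n_channels = sim$n_channels)

  # --- adaptive: perceive, learn, value ------------------------------------
  ob <- al_observe(sim$al, x)
  sim$al <- ob$al
  v_hat <- if (sim$lesion$disable_al) 0 else ob$v_hat
  strength_al <- abs(v_hat)

  # --- reactive: allostatic modulation, SEFs, WTA --------------------------
  sim$systems <- allostatic_modulate(sim$systems, drives, cfg$rl$kappa,
                                     sim$arena)
  proposals <- lapply(sim$systems, function(bs) {
    sensed <- sample_field(sim$arena$fields[[bs$field_ref]], sim$pose$position)
    if (sensed < cfg$world$sense_floor) sensed <- 0
    propose_action_bs(bs, compute_sef(bs, sensed), sim$arena, sim$pose,
                      cfg$rl$probe_r, cfg$rl$n_probe, cfg$world$v_max,
                      cfg$world$sense_floor)
  })
  wta <- select_wta(proposals)
  rl_action <- wta$winner$action
  strength_rl <- wta$strength_rl

  # --- adaptive shaping (conditioned response) -----------------------------
  cr_fired <- FALSE
  if (sim$lesion$disable_al) {
    shaped <- list(action = rl_action, replaced = FALSE)
  } else {
    f_dim <- if (length(sim$arena$landmarks)) {
      length(sim$arena$landmarks[[1]]$features)
    } else 0L
    bearing <- stimulus_bearing(sim$al$bank$mu[ob$k, ], cfg$world$n_rays, f_dim)
    shaped <- shape_response(v_hat, bearing, rl_action, strength_rl,
                             cfg$al$theta_cr, cfg$world$v_max)
    cr_fired <- !is.na(bearing) && abs(v_hat) >= cfg$al$theta_cr
  }

  # --- contextual: gate, match, score, select ------------------------------
  executed <- shaped$action
  layer <- if (shaped$replaced) "AL" else "RL"
  contributors <- integer(0)
  cl_on <- cfg$cl$enabled && !sim$lesion$disable_cl && sim$ltm$n > 0L
  if (cl_on) {
    sim$wm <- update_priming(sim$wm, sim$prev_contributors, sim$ltm)
    if (gate_engage(strength_rl, strength_al, cfg$cl$theta_gate)) {
      # match on the encoded percept state: continuous in pose, so evidence
      # hands off smoothly between consecutive segments of a sequence
      e <- match_evidence(sim$ltm, x, cfg$cl$sigma_e)
      trace <- score_segments(sim$ltm, e, sim$wm, sim$outcomes, drives,
                              cfg$cl$c0, cfg$cl$e_min)
      sel <- select_action_cl(trace, sim$ltm, sim$pose, cfg$cl$mode,
                              cfg$cl$tau_c, cfg$world$v_max,
                              cfg$cl$lookahead, cfg$cl$tau_act, cfg$cl$c_act)
      if (!is_null_action(sel$action)) {
        executed <- sel$action
        layer <- "CL"
        contributors <- sel$contributors
        sim$wm <- learn_chain_links(sim$wm, contributors,
                                    sim$prev_contributors)
      }
    }
  }
  sim$prev_contributors <- contributors

  # --- actuation ------------------------------------------------------------
  pose_before <- sim$pose
  sim$pose <- apply_action(sim$pose, executed, cfg$world$noise_sd,
                           rng_stream(reg, "world"), sim$arena,
                           cfg$world$v_max)
  if (executed$mode == "allocentric" && any(executed$vec != 0)) {
    # body orientation follows the commanded velocity, so percepts and the
    # egocentric projections of waypoint runs stay replay-consistent
    sim$pose$heading <- atan2(executed$vec[2], executed$vec[1])
  }

  # --- STM acquisition -------------------------------------------------------
  if (!sim$lesion$disable_cl && ob$qualifies) {
    ego <- if (executed$mode == "egocentric") {
      c(executed$turn, executed$speed)
    } else {
      c(wrap_angle(atan2(executed$vec[2], executed$vec[1]) - pose_before$heading),
        min(vnorm(executed$vec), cfg$world$v_max))
    }
    seg <- make_segment(ob$k, x, executed, ego[1], ego[2], pose_before, step)
    sim$stm <- store_segment(sim$stm, seg, 0, 1) # qualification already decided
  }

  # --- outcomes ---------------------------------------------------------------
  trig <- trigger_outcome(sim$arena, sim$pose, sim$outcomes, sim$site_state,
                          step, cfg$world$refractory)
  sim$site_state <- trig$site_state
  ev <- trig$event
  press <- !is.null(ev) && isTRUE(ev$armed_by_agent)
  consumed_id <- NA_character_
  if (!is.null(ev)) {
    if (deliver) {
      if (!sim$lesion$disable_al) {
        sim$al$w <- update_value(sim$al$w, ob$k, ev$valence, TRUE)
      }
      if (consume) sim$vars <- update_needs(sim$vars, ev$outcome_id)
      consumed_id <- ev$outcome_id
      if (!sim$lesion$disable_cl &&
          check_agency(sim$stm, ev$armed_by_agent, step, cfg$cl$W)) {
        site <- Find(function(s) s$id == ev$site_id, sim$arena$outcome_sites)
        goal <- list(outcome_id = ev$outcome_id,
                     pred = x, pos = site$pos,
                     need_id = ev$need_id, valence = ev$valence)
        con <- consolidate_sequence(sim$ltm, sim$wm, sim$stm, goal)
        sim$ltm <- con$ltm
        sim$wm <- con$wm
        sim$stm <- con$stm
        sim$prev_contributors <- integer(0)
      }
    }
  }
  # classical extinction: a conditioned response emitted (or a press made)
  # without reinforcement is a CS-alone trial for the active prototype
  us_delivered <- !is.null(ev) && deliver
  if (!sim$lesion$disable_al && !us_delivered && (cr_fired || press)) {
    sim$al$w <- update_value(sim$al$w, ob$k, 0, FALSE)
  }

  rec <- list(step = step, x = sim$pose$position[1], y = sim$pose$position[2],
              heading = sim$pose$heading, layer = layer,
              bs = wta$winner$bs_id, mode = executed$mode,
              press = press, outcome = consumed_id,
              levels = vapply(sim$vars, function(v) v$level, 0))
  list(sim = sim, rec = rec)
}

#' Run a phase of consecutive steps
#'
#' @param sim a [dac_sim()].
#' @param reg an [rng_registry()].
#' @param n_steps step budget.
#' @param deliver,consume passed to [dac_step()].
#' @param stop_on_outcome end the phase as soon as an outcome is consumed.
#' @param kidnap_at,kidnap_pos optional teleport: at phase-step
#'   \code{kidnap_at} the agent is moved to \code{kidnap_pos} with a random
#'   heading (drawn from the \code{"protocol"} stream).
#' @param log keep per-step records?
#' @return \code{list(sim, log, presses, consumed, steps_used, success)}.
#' @export
run_phase <- function(sim, reg, n_steps, deliver = TRUE, consume = TRUE,
                      stop_on_outcome = FALSE, kidnap_at = NULL,
                      kidnap_pos = NULL, log = FALSE) {
  recs <- if (log) vector("list", n_steps) else NULL
  presses <- 0L
  consumed <- 0L
  steps_used <- 0L
  success <- FALSE
  for (i in seq_len(n_steps)) {
    if (!is.null(kidnap_at) && i == kidnap_at) {
      h <- stream_runif(rng_stream(reg, "protocol"), 1, -pi, pi)
      sim$pose <- structure(list(position = kidnap_pos, heading = h),
                            class = "agent_pose")
      sim$stm <- stm_new(sim$config$cl$L) # displacement breaks the episode
    }
    out <- dac_step(sim, reg, deliver = deliver, consume = consume)
    sim <- out$sim
    steps_used <- i
    if (log) recs[[i]] <- out$rec
    if (out$rec$press) presses <- presses + 1L
    if (!is.na(out$rec$outcome)) {
      consumed <- consumed + 1L
      if (stop_on_outcome) {
        success <- TRUE
        break
      }
    }
  }
  if (log) recs <- recs[seq_len(steps_used)]
  list(sim = sim, log = recs, presses = presses, consumed = consumed,
       steps_used = steps_used, success = success)
}
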