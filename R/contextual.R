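#' Sub-threshold gate for contextual-layer engagement
#'
#' The contextual layer engages only when both the reactive and the adaptive
#' layers bid below threshold for the motor plant (strict inequality), i.e.
#' when neither reflexes nor conditioned responses claim the action.
#'
#' @param strength_rl reactive winner strength, >= 0.
#' @param strength_al adaptive strength (absolute value estimate), >= 0.
#' @param theta_gate gating threshold.
#' @return logical.
#' @export
gate_engage <- function(strength_rl, strength_al, theta_gate) {
  stopifnot(strength_rl >= 0, strength_al >= 0)
  max(strength_rl, strength_al) < theta_gate
}

#' Create an empty short-term memory
#' @param L ring capacity.
#' @return an STM object.
#' @export
stm_new <- function(L = 30) {
  structure(list(segments = list(), L = as.integer(L)), class = "dac_stm")
}

# A segment couples the perceptual prediction with the motor activity of the
# step, plus the pose at acquisition (used later as a waypoint).
make_segment <- function(k, pred, act, ego_turn, ego_speed, pose, step) {
  list(k = k, pred = pred, action = act, ego_turn = ego_turn,
       ego_speed = ego_speed, pos = pose$position, heading = pose$heading,
       step = step)
}

#' Conditionally append a segment to short-term memory
#'
#' The segment is stored iff the step's reconstruction error is below the
#' current time-averaged error (the STM acquisition threshold): only
#' well-predicted sensor states enter memory. STM is a ring: when full, the
#' oldest segment is dropped.
#'
#' @param stm an [stm_new()] object.
#' @param seg a segment (internal structure).
#' @param eps the step's reconstruction error.
#' @param eps_bar the time-averaged reconstruction error.
#' @return the (possibly unchanged) STM.
#' @export
store_segment <- function(stm, seg, eps, eps_bar) {
  if (!(eps < eps_bar)) return(stm)
  stm$segments[[length(stm$segments) + 1L]] <- seg
  if (length(stm$segments) > stm$L) stm$segments <- stm$segments[-1L]
  stm
}

#' Agency check gating consolidation
#'
#' Consolidation is allowed only for behavioural sequences causally related
#' to goal achievement: the goal site must have been armed by the agent's
#' own action (not an experimenter-scheduled free delivery) and at least one
#' STM segment must have been acquired within the last \code{W} steps.
#'
#' @param stm the STM at the moment the goal event fired.
#' @param armed_by_agent did the agent's own action arm the site?
#' @param step current step index.
#' @param W agency window in steps.
#' @return logical.
#' @export
check_agency <- function(stm, armed_by_agent, step, W = 10) {
  if (!isTRUE(armed_by_agent)) return(FALSE)
  if (!length(stm$segments)) return(FALSE)
  any(vapply(stm$segments, function(s) s$step, 0) >= step - W)
}

#' Create an empty long-term memory
#' @param m percept dimension.
#' @param max_seq maximum number of retained sequences (oldest dropped).
#' @return an LTM object.
#' @export
ltm_new <- function(m, max_seq = 10) {
  structure(list(n = 0L, m = as.integer(m),
                 pred = matrix(numeric(0), 0, m),
                 k = integer(0), ego_turn = numeric(0), ego_speed = numeric(0),
                 px = numeric(0), py = numeric(0), step = integer(0),
                 seq_id = integer(0), d = integer(0),
                 wp = matrix(numeric(0), 0, 2),
                 goal_idx = integer(0), goals = list(),
                 max_seq = as.integer(max_seq)),
            class = "dac_ltm")
}

#' Create a fresh working-memory state
#' @param phi trigger decay in (0, 1).
#' @param gamma priming gain in (0, 1].
#' @param rho_C chaining learning rate in (0, 1].
#' @return a WM object.
#' @export
wm_new <- function(phi = 0.2, gamma = 0.9, rho_C = 0.1) {
  structure(list(c = numeric(0), C = matrix(numeric(0), 0, 0),
                 phi = phi, gamma = gamma, rho_C = rho_C),
            class = "dac_wm")
}

#' Consolidate the current STM into LTM
#'
#' The STM content is retained as one sequence conserving acquisition order,
#' together with the goal descriptor (outcome id, goal percept prediction,
#' goal position, need served) and the valence marker (sign of the outcome
#' valence at consolidation). Per-segment goal distances count events to the
#' goal: the final segment has distance 0. Each segment's next waypoint is
#' the stored pose of its successor (the goal position for the final
#' segment). STM is reset; WM rows are extended with zero trigger values.
#' When the sequence cap is exceeded, the oldest sequence is dropped.
#'
#' @param ltm an [ltm_new()] object.
#' @param wm a [wm_new()] object.
#' @param stm the STM to consolidate (must be non-empty).
#' @param goal list with \code{outcome_id}, \code{pred} (goal percept
#'   prediction), \code{pos}, \code{need_id}, \code{valence}.
#' @return \code{list(ltm, wm, stm)} with STM emptied.
#' @export
consolidate_sequence <- function(ltm, wm, stm, goal) {
  ns <- length(stm$segments)
  if (ns == 0L) return(list(ltm = ltm, wm = wm, stm = stm))
  gi <- length(ltm$goals) + 1L
  ltm$goals[[gi]] <- list(outcome_id = goal$outcome_id, pred = goal$pred,
                          pos = goal$pos, need_id = goal$need_id,
                          valence_sign = sign(goal$valence))
  segs <- stm$segments
  pred <- do.call(rbind, lapply(segs, function(s) s$pred))
  px <- vapply(segs, function(s) s$pos[1], 0)
  py <- vapply(segs, function(s) s$pos[2], 0)
  wp <- cbind(c(px[-1L], goal$pos[1]), c(py[-1L], goal$pos[2]))
  ltm$pred <- rbind(ltm$pred, pred)
  ltm$k <- c(ltm$k, vapply(segs, function(s) s$k, 0L))
  ltm$ego_turn <- c(ltm$ego_turn, vapply(segs, function(s) s$ego_turn, 0))
  ltm$ego_speed <- c(ltm$ego_speed, vapply(segs, function(s) s$ego_speed, 0))
  ltm$px <- c(ltm$px, px)
  ltm$py <- c(ltm$py, py)
  ltm$step <- c(ltm$step, vapply(segs, function(s) as.integer(s$step), 0L))
  ltm$seq_id <- c(ltm$seq_id, rep(gi, ns))
  ltm$d <- c(ltm$d, rev(seq_len(ns)) - 1L)
  ltm$wp <- rbind(ltm$wp, wp)
  ltm$goal_idx <- c(ltm$goal_idx, rep(gi, ns))
  ltm$n <- ltm$n + ns
  wm$c <- c(wm$c, numeric(ns))
  C <- matrix(0, ltm$n, ltm$n)
  if (nrow(wm$C)) C[seq_len(nrow(wm$C)), seq_len(ncol(wm$C))] <- wm$C
  wm$C <- C
  # enforce the sequence cap
  nseq <- length(unique(ltm$seq_id))
  if (nseq > ltm$max_seq) {
    drop_seq <- sort(unique(ltm$seq_id))[seq_len(nseq - ltm$max_seq)]
    keep <- !(ltm$seq_id %in% drop_seq)
    ltm$pred <- ltm$pred[keep, , drop = FALSE]
    for (f in c("k", "ego_turn", "ego_speed", "px", "py", "step",
                "seq_id", "d", "goal_idx")) {
      ltm[[f]] <- ltm[[f]][keep]
    }
    ltm$wp <- ltm$wp[keep, , drop = FALSE]
    ltm$n <- sum(keep)
    wm$c <- wm$c[keep]
    wm$C <- wm$C[keep, keep, drop = FALSE]
  }
  stm$segments <- list()
  list(ltm = ltm, wm = wm, stm = stm)
}

#' Keep only the most recent sequences in LTM
#'
#' Prunes LTM (and the matching working-memory state) to the last
#' \code{keep} consolidated sequences. Used by replay benchmarks that probe
#' reuse of the final behavioural plan.
#'
#' @param ltm the LTM.
#' @param wm the WM.
#' @param keep number of most recent sequences to retain.
#' @return \code{list(ltm, wm)}.
#' @export
ltm_keep_recent <- function(ltm, wm, keep = 1L) {
  ids <- unique(ltm$seq_id)
  if (length(ids) <= keep) return(list(ltm = ltm, wm = wm))
  keep_ids <- ids[(length(ids) - keep + 1L):length(ids)]
  mask <- ltm$seq_id %in% keep_ids
  ltm$pred <- ltm$pred[mask, , drop = FALSE]
  for (f in c("k", "ego_turn", "ego_speed", "px", "py", "step",
              "seq_id", "d", "goal_idx")) {
    ltm[[f]] <- ltm[[f]][mask]
  }
  ltm$wp <- ltm$wp[mask, , drop = FALSE]
  ltm$n <- sum(mask)
  wm$c <- wm$c[mask]
  wm$C <- wm$C[mask, mask, drop = FALSE]
  list(ltm = ltm, wm = wm)
}

#' Match the current perceptual prediction against LTM
#'
#' Evidence for segment i is a Gaussian similarity between the adaptive
#' layer's current prediction and the segment's stored prediction:
#' \eqn{e_i = \exp(-\|x - p_i\|^2 / (2\sigma_e^2))}.
#'
#' @param ltm the LTM.
#' @param prediction current perceptual prediction vector.
#' @param sigma_e evidence bandwidth, > 0.
#' @return numeric vector of evidences in (0, 1], length \code{ltm$n}.
#' @export
match_evidence <- function(ltm, prediction, sigma_e) {
  stopifnot(sigma_e > 0)
  if (ltm$n == 0L) return(numeric(0))
  d2 <- rowSums((ltm$pred - rep(prediction, each = ltm$n))^2)
  exp(-d2 / (2 * sigma_e^2))
}

#' Working-memory priming update
#'
#' All trigger values decay by \code{1 - phi}; then each contributor of the
#' previous step primes (a) its within-sequence successor with gain
#' \code{gamma} and (b) every segment it has a learned chain link to, with
#' gain \code{gamma * C[j, i]}. Priming takes the maximum with the decayed
#' value, so trigger values stay in [0, 1].
#'
#' @param wm the WM.
#' @param prev_contributors integer indices of last step's contributors.
#' @param ltm the LTM (for sequence structure).
#' @return the updated WM.
#' @export
update_priming <- function(wm, prev_contributors, ltm) {
  if (!length(wm$c)) return(wm)
  wm$c <- (1 - wm$phi) * wm$c
  for (j in prev_contributors) {
    if (j < ltm$n && ltm$d[j] > 0L && ltm$seq_id[j + 1L] == ltm$seq_id[j]) {
      wm$c[j + 1L] <- max(wm$c[j + 1L], wm$gamma)
    }
    wm$c <- pmax(wm$c, wm$gamma * wm$C[j, ])
  }
  wm
}

#' Learn cross-segment chaining links
#'
#' Segments active at successive decisions become associated:
#' \code{C[j, i] <- C[j, i] + rho_C * (1 - C[j, i])} for every previous
#' contributor j and current contributor i (j != i). Links saturate at 1.
#'
#' @param wm the WM.
#' @param contributors_t current contributors.
#' @param contributors_prev previous contributors.
#' @return the updated WM.
#' @export
learn_chain_links <- function(wm, contributors_t, contributors_prev) {
  for (j in contributors_prev) {
    for (i in contributors_t) {
      if (i != j) wm$C[j, i] <- wm$C[j, i] + wm$rho_C * (1 - wm$C[j, i])
    }
  }
  wm
}

#' Re-evaluate a goal at decision time
#'
#' The expected value of a goal is its outcome's current table valence
#' scaled by (1 + drive of the need it serves). Reading the table at
#' decision time — rather than using the valence frozen at consolidation —
#' is what makes the contextual layer devaluation-sensitive without
#' re-learning.
#'
#' @param outcomes an [outcome_table()].
#' @param drives named drive vector.
#' @param goal a goal descriptor (from LTM).
#' @return signed scalar value.
#' @export
reevaluate_goal <- function(outcomes, drives, goal) {
  entry <- outcomes[[goal$outcome_id]]
  if (is.null(entry)) stop("reevaluate_goal: unknown outcome '", goal$outcome_id, "'")
  d <- drives[[goal$need_id]]
  if (is.null(d) || is.na(d)) d <- 0
  entry$valence * (1 + d)
}

#' Four-factor segment scoring
#'
#' Each LTM segment is weighted by the product of its four factors:
#' perceptual evidence \code{e_i}, memory chaining \code{(c_i + c0)}, goal
#' fidelity \code{1 / (1 + d_i)} and the re-evaluated goal value. Segments of
#' sequences whose goal value is positive receive appetitive weights
#' \code{w_i}; segments of negatively valued (devalued/aversive) sequences
#' receive repulsive weights \code{r_i} of the same magnitude, flagged
#' aversive. A goal value of exactly zero nullifies the whole sequence.
#'
#' @param ltm the LTM.
#' @param e evidence vector from [match_evidence()].
#' @param wm the WM.
#' @param outcomes an [outcome_table()].
#' @param drives named drive vector.
#' @param c0 baseline chaining term (lets evidence act without priming).
#' @param e_min evidence floor: segments matching worse than this
#'   contribute nothing, so the layer abstains when nothing in LTM matches
#'   the current prediction (e.g. right after a kidnap).
#' @return a decision trace: \code{list(e, chain, dist, v, w, r)}.
#' @export
score_segments <- function(ltm, e, wm, outcomes, drives, c0 = 0.2,
                           e_min = 0) {
  if (ltm$n == 0L) {
    z <- numeric(0)
    return(list(e = z, c = z, chain = z, dist = z, v = z, w = z, r = z))
  }
  vg <- vapply(ltm$goals, function(g) reevaluate_goal(outcomes, drives, g), 0)
  v <- vg[ltm$goal_idx]
  chain <- wm$c + c0
  dist <- 1 / (1 + ltm$d)
  base <- e * chain * dist
  base[e < e_min] <- 0
  list(e = e, c = wm$c, chain = chain, dist = dist, v = v,
       w = base * pmax(0, v), r = base * abs(pmin(0, v)))
}

#' Contextual-layer action selection (weighted sum over segments)
#'
#' Active segments are triggered by perceptual evidence or working-memory
#' priming: segments matching at least \code{tau_act} times the best
#' current match compete, as do recently primed segments (trigger value at
#' least \code{c_act}) whose evidence clears the floor.
#' Among the active set, contributors are the segments scoring at least
#' \code{tau_c} times the maximum four-factor score (appetitive and
#' aversive pooled) — so goal distance and value arbitrate between
#' concurrently active sequences rather than overriding perception.
#' In allocentric mode the
#' action is a movement vector: the score-weighted sum of displacement
#' vectors from the agent's position to each contributor's next waypoint,
#' with aversive contributions negated, normalized and scaled to
#' \code{v_max}. In egocentric mode it is the score-weighted circular mean
#' of the contributors' stored egocentric actions (aversive turns reversed).
#' If all scores are zero, or contributions cancel, the layer abstains and
#' returns the null action.
#'
#' @param trace a [score_segments()] trace.
#' @param ltm the LTM.
#' @param pose current agent pose.
#' @param mode \code{"allocentric"} or \code{"egocentric"}.
#' @param tau_c contributor threshold as a fraction of the max score.
#' @param v_max speed ceiling.
#' @param lookahead in allocentric mode, a contributor's waypoint is the
#'   first stored pose along its sequence farther than this from the agent
#'   (pure-pursuit targeting), so dense waypoint chains are followed
#'   without overshoot ping-pong; 0 restores the immediate successor.
#' @param tau_act evidence-activation threshold as a fraction of the best
#'   match.
#' @param c_act priming-activation threshold on the trigger value.
#' @return \code{list(action, contributors)}.
#' @export
select_action_cl <- function(trace, ltm, pose, mode = "allocentric",
                             tau_c = 0.5, v_max = 0.5, lookahead = 0,
                             tau_act = 0.9, c_act = 0.5) {
  score <- trace$w + trace$r
  if (!length(score) || max(score) <= 0) {
    return(list(action = null_action(), contributors = integer(0)))
  }
  active <- (trace$e >= tau_act * max(trace$e) | trace$c >= c_act) & score > 0
  if (!any(active)) {
    return(list(action = null_action(), contributors = integer(0)))
  }
  contrib <- which(active & score >= tau_c * max(score[active]))
  s <- score[contrib]
  aversive <- trace$r[contrib] > 0
  if (mode == "allocentric") {
    wp <- vapply(contrib, function(i) next_waypoint(ltm, i, pose, lookahead),
                 c(0, 0))
    dx <- wp[1, ] - pose$position[1]
    dy <- wp[2, ] - pose$position[2]
    sgn <- ifelse(aversive, -1, 1)
    vec <- c(sum(s * sgn * dx), sum(s * sgn * dy))
    nv <- vnorm(vec)
    if (nv < 1e-9) return(list(action = null_action(), contributors = contrib))
    list(action = action("allocentric", vec = vec * (v_max / nv)),
         contributors = contrib)
  } else {
    turns <- ltm$ego_turn[contrib] + ifelse(aversive, pi, 0)
    sx <- sum(s * cos(turns))
    sy <- sum(s * sin(turns))
    if (sqrt(sx^2 + sy^2) < 1e-9) {
      return(list(action = null_action(), contributors = contrib))
    }
    speed <- min(sum(s * ltm$ego_speed[contrib]) / sum(s), v_max)
    if (speed <= 0) return(list(action = null_action(), contributors = contrib))
    list(action = action("egocentric", turn = wrap_angle(atan2(sy, sx)),
                         speed = speed),
         contributors = contrib)
  }
}

# Pure-pursuit waypoint for segment i: starting from the remaining-path
# pose closest to the agent (so a lagging evidence match cannot select a
# point behind the agent), the first pose farther than `lookahead`; the
# goal position when every remaining pose is within reach.
next_waypoint <- function(ltm, i, pose, lookahead = 0) {
  sq <- ltm$seq_id[i]
  gpos <- ltm$goals[[ltm$goal_idx[i]]]$pos
  jmax <- i
  while (jmax < ltm$n && ltm$seq_id[jmax + 1L] == sq) jmax <- jmax + 1L
  if (i == jmax) return(gpos)
  js <- (i + 1L):jmax
  d <- sqrt((ltm$px[js] - pose$position[1])^2 +
            (ltm$py[js] - pose$position[2])^2)
  for (idx in which.min(d):length(js)) {
    if (d[idx] > lookahead) return(c(ltm$px[js[idx]], ltm$py[js[idx]]))
  }
  gpos
}

#' Decision trace as a data frame
#'
#' One row per LTM segment with the four factor values, the combined
#' weights and the contributor flag — the auditable record of a
#' contextual-layer decision.
#'
#' @param trace a [score_segments()] trace.
#' @param ltm the LTM.
#' @param contributors contributor indices from [select_action_cl()].
#' @return a data.frame.
#' @export
trace_to_df <- function(trace, ltm, contributors = integer(0)) {
  if (ltm$n == 0L) {
    return(data.frame(segment = integer(0), seq_id = integer(0),
                      d = integer(0), evidence = numeric(0),
                      chain = numeric(0), dist = numeric(0),
                      value = numeric(0), weight = numeric(0),
                      repulsion = numeric(0), contributor = logical(0)))
  }
  data.frame(segment = seq_len(ltm$n), seq_id = ltm$seq_id, d = ltm$d,
             evidence = trace$e, chain = trace$chain, dist = trace$dist,
             value = trace$v, weight = trace$w, repulsion = trace$r,
             contributor = seq_len(ltm$n) %in% contributors)
}
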