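#' Construct a behaviour system
#'
#' A behaviour system (BS) is a homeostatic sensorimotor loop of the reactive
#' layer: it senses one affordance field and acts to bring the sensed value
#' to its desired value (its self-essential function, SEF). The allostatic
#' controller moves the desired value with the drive of the need the BS
#' serves.
#'
#' @param bs_id character id.
#' @param field_ref id of the affordance field the BS senses.
#' @param need_id name of the essential variable served.
#' @param baseline_desired desired field value at zero drive.
#' @param gain SEF-to-strength gain, >= 0.
#' @param rank priority rank for winner-take-all tie-breaking (lower wins).
#' @return an object of class \code{behaviour_system}.
#' @export
behaviour_system <- function(bs_id, field_ref, need_id, baseline_desired,
                             gain = 1, rank = 1L) {
  stopifnot(gain >= 0)
  structure(list(bs_id = bs_id, field_ref = field_ref, need_id = need_id,
                 baseline_desired = baseline_desired,
                 desired_value = baseline_desired, gain = gain,
                 rank = as.integer(rank)),
            class = "behaviour_system")
}

#' Self-essential function reading
#'
#' The SEF is the signed discrepancy between the desired and the sensed
#' value of the BS's affordance gradient; its absolute size, scaled by the
#' gain, is the strength with which the BS bids for the motor plant.
#'
#' @param bs a [behaviour_system()].
#' @param sensed sensed field value at the agent's position.
#' @return \code{list(bs_id, sensed, desired, sef, strength)}.
#' @export
compute_sef <- function(bs, sensed) {
  sef <- bs$desired_value - sensed
  list(bs_id = bs$bs_id, sensed = sensed, desired = bs$desired_value,
       sef = sef, strength = bs$gain * abs(sef))
}

#' Gradient-ascent action proposal of one behaviour system
#'
#' The BS probes its field at \code{n_probe} headings (relative to the
#' agent's heading) at distance \code{probe_r} and turns toward the probe
#' that best reduces its SEF: the maximum sampled value when sensed is below
#' desired, the minimum when above. Probe positions outside the arena are
#' clamped to the bounds before sampling, and probe values below the
#' detection floor read as 0 (out-of-range gradients are not climbable).
#' Ties go to the lowest heading index. Speed is
#' \code{v_max * min(1, |sef|)}; a satisfied BS (sef = 0) proposes the
#' null action with zero strength.
#'
#' @param bs a [behaviour_system()].
#' @param reading the [compute_sef()] reading for this step.
#' @param arena the arena.
#' @param pose the agent pose.
#' @param probe_r probe distance, > 0.
#' @param n_probe number of probe headings, >= 3.
#' @param v_max speed ceiling.
#' @param sense_floor detection floor applied to probe samples.
#' @return \code{list(bs_id, action, strength, rank)}.
#' @export
propose_action_bs <- function(bs, reading, arena, pose, probe_r = 0.5,
                              n_probe = 8, v_max = 0.5, sense_floor = 0) {
  stopifnot(n_probe >= 3, probe_r > 0)
  if (reading$sef == 0) {
    return(list(bs_id = bs$bs_id, action = null_action(), strength = 0,
                rank = bs$rank))
  }
  field <- arena$fields[[bs$field_ref]]
  rel <- 2 * pi * (seq_len(n_probe) - 1L) / n_probe
  h <- pose$heading + rel
  P <- cbind(pmin(pmax(pose$position[1] + probe_r * cos(h), 0), arena$width),
             pmin(pmax(pose$position[2] + probe_r * sin(h), 0), arena$height))
  v <- sample_field_many(field, P)
  v[v < sense_floor] <- 0
  j <- if (reading$sef > 0) which.max(v) else which.min(v)
  act <- action("egocentric", turn = wrap_angle(rel[j]),
                speed = v_max * min(1, abs(reading$sef)))
  list(bs_id = bs$bs_id, action = act, strength = reading$strength,
       rank = bs$rank)
}

#' Allostatic modulation of behaviour systems
#'
#' The allostatic controller prioritizes BSs by need: each BS's desired
#' value is set to its baseline plus \code{kappa} times the drive of the need
#' it serves, clipped to the attainable maximum of its field. Gains are left
#' unchanged under the default policy.
#'
#' @param systems list of [behaviour_system()]s.
#' @param drives named drive vector from [need_drives()].
#' @param kappa drive-to-desired coupling, >= 0.
#' @param arena the arena (for field caps).
#' @return modulated copies of the systems.
#' @export
allostatic_modulate <- function(systems, drives, kappa, arena) {
  lapply(systems, function(bs) {
    d <- drives[[bs$need_id]]
    if (is.null(d) || is.na(d)) d <- 0
    cap <- field_cap(arena$fields[[bs$field_ref]])
    bs$desired_value <- min(bs$baseline_desired + kappa * d, cap)
    bs
  })
}

#' Strict winner-take-all selection across proposals
#'
#' Returns the proposal with maximal strength; ties are broken by lowest
#' priority rank, then by position in the list. The winner's strength is
#' exported as the reactive layer's contribution to contextual-layer gating.
#'
#' @param proposals non-empty list of proposals from [propose_action_bs()].
#' @return \code{list(winner, strength_rl)}.
#' @export
select_wta <- function(proposals) {
  if (!length(proposals)) stop("select_wta: empty proposal list")
  s <- vapply(proposals, function(p) p$strength, 0)
  r <- vapply(proposals, function(p) as.integer(p$rank), 0L)
  best <- which(s == max(s))
  if (length(best) > 1L) best <- best[order(r[best], best)][1L] else best <- best[1L]
  list(winner = proposals[[best]], strength_rl = s[best])
}
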