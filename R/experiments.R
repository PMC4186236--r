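#' Classical-conditioning protocol (acquisition then extinction)
#'
#' A stationary agent receives \code{n_acq} paired CS-US trials followed by
#' \code{n_ext} CS-alone trials. The CS percept is fixed, so it maps to one
#' prototype and the logged value follows the single-stimulus delta-rule
#' closed form \eqn{u_N = US (1 - (1-\eta)^N)} during acquisition and
#' geometric extinction afterwards. A conditioned response is emitted on a
#' trial when the post-trial value magnitude reaches \code{theta_cr}.
#'
#' @param n_acq,n_ext numbers of acquisition and extinction trials.
#' @param us_valence US magnitude.
#' @param config resolved configuration (uses \code{al.*}).
#' @param cs fixed CS percept vector.
#' @return list with \code{curve} (per-trial data.frame), \code{u_acq}
#'   (value after acquisition), \code{u_final}, and \code{first_cr_trial}.
#' @export
run_conditioning <- function(n_acq = 50, n_ext = 50, us_valence = 1,
                             config = dac_default_config(),
                             cs = c(1, 0, 0, 1)) {
  al <- al_state(config$al$K, length(cs), config$al$alpha, config$al$eta,
                 config$al$lambda, config$al$theta_cr, config$al$eps_bar0)
  n <- n_acq + n_ext
  u <- numeric(n)
  cr <- logical(n)
  for (t in seq_len(n)) {
    ob <- al_observe(al, cs)
    al <- ob$al
    al$w <- update_value(al$w, ob$k, us_valence, us_present = t <= n_acq)
    u[t] <- al$w$u[ob$k]
    cr[t] <- abs(u[t]) >= config$al$theta_cr
  }
  curve <- data.frame(trial = seq_len(n),
                      phase = rep(c("acquisition", "extinction"),
                                  c(n_acq, n_ext)),
                      u = u, cr = cr)
  list(curve = curve, u_acq = u[n_acq], u_final = u[n],
       first_cr_trial = if (any(cr)) which(cr)[1] else NA_integer_)
}

# Shared scaffolding: a foraging-style agent on a fixture arena.
new_forager <- function(config, fx, lesion = list(), n_channels = NULL) {
  nd <- config$needs$hunger
  vars <- list(essential_variable("hunger", level = nd$level0,
                                  set_point = nd$set_point,
                                  decay_rate = nd$decay,
                                  replenish = c(food = nd$replenish_food)))
  systems <- list(behaviour_system("forage", "food_odor", "hunger",
                                   baseline_desired = 0.5,
                                   gain = config$rl$gain, rank = 1L))
  outs <- outcome_table(food = list(valence = 1, need_id = "hunger"))
  dac_sim(config, fx$arena, outs, vars, systems, fx$start, lesion = lesion,
          n_channels = n_channels)
}

# Replace the arena mid-protocol (context switch), keeping the learned
# layers. Percept dimension must be preserved (see dac_sim n_channels).
swap_arena <- function(sim, arena, pose, arming = NULL) {
  sim$arena <- arena
  sim$pose <- pose
  site_state <- list()
  for (s in arena$outcome_sites) {
    st <- if (!is.null(arming)) arming[[s$id]] else NULL
    if (is.null(st)) st <- list(armed = TRUE, armed_by_agent = TRUE)
    st$refractory_until <- -Inf
    site_state[[s$id]] <- st
  }
  sim$site_state <- site_state
  sim
}

# The nausea-pairing context: a featureless small box, no lever, no odour
# gradient, a distinct context landmark/cue, and a scheduled (free,
# experimenter-armed) delivery site covering the whole box.
deval_context_arena <- function() {
  arena(6, 6,
    landmarks = list(list(id = "context_lm", pos = c(3, 3),
                          features = c(0, 0, 1))),
    cues = list(list(id = "context_deval", pos = c(3, 3), radius = 20,
                     channel = 2L)),
    outcome_sites = list(list(id = "free_food", pos = c(3, 3),
                              outcome_id = "food", radius = 10)),
    fields = list(food_odor = affordance_field("food_odor", list())))
}

#' Outcome-devaluation protocol (goal-directed vs habitual control)
#'
#' Per seed and per variant (intact, contextual layer disabled) the agent
#' is (1) trained in a lever box where entering the lever radius presses
#' and delivers food; (2) probed for a baseline press rate under
#' deprivation; (3) devalued: the food's table valence is set to -1 and
#' food is paired with the negative US in a separate context (no lever);
#' (4) tested in extinction: lever present, presses logged, nothing
#' delivered. The dissociation signature is a large intact drop from
#' baseline and a near-zero lesioned drop.
#'
#' @param n_seeds number of replicate seeds.
#' @param base_seed first master seed; seed i uses \code{base_seed + i - 1}.
#' @param config resolved configuration.
#' @param steps_train,steps_base,steps_deval,steps_test phase budgets.
#' @return list with \code{metrics} (per seed x variant data.frame) and
#'   \code{summary} (mean drops and per-seed dissociation count).
#' @export
run_devaluation <- function(n_seeds = 20, base_seed = 1,
                            config = dac_default_config(),
                            steps_train = 700, steps_base = 300,
                            steps_deval = 40, steps_test = 300) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    master <- base_seed + i - 1L
    fx <- generate_arena_fixture("lever_box", master)
    ctx <- deval_context_arena()
    for (variant in c("intact", "lesion_cl")) {
      lesion <- if (variant == "lesion_cl") list(disable_cl = TRUE) else list()
      reg <- rng_registry(master)
      # lever-box context is cue channel 1, nausea context channel 2
      sim <- new_forager(config, fx, lesion, n_channels = 2L)
      sim <- run_phase(sim, reg, steps_train)$sim
      sim$pose <- fx$start
      base <- run_phase(sim, reg, steps_base, consume = FALSE)
      sim <- base$sim
      u_before <- if (length(sim$al$w$u)) max(sim$al$w$u) else 0
      k_lever <- if (length(sim$al$w$u)) which.max(sim$al$w$u) else NA_integer_
      # devaluation: table edit + aversive pairing away from the lever
      sim$outcomes <- devalue_outcome(sim$outcomes, "food", -1)
      lever_arena <- sim$arena
      sim <- swap_arena(sim, ctx, agent_pose(3, 3, 0),
                        arming = list(free_food = list(armed = TRUE,
                                                       armed_by_agent = FALSE)))
      sim <- run_phase(sim, reg, steps_deval, consume = FALSE)$sim
      u_after <- if (!is.na(k_lever)) sim$al$w$u[k_lever] else 0
      sim <- swap_arena(sim, lever_arena, fx$start)
      test <- run_phase(sim, reg, steps_test, deliver = FALSE)
      base_rate <- base$presses / steps_base
      test_rate <- test$presses / steps_test
      drop <- if (base_rate > 0) (base_rate - test_rate) / base_rate else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        seed = master, variant = variant, phase = "devaluation",
        base_rate = base_rate, test_rate = test_rate, drop = drop,
        u_lever_pre = u_before, u_lever_post_deval = u_after)
    }
  }
  metrics <- do.call(rbind, rows)
  di <- metrics[metrics$variant == "intact", ]
  dl <- metrics[metrics$variant == "lesion_cl", ]
  summary <- list(
    intact_drop_mean = mean(di$drop, na.rm = TRUE),
    lesion_drop_mean = mean(dl$drop, na.rm = TRUE),
    dissociation_count = sum(di$drop > dl$drop, na.rm = TRUE),
    n_seeds = n_seeds)
  list(metrics = metrics, summary = summary)
}

#' Foraging with kidnap recovery
#'
#' Per seed, intact and contextual-layer-lesioned agents are trained to
#' forage from a home position to odour-marked food sites inside a landmark
#' ring. In test trials the agent is teleported mid-trial to a random
#' previously visited location (the same locations for both variants) and
#' recovery — still reaching food within the budget — is logged.
#'
#' @param n_seeds replicate seeds.
#' @param base_seed first master seed.
#' @param config resolved configuration.
#' @param n_train training trials per agent.
#' @param n_kidnap kidnap test trials per agent.
#' @param trial_steps training trial budget.
#' @param test_steps test trial budget.
#' @param kidnap_at phase step of the teleport.
#' @return list with \code{metrics} and \code{summary} (recovery rates).
#' @export
run_foraging_kidnap <- function(n_seeds = 20, base_seed = 1,
                                config = NULL, n_train = 6, n_kidnap = 4,
                                trial_steps = 300, test_steps = 80,
                                kidnap_at = 20) {
  if (is.null(config)) {
    config <- dac_default_config()
    config$world$sensor_range <- 25 # the landmark ring is visible throughout
  }
  rows <- list()
  for (i in seq_len(n_seeds)) {
    master <- base_seed + i - 1L
    fx <- generate_arena_fixture("foraging", master)
    visited <- NULL
    kidnap_pos <- NULL
    for (variant in c("intact", "lesion_cl")) {
      lesion <- if (variant == "lesion_cl") list(disable_cl = TRUE) else list()
      reg <- rng_registry(master)
      sim <- new_forager(config, fx, lesion)
      for (tr in seq_len(n_train)) {
        sim$pose <- fx$start
        ph <- run_phase(sim, reg, trial_steps, stop_on_outcome = TRUE,
                        log = variant == "intact")
        sim <- ph$sim
        if (variant == "intact" && !is.null(ph$log)) {
          xy <- cbind(vapply(ph$log, `[[`, 0, "x"),
                      vapply(ph$log, `[[`, 0, "y"))
          visited <- rbind(visited, xy)
        }
      }
      if (is.null(kidnap_pos)) {
        ks <- rng_stream(rng_registry(master), "kidnap")
        idx <- floor(stream_runif(ks, n_kidnap, 1, nrow(visited) + 1))
        kidnap_pos <- lapply(idx, function(j) as.numeric(visited[j, ]))
      }
      rec <- 0L
      for (tr in seq_len(n_kidnap)) {
        sim$pose <- fx$start
        ph <- run_phase(sim, reg, test_steps, stop_on_outcome = TRUE,
                        kidnap_at = kidnap_at, kidnap_pos = kidnap_pos[[tr]])
        sim <- ph$sim
        if (ph$success && ph$steps_used > kidnap_at) rec <- rec + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seed = master, variant = variant, phase = "kidnap",
        recovered = rec, trials = n_kidnap,
        recovery_rate = rec / n_kidnap)
    }
  }
  metrics <- do.call(rbind, rows)
  agg <- function(v) {
    m <- metrics[metrics$variant == v, ]
    sum(m$recovered) / sum(m$trials)
  }
  list(metrics = metrics,
       summary = list(recovery_intact = agg("intact"),
                      recovery_lesion = agg("lesion_cl"),
                      n_seeds = n_seeds))
}

#' Egocentric vs allocentric robustness under motor noise
#'
#' Per seed an agent is trained on the corridor maze (a route-learning
#' benchmark: shaping starts along the corridor, a final noise-free trial
#' from the test start consolidating one canonical route). The trained
#' state is then replayed in independent test trials for each combination
#' of contextual-layer action encoding (egocentric, allocentric) and motor
#' noise level, from the far start with a budget that requires following
#' the route. Success rates and trajectory dispersion (the behavioural
#' entropy proxy) are logged; the same noise draws are used for both
#' encodings at each (noise, trial) cell.
#'
#' @param n_seeds replicate seeds.
#' @param base_seed first master seed.
#' @param noise_grid motor noise standard deviations.
#' @param n_test test trials per cell.
#' @param config resolved configuration.
#' @param n_train training trials.
#' @param trial_steps training trial budget.
#' @param test_steps test trial budget (short relative to random search, so
#'   success requires directed navigation).
#' @return list with \code{metrics}, \code{success} (mode x noise rates)
#'   and \code{dispersion} (mode x noise mean dispersion).
#' @export
run_entropy_benchmark <- function(n_seeds = 20, base_seed = 1,
                                  noise_grid = c(0, 0.1, 0.2, 0.4),
                                  n_test = 4, config = NULL, n_train = 12,
                                  trial_steps = 350, test_steps = 100) {
  if (is.null(config)) config <- dac_default_config()
  modes <- c("egocentric", "allocentric")
  rows <- list()
  for (i in seq_len(n_seeds)) {
    master <- base_seed + i - 1L
    fx <- generate_arena_fixture("corridor_maze", master)
    reg <- rng_registry(master)
    sim0 <- new_forager(config, fx)
    # backward shaping: starts recede from the goal so sequence coverage
    # grows backward along the route; the final trial is noise-free from
    # the test start, consolidating one canonical full route
    starts <- seq(14, 1, length.out = n_train - 2L)
    for (tr in seq_len(n_train)) {
      if (tr >= n_train - 1L) {
        # two noise-free trials from the test start: the first makes the
        # start region perceptually familiar, so the second consolidates a
        # canonical route whose first segment shares the test entry pose
        sim0$config$world$noise_sd <- 0
        sim0$pose <- fx$start
      } else {
        sim0$config$world$noise_sd <- config$world$noise_sd
        # shaping placements use the lower corridor lane, clear of the
        # pocket capture basins
        sim0$pose <- agent_pose(starts[tr], 1.5, 0)
      }
      sim0 <- run_phase(sim0, reg, trial_steps, stop_on_outcome = TRUE)$sim
    }
    sim0$config$world$noise_sd <- config$world$noise_sd
    # the benchmark probes reuse of the final behavioural plan: replay
    # works from the canonical route, not a mixture of training excursions
    pr <- ltm_keep_recent(sim0$ltm, sim0$wm, 1L)
    sim0$ltm <- pr$ltm
    sim0$wm <- pr$wm
    sim0$prev_contributors <- integer(0)
    for (mode in modes) {
      for (ns in noise_grid) {
        trajs <- list()
        succ <- 0L
        for (t in seq_len(n_test)) {
          sim <- sim0
          sim$config$cl$mode <- mode
          sim$config$world$noise_sd <- ns
          sim$pose <- fx$start
          sim$stm <- stm_new(config$cl$L)
          sim$prev_contributors <- integer(0)
          # identical draws across modes within a (noise, trial) cell
          reg_t <- rng_registry(stream_seed(master, paste0("t", t, "n", ns)))
          ph <- run_phase(sim, reg_t, test_steps, stop_on_outcome = TRUE,
                          log = TRUE)
          if (ph$success) succ <- succ + 1L
          trajs[[t]] <- cbind(vapply(ph$log, `[[`, 0, "x"),
                              vapply(ph$log, `[[`, 0, "y"))
        }
        disp <- if (n_test >= 2) compute_dispersion(trajs, 20) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          seed = master, variant = mode, phase = paste0("noise_", ns),
          noise = ns, success_rate = succ / n_test, dispersion = disp)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  agg <- function(col) {
    out <- matrix(NA_real_, length(modes), length(noise_grid),
                  dimnames = list(modes, paste0("noise_", noise_grid)))
    for (mo in modes) for (j in seq_along(noise_grid)) {
      sel <- metrics$variant == mo & metrics$noise == noise_grid[j]
      out[mo, j] <- mean(metrics[[col]][sel])
    }
    out
  }
  list(metrics = metrics, success = agg("success_rate"),
       dispersion = agg("dispersion"))
}

#' Maze navigation with distracters
#'
#' A corridor maze whose goal field has distracter local maxima inside
#' pocket alcoves (plus goal-like distracter landmarks). Purely reactive
#' (contextual-layer-lesioned) agents following the affordance gradient get
#' trapped in the pockets; intact agents bypass them using consolidated
#' sequences. Training trials start from randomized positions along the
#' corridor (shaping); test trials start at the far end.
#'
#' @param n_seeds replicate seeds.
#' @param base_seed first master seed.
#' @param config resolved configuration.
#' @param n_train,n_test trial counts.
#' @param trial_steps per-trial budget.
#' @param n_distracters distracter pockets (0 for the open corridor).
#' @return list with \code{metrics} and \code{summary}.
#' @export
run_maze_distracters <- function(n_seeds = 5, base_seed = 1, config = NULL,
                                 n_train = 12, n_test = 3, trial_steps = 400,
                                 n_distracters = 2L) {
  if (is.null(config)) config <- dac_default_config()
  rows <- list()
  for (i in seq_len(n_seeds)) {
    master <- base_seed + i - 1L
    fx <- generate_arena_fixture("corridor_maze", master, n_distracters)
    for (variant in c("intact", "lesion_cl")) {
      lesion <- if (variant == "lesion_cl") list(disable_cl = TRUE) else list()
      reg <- rng_registry(master)
      sim <- new_forager(config, fx, lesion)
      # backward shaping: training starts recede from the goal
      starts <- seq(14, 1, length.out = n_train)
      for (tr in seq_len(n_train)) {
        sim$pose <- agent_pose(starts[tr], 1.5, 0)
        sim <- run_phase(sim, reg, trial_steps, stop_on_outcome = TRUE)$sim
      }
      succ <- 0L
      lens <- c()
      for (tr in seq_len(n_test)) {
        sim$pose <- fx$start
        ph <- run_phase(sim, reg, trial_steps, stop_on_outcome = TRUE)
        sim <- ph$sim
        if (ph$success) {
          succ <- succ + 1L
          lens <- c(lens, ph$steps_used)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seed = master, variant = variant, phase = "maze",
        success_rate = succ / n_test,
        median_steps = if (length(lens)) stats::median(lens) else NA_real_)
    }
  }
  metrics <- do.call(rbind, rows)
  agg <- function(v, col) mean(metrics[[col]][metrics$variant == v], na.rm = TRUE)
  list(metrics = metrics,
       summary = list(success_intact = agg("intact", "success_rate"),
                      success_lesion = agg("lesion_cl", "success_rate"),
                      steps_intact = agg("intact", "median_steps"),
                      steps_lesion = agg("lesion_cl", "median_steps")))
}

#' Trajectory dispersion at progress checkpoints
#'
#' Each trajectory is resampled to \code{n_checkpoints} points by
#' normalized path progress (arc length); the dispersion is the mean over
#' checkpoints of the mean pairwise Euclidean distance between trajectories
#' at that checkpoint. This is the behavioural-entropy proxy.
#'
#' @param trajectories list of n x 2 position matrices (>= 2).
#' @param n_checkpoints number of progress checkpoints.
#' @return scalar dispersion.
#' @export
compute_dispersion <- function(trajectories, n_checkpoints = 20) {
  if (length(trajectories) < 2) {
    stop("compute_dispersion: need at least 2 trajectories")
  }
  qs <- seq(0, 1, length.out = n_checkpoints)
  R <- lapply(trajectories, function(tr) {
    tr <- as.matrix(tr)
    if (nrow(tr) == 1L) {
      return(matrix(rep(tr[1, ], n_checkpoints), ncol = 2, byrow = TRUE))
    }
    seglen <- sqrt(diff(tr[, 1])^2 + diff(tr[, 2])^2)
    s <- c(0, cumsum(seglen))
    if (s[length(s)] == 0) {
      return(matrix(rep(tr[1, ], n_checkpoints), ncol = 2, byrow = TRUE))
    }
    s <- s / s[length(s)]
    cbind(stats::approx(s, tr[, 1], xout = qs, ties = "ordered")$y,
          stats::approx(s, tr[, 2], xout = qs, ties = "ordered")$y)
  })
  n <- length(R)
  total <- 0
  for (q in seq_len(n_checkpoints)) {
    P <- t(vapply(R, function(r) r[q, ], c(0, 0)))
    dsum <- 0
    cnt <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        dsum <- dsum + sqrt(sum((P[a, ] - P[b, ])^2))
        cnt <- cnt + 1
      }
    }
    total <- total + dsum / cnt
  }
  total / n_checkpoints
}
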