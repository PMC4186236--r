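# Independent oracles, written as plain loops against the documented
# contracts (not against the package internals).

# argmax-with-tie-rule oracle for winner-take-all selection
oracle_wta <- function(strengths, ranks) {
  best <- 1L
  for (i in seq_along(strengths)) {
    if (strengths[i] > strengths[best] ||
        (strengths[i] == strengths[best] && ranks[i] < ranks[best])) {
      best <- i
    }
  }
  best
}

# four-factor weights, one segment at a time
oracle_weights <- function(ltm, e, cvec, outcomes, drives, c0, e_min) {
  w <- numeric(ltm$n)
  r <- numeric(ltm$n)
  for (i in seq_len(ltm$n)) {
    g <- ltm$goals[[ltm$goal_idx[i]]]
    drv <- drives[[g$need_id]]
    if (is.null(drv) || is.na(drv)) drv <- 0
    v <- outcomes[[g$outcome_id]]$valence * (1 + drv)
    base <- e[i] * (cvec[i] + c0) / (1 + ltm$d[i])
    if (e[i] < e_min) base <- 0
    if (v > 0) w[i] <- base * v
    if (v < 0) r[i] <- base * (-v)
  }
  list(w = w, r = r)
}

# pure-pursuit waypoint: from the closest remaining pose of i's sequence,
# the first pose farther than `lookahead`; the goal position as fallback
oracle_waypoint <- function(ltm, i, pos, lookahead) {
  idx <- which(ltm$seq_id == ltm$seq_id[i])
  idx <- idx[idx > i]
  if (!length(idx)) return(ltm$goals[[ltm$goal_idx[i]]]$pos)
  d <- sapply(idx, function(j) sqrt((ltm$px[j] - pos[1])^2 + (ltm$py[j] - pos[2])^2))
  start <- which.min(d)
  for (k in start:length(idx)) {
    if (d[k] > lookahead) return(c(ltm$px[idx[k]], ltm$py[idx[k]]))
  }
  ltm$goals[[ltm$goal_idx[i]]]$pos
}

# full contextual-layer action recomputation per the documented rule
oracle_cl_action <- function(ltm, e, cvec, w, r, pose, mode, tau_c, v_max,
                             lookahead, tau_act, c_act) {
  score <- w + r
  if (max(score) <= 0) return(list(action = NULL, contributors = integer(0)))
  active <- which((e >= tau_act * max(e) | cvec >= c_act) & score > 0)
  if (!length(active)) return(list(action = NULL, contributors = integer(0)))
  mx <- max(score[active])
  contrib <- active[score[active] >= tau_c * mx]
  s <- score[contrib]
  if (mode == "allocentric") {
    vec <- c(0, 0)
    for (j in seq_along(contrib)) {
      i <- contrib[j]
      wp <- oracle_waypoint(ltm, i, pose$position, lookahead)
      sgn <- if (r[i] > 0) -1 else 1
      vec <- vec + s[j] * sgn * (wp - pose$position)
    }
    nv <- sqrt(sum(vec^2))
    if (nv < 1e-9) return(list(action = NULL, contributors = contrib))
    list(action = vec * v_max / nv, contributors = contrib)
  } else {
    sx <- 0; sy <- 0; sp <- 0
    for (j in seq_along(contrib)) {
      i <- contrib[j]
      turn <- ltm$ego_turn[i] + if (r[i] > 0) pi else 0
      sx <- sx + s[j] * cos(turn)
      sy <- sy + s[j] * sin(turn)
      sp <- sp + s[j] * ltm$ego_speed[i]
    }
    if (sqrt(sx^2 + sy^2) < 1e-9) return(list(action = NULL, contributors = contrib))
    speed <- min(sp / sum(s), v_max)
    if (speed <= 0) return(list(action = NULL, contributors = contrib))
    list(action = c(atan2(sy, sx), speed), contributors = contrib)
  }
}

# O(n^2) dispersion recomputation on pre-resampled checkpoint matrices
oracle_dispersion <- function(R) {
  n <- length(R)
  q <- nrow(R[[1]])
  tot <- 0
  for (cp in 1:q) {
    acc <- 0; cnt <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      acc <- acc + sqrt(sum((R[[a]][cp, ] - R[[b]][cp, ])^2))
      cnt <- cnt + 1
    }
    tot <- tot + acc / cnt
  }
  tot / q
}

# build a small random LTM (and trigger values) through the package API
random_ltm <- function(m = 4, max_segments = 10, n_goals = 2) {
  ltm <- ltm_new(m, max_seq = 10)
  wm <- wm_new()
  total <- 0L
  step <- 0L
  for (g in seq_len(n_goals)) {
    ns <- sample(1:(max_segments %/% n_goals), 1)
    if (total + ns > max_segments) ns <- max_segments - total
    if (ns < 1) break
    stm <- stm_new(30)
    for (i in seq_len(ns)) {
      step <- step + 1L
      seg <- dacsim:::make_segment(
        k = 1L, pred = runif(m), act = null_action(),
        ego_turn = runif(1, -pi, pi), ego_speed = runif(1, 0, 0.5),
        pose = agent_pose(runif(1, 0, 10), runif(1, 0, 10), runif(1, -pi, pi)),
        step = step)
      stm <- store_segment(stm, seg, 0, 1)
    }
    goal <- list(outcome_id = sample(c("food", "shock"), 1),
                 pred = runif(m), pos = runif(2, 0, 10),
                 need_id = "hunger", valence = sample(c(-1, 1), 1))
    con <- consolidate_sequence(ltm, wm, stm, goal)
    ltm <- con$ltm
    wm <- con$wm
    total <- total + ns
  }
  wm$c <- runif(length(wm$c))
  list(ltm = ltm, wm = wm)
}

test_outcomes <- function() {
  outcome_table(food = list(valence = 1, need_id = "hunger"),
                shock = list(valence = -1, need_id = "safety"))
}
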