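test_that("the sub-threshold gate uses a strict maximum rule", {
  expect_true(gate_engage(0, 0, 0.3))
  expect_false(gate_engage(0.5, 0.1, 0.3))
  expect_false(gate_engage(0.3, 0, 0.3)) # boundary: strict inequality
})

test_that("STM stores below the running-average threshold, as a ring", {
  stm <- stm_new(3)
  stm <- store_segment(stm, simple_segment(1), 0, 0.5)
  expect_length(stm$segments, 1)
  stm <- store_segment(stm, simple_segment(2), 0.6, 0.5)
  expect_length(stm$segments, 1) # rejected: error above threshold
  for (s in 3:6) stm <- store_segment(stm, simple_segment(s), 0.1, 0.5)
  expect_length(stm$segments, 3)
  expect_equal(vapply(stm$segments, function(s) s$step, 0), c(4, 5, 6))
})

test_that("the agency gate blocks free deliveries and empty memories", {
  stm <- stm_new(10)
  stm <- store_segment(stm, simple_segment(95), 0, 1)
  expect_true(check_agency(stm, TRUE, 100, W = 10))
  expect_false(check_agency(stm, FALSE, 100, W = 10)) # experimenter-scheduled
  expect_false(check_agency(stm_new(10), TRUE, 100, W = 10))
  stale <- store_segment(stm_new(10), simple_segment(50), 0, 1)
  expect_false(check_agency(stale, TRUE, 100, W = 10))
})

test_that("consolidation conserves order, assigns distances, resets STM", {
  con <- seq_to_ltm(5)
  expect_equal(con$ltm$d, c(4, 3, 2, 1, 0))
  expect_equal(con$ltm$step, 1:5)
  expect_true(all(diff(con$ltm$step) > 0))
  expect_length(con$stm$segments, 0)
  expect_length(con$wm$c, 5)
  # second episode appends in arrival order
  con2 <- seq_to_ltm(3, ltm = con$ltm, wm = con$wm)
  expect_equal(length(con2$ltm$goals), 2)
  expect_equal(con2$ltm$seq_id, c(rep(1, 5), rep(2, 3)))
  expect_equal(con2$ltm$d[6:8], c(2, 1, 0))
})

test_that("evidence matching is a Gaussian of prediction distance", {
  con <- seq_to_ltm(4)
  e <- match_evidence(con$ltm, c(2, 0, 0), sigma_e = 0.5)
  expect_equal(e[2], 1) # exact match
  e2 <- match_evidence(con$ltm, c(2 + 0.5 * sqrt(2 * log(2)), 0, 0), 0.5)
  expect_equal(e2[2], 0.5, tolerance = 1e-12)
  # monotone in distance
  set.seed(9)
  for (i in 1:30) {
    p1 <- c(2, 0, 0) + rnorm(3, 0, 0.1)
    p2 <- c(2, 0, 0) + rnorm(3, 0, 1.5)
    d1 <- sqrt(sum((p1 - c(2, 0, 0))^2))
    d2 <- sqrt(sum((p2 - c(2, 0, 0))^2))
    ee <- c(match_evidence(con$ltm, p1, 0.5)[2], match_evidence(con$ltm, p2, 0.5)[2])
    expect_equal(order(c(d1, d2)), order(-ee))
  }
})

test_that("priming decays triggers and boosts successors and linked segments", {
  con <- seq_to_ltm(5)
  wm <- con$wm
  wm$c <- rep(0.8, 5)
  wm2 <- update_priming(wm, integer(0), con$ltm)
  expect_equal(wm2$c, rep(0.8 * (1 - wm$phi), 5)) # pure decay
  wm$gamma <- 1
  wm3 <- update_priming(wm, 2L, con$ltm)
  expect_equal(wm3$c[3], 1) # successor primed to gamma
  # repeated decay drives triggers to zero
  wmz <- con$wm
  wmz$c <- rep(1, 5)
  for (i in 1:200) wmz <- update_priming(wmz, integer(0), con$ltm)
  expect_lt(max(wmz$c), 1e-6)
  # learned cross-links prime proportionally
  wmc <- con$wm
  wmc$C[1, 4] <- 0.5
  wmc <- update_priming(wmc, 1L, con$ltm)
  expect_equal(wmc$c[4], 0.9 * 0.5)
})

test_that("chain links saturate at one and ignore empty contributor sets", {
  con <- seq_to_ltm(5)
  wm <- con$wm
  wm2 <- learn_chain_links(wm, 2L, 1L)
  expect_equal(wm2$C[1, 2], 0.1)
  for (i in 1:500) wm2 <- learn_chain_links(wm2, 2L, 1L)
  expect_lte(wm2$C[1, 2], 1)
  expect_gt(wm2$C[1, 2], 0.99)
  wm3 <- learn_chain_links(wm, integer(0), integer(0))
  expect_equal(wm3$C, wm$C)
})

test_that("goal re-evaluation multiplies table valence and drive", {
  outs <- test_outcomes()
  goal <- list(outcome_id = "food", need_id = "hunger")
  expect_equal(reevaluate_goal(outs, c(hunger = 0), goal), 1)
  expect_equal(reevaluate_goal(outs, c(hunger = 1), goal), 2)
  outs2 <- devalue_outcome(outs, "food", -1)
  expect_lt(reevaluate_goal(outs2, c(hunger = 0.7), goal), 0)
  expect_error(reevaluate_goal(outs, c(hunger = 0), list(outcome_id = "x",
                                                         need_id = "hunger")),
               "unknown")
})

test_that("devaluation to zero nullifies every weight of the goal's sequences", {
  con <- seq_to_ltm(6)
  outs <- devalue_outcome(test_outcomes(), "food", 0)
  e <- rep(1, 6)
  tr <- score_segments(con$ltm, e, con$wm, outs, c(hunger = 1), 0.2, 0)
  expect_identical(tr$w, rep(0, 6))
  expect_identical(tr$r, rep(0, 6))
})

test_that("goal distance divides weights 5:1 between d = 0 and d = 4", {
  con <- seq_to_ltm(5)
  tr <- score_segments(con$ltm, rep(1, 5), con$wm, test_outcomes(),
                       c(hunger = 0), 0.2, 0)
  expect_equal(tr$w[5] / tr$w[1], 5)
})

test_that("single-contributor allocentric selection points at the waypoint", {
  m <- 3
  ltm <- ltm_new(m)
  wm <- wm_new()
  stm <- store_segment(stm_new(10), simple_segment(1, pos = c(0, 0)), 0, 1)
  con <- consolidate_sequence(ltm, wm, stm, list(
    outcome_id = "food", pred = c(9, 9, 9), pos = c(0, 3),
    need_id = "hunger", valence = 1))
  e <- 1
  tr <- score_segments(con$ltm, e, con$wm, test_outcomes(), c(hunger = 0), 0.2, 0)
  sel <- select_action_cl(tr, con$ltm, agent_pose(0, 0, 0), "allocentric",
                          0.5, 0.5, 0, 0.9, 0.5)
  expect_equal(sel$action$vec, c(0, 0.5), tolerance = 1e-12) # unit north * v_max
})

test_that("opposed equal contributions cancel to the null action", {
  m <- 3
  ltm <- ltm_new(m)
  wm <- wm_new()
  for (g in 1:2) {
    stm <- store_segment(stm_new(10),
                         simple_segment(g, pos = c(0, 0), pred = c(5, 5, 5)), 0, 1)
    con <- consolidate_sequence(ltm, wm, stm, list(
      outcome_id = "food", pred = c(9, 9, 9),
      pos = if (g == 1) c(0, 3) else c(0, -3),
      need_id = "hunger", valence = 1))
    ltm <- con$ltm
    wm <- con$wm
  }
  tr <- score_segments(ltm, rep(1, 2), wm, test_outcomes(), c(hunger = 0), 0.2, 0)
  sel <- select_action_cl(tr, ltm, agent_pose(0, 0, 0), "allocentric",
                          0.5, 0.5, 0, 0.9, 0.5)
  expect_true(sel$action$speed == 0 && all(sel$action$vec == 0))
})

test_that("all-zero weights make the layer abstain", {
  con <- seq_to_ltm(3)
  tr <- score_segments(con$ltm, rep(1, 3), con$wm,
                       devalue_outcome(test_outcomes(), "food", 0),
                       c(hunger = 0), 0.2, 0)
  sel <- select_action_cl(tr, con$ltm, agent_pose(0, 0, 0), "allocentric")
  expect_length(sel$contributors, 0)
  expect_true(all(sel$action$vec == 0) && sel$action$speed == 0)
})

test_that("pruning keeps the most recent sequences consistent with WM", {
  con <- seq_to_ltm(4)
  con2 <- seq_to_ltm(3, ltm = con$ltm, wm = con$wm)
  pr <- ltm_keep_recent(con2$ltm, con2$wm, 1L)
  expect_equal(unique(pr$ltm$seq_id), 2)
  expect_equal(pr$ltm$n, 3)
  expect_length(pr$wm$c, 3)
  expect_equal(dim(pr$wm$C), c(3, 3))
})

test_that("decision traces tabulate all four factors per segment", {
  con <- seq_to_ltm(4)
  e <- c(1, 0.5, 0.25, 1)
  tr <- score_segments(con$ltm, e, con$wm, test_outcomes(), c(hunger = 0.5),
                       0.2, 0)
  df <- trace_to_df(tr, con$ltm, contributors = c(4L))
  expect_equal(nrow(df), 4)
  expect_equal(df$evidence, e)
  expect_true(df$contributor[4] && !any(df$contributor[1:3]))
  expect_equal(df$weight, tr$w)
})
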