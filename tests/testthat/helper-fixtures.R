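# Small in-code fixtures shared across test files.

simple_segment <- function(step, pos = c(step, 0), turn = 0, speed = 0.5,
                           pred = c(step, 0, 0), heading = 0) {
  dacsim:::make_segment(1L, pred, null_action(), turn, speed,
                        agent_pose(pos[1], pos[2], heading), step)
}

seq_to_ltm <- function(n = 5, goal_valence = 1, outcome_id = "food",
                       m = 3, ltm = ltm_new(m), wm = wm_new()) {
  stm <- stm_new(30)
  for (i in seq_len(n)) stm <- store_segment(stm, simple_segment(i), 0, 1)
  consolidate_sequence(ltm, wm, stm, list(
    outcome_id = outcome_id, pred = c(n + 1, 0, 0), pos = c(n + 1, 0),
    need_id = "hunger", valence = goal_valence))
}
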