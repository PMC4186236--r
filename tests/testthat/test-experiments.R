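test_that("conditioning reproduces the delta-rule closed forms", {
  rc <- run_conditioning(n_acq = 50, n_ext = 50, us_valence = 1)
  expect_equal(rc$u_acq, 1 - 0.9^50, tolerance = 1e-9)
  expect_lt(rc$u_final, 0.01)
  expect_equal(nrow(rc$curve), 100)
  # first CR trial: smallest N with US(1-(1-eta)^N) >= theta_cr,
  # solved numerically from the recursion
  u <- 0
  first <- NA
  for (n in 1:50) {
    u <- u + 0.1 * (1 - u)
    if (is.na(first) && u >= 0.1) first <- n
  }
  expect_equal(rc$first_cr_trial, first)
})

test_that("conditioning tracks different learning rates and US magnitudes", {
  cfg <- dac_default_config()
  cfg$al$eta <- 0.25
  rc <- run_conditioning(n_acq = 30, n_ext = 10, us_valence = 0.6, config = cfg)
  expect_equal(rc$u_acq, 0.6 * (1 - 0.75^30), tolerance = 1e-9)
  expect_equal(rc$u_final, 0.6 * (1 - 0.75^30) * 0.75^10, tolerance = 1e-9)
})

test_that("dispersion matches hand-computed and brute-force values", {
  t1 <- cbind(seq(0, 10, length.out = 40), rep(0, 40))
  t2 <- cbind(seq(0, 10, length.out = 25), rep(2, 25)) # parallel, offset 2
  expect_equal(compute_dispersion(list(t1, t1), 10), 0)
  expect_equal(compute_dispersion(list(t1, t2), 10), 2, tolerance = 1e-9)
  expect_error(compute_dispersion(list(t1), 10), "at least 2")
  set.seed(21)
  trajs <- lapply(1:3, function(i) {
    n <- sample(20:40, 1)
    cbind(cumsum(runif(n)), cumsum(rnorm(n)))
  })
  got <- compute_dispersion(trajs, 15)
  qs <- seq(0, 1, length.out = 15)
  R <- lapply(trajs, function(tr) {
    s <- c(0, cumsum(sqrt(diff(tr[, 1])^2 + diff(tr[, 2])^2)))
    s <- s / max(s)
    cbind(approx(s, tr[, 1], qs, ties = "ordered")$y,
          approx(s, tr[, 2], qs, ties = "ordered")$y)
  })
  expect_equal(got, oracle_dispersion(R), tolerance = 1e-12)
})

test_that("kidnapping to the goal position succeeds almost immediately", {
  cfg <- dac_default_config()
  cfg$world$sensor_range <- 25
  fx <- generate_arena_fixture("foraging", 5)
  sim <- dacsim:::new_forager(cfg, fx)
  reg <- rng_registry(5)
  goal <- fx$arena$outcome_sites[[1]]$pos
  ph <- run_phase(sim, reg, 40, stop_on_outcome = TRUE,
                  kidnap_at = 10, kidnap_pos = goal)
  expect_true(ph$success)
  expect_lte(ph$steps_used, 12)
})

test_that("a lesioned agent dropped in a zero-field zone fails within budget", {
  cfg <- dac_default_config()
  # large arena: the odour fields are undetectable in the far corner
  a <- arena(40, 40,
             landmarks = list(list(id = "lm", pos = c(20, 20), features = c(1, 0, 0))),
             outcome_sites = list(list(id = "f", pos = c(5, 5),
                                       outcome_id = "food", radius = 0.8)),
             fields = list(food_odor = affordance_field("food_odor", list(
               list(center = c(5, 5), amplitude = 1, sigma = 1.2)))))
  vars <- list(essential_variable("hunger", 0.5, 1, 0.01, c(food = 0.3)))
  sys <- list(behaviour_system("forage", "food_odor", "hunger", 0.5,
                               gain = cfg$rl$gain))
  outs <- outcome_table(food = list(valence = 1, need_id = "hunger"))
  sim <- dac_sim(cfg, a, outs, vars, sys, agent_pose(5, 6, 0),
                 lesion = list(disable_cl = TRUE))
  reg <- rng_registry(3)
  ph <- run_phase(sim, reg, 60, stop_on_outcome = TRUE,
                  kidnap_at = 5, kidnap_pos = c(38, 38))
  expect_false(ph$success)
})

test_that("devaluation leaves AL value untouched at unvisited prototypes", {
  # the nausea context activates its own prototype; the lever prototype
  # receives no US there, so its value cannot move
  al <- dacsim:::al_state(K = 8, m = 3, alpha = 0.1, eta = 0.1, lambda = 0.1,
                          theta_cr = 0.1)
  lever <- c(1, 0, 0)
  context <- c(0, 0, 1)
  for (i in 1:20) {
    ob <- dacsim:::al_observe(al, lever)
    al <- ob$al
    al$w <- update_value(al$w, ob$k, 1, TRUE)
  }
  k_lever <- perceive(al$bank, lever)$k
  u_before <- al$w$u[k_lever]
  for (i in 1:10) {
    ob <- dacsim:::al_observe(al, context)
    al <- ob$al
    al$w <- update_value(al$w, ob$k, -1, TRUE)
  }
  expect_identical(al$w$u[perceive(al$bank, lever)$k], u_before)
  expect_lt(al$w$u[perceive(al$bank, context)$k], 0)
})

test_that("maze distracters trap reactive control but not the intact agent", {
  mz <- run_maze_distracters(n_seeds = 2, n_test = 2)
  expect_gte(mz$summary$success_intact, mz$summary$success_lesion)
  expect_gt(mz$summary$success_intact, 0.5)
  if (!is.nan(mz$summary$steps_lesion) && !is.nan(mz$summary$steps_intact)) {
    expect_lte(mz$summary$steps_intact, mz$summary$steps_lesion)
  }
})

test_that("an open corridor without distracters is solved by both variants", {
  # generous budget: the reactive variant can spend long stretches pinned
  # on a wall before heading noise frees it
  mz <- run_maze_distracters(n_seeds = 1, n_train = 6, n_test = 2,
                             trial_steps = 800, n_distracters = 0L)
  expect_equal(mz$summary$success_intact, 1)
  expect_equal(mz$summary$success_lesion, 1)
})

test_that("arena fixtures are deterministic, valid, and carry their anchors", {
  kinds <- c("open_field", "lever_box", "corridor_maze", "foraging")
  for (kind in kinds) {
    j1 <- as.character(write_arena(generate_arena_fixture(kind, 17)$arena))
    j2 <- as.character(write_arena(generate_arena_fixture(kind, 17)$arena))
    expect_identical(j1, j2)
    for (seed in 1:25) {
      fx <- generate_arena_fixture(kind, seed)
      expect_silent(validate_arena(fx$arena))
    }
  }
  expect_error(generate_arena_fixture("volcano", 1), "unknown kind")
})

test_that("corridor fixtures hold a distracter cue near the goal's features", {
  cfg <- dac_default_config()
  for (seed in 1:10) {
    fx <- generate_arena_fixture("corridor_maze", seed)
    lms <- fx$arena$landmarks
    gf <- Find(function(l) l$id == "goal_beacon", lms)$features
    dists <- vapply(Filter(function(l) grepl("^distracter", l$id), lms),
                    function(l) sqrt(sum((l$features - gf)^2)), 0)
    expect_gt(length(dists), 0)
    expect_true(any(dists <= cfg$cl$sigma_e))
  }
})
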