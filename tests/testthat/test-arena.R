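test_that("sample_field evaluates Gaussian source kernels", {
  f <- affordance_field("f", list(list(center = c(0, 0), amplitude = 1, sigma = 1)))
  expect_equal(sample_field(f, c(0, 0)), 1.0)
  # half maximum at sigma * sqrt(2 ln 2)
  expect_equal(sample_field(f, c(0, sqrt(2 * log(2)))), 0.5)
  # linearity: co-located amplitudes add
  f2 <- affordance_field("f2", list(
    list(center = c(0, 0), amplitude = 0.3, sigma = 1),
    list(center = c(0, 0), amplitude = 0.7, sigma = 1)))
  for (i in 1:20) {
    p <- runif(2, -3, 3)
    expect_equal(sample_field(f2, p), sample_field(f, p), tolerance = 1e-12)
  }
})

test_that("field of concatenated source lists equals the sum of the fields", {
  set.seed(42)
  s1 <- lapply(1:3, function(i) list(center = runif(2, 0, 10),
                                     amplitude = runif(1), sigma = runif(1, 0.5, 3)))
  s2 <- lapply(1:2, function(i) list(center = runif(2, 0, 10),
                                     amplitude = runif(1), sigma = runif(1, 0.5, 3)))
  fa <- affordance_field("a", s1)
  fb <- affordance_field("b", s2)
  fc <- affordance_field("c", c(s1, s2))
  for (i in 1:50) {
    p <- runif(2, 0, 10)
    expect_equal(sample_field(fc, p), sample_field(fa, p) + sample_field(fb, p),
                 tolerance = 1e-12)
  }
})

test_that("sample_field rejects out-of-bounds positions when given an arena", {
  a <- arena(5, 5, fields = list(f = affordance_field("f", list())))
  expect_error(sample_field(a$fields$f, c(6, 1), a), "outside")
})

test_that("apply_action moves deterministically without noise", {
  a <- arena(10, 10)
  p <- agent_pose(0, 0, 0)
  p2 <- apply_action(p, action("egocentric", turn = 0, speed = 1), 0, NULL, a, 2)
  expect_equal(p2$position, c(1, 0), tolerance = 1e-9)
  expect_equal(p2$heading, 0)
  p3 <- apply_action(p, action("allocentric", vec = c(0, 2)), 0, NULL, a, 5)
  expect_equal(p3$position, c(0, 2), tolerance = 1e-9)
  expect_equal(p3$heading, 0) # allocentric motion leaves heading unchanged
})

test_that("walls stop motion at the wall face", {
  a <- arena(10, 10, walls = list(c(5, 0, 5, 10)))
  p <- agent_pose(4, 3, 0)
  # geometric oracle: motion from (4,3) east by 3 hits x = 5 at t = 1/3
  p2 <- apply_action(p, action("egocentric", turn = 0, speed = 3), 0, NULL, a, 5)
  expect_equal(p2$position[1], 5, tolerance = 1e-6)
  expect_equal(p2$position[2], 3, tolerance = 1e-6)
  # arena bounds clamp likewise
  p3 <- apply_action(agent_pose(9.5, 5, 0), action("egocentric", 0, 2), 0, NULL, a, 5)
  expect_equal(p3$position[1], 10, tolerance = 1e-6)
})

test_that("essential-variable dynamics decay, replenish and clip", {
  v <- essential_variable("hunger", level = 0.5, set_point = 0.8,
                          decay_rate = 0.01, replenish = c(food = 1.0))
  v2 <- update_needs(list(v))[[1]]
  expect_equal(v2$level, 0.49)
  expect_equal(need_drives(list(v2))[["hunger"]], 0.8 - 0.49)
  v3 <- update_needs(list(essential_variable("hunger", 0.2, 1, 0.01,
                                             c(food = 1.0))), "food")[[1]]
  expect_equal(v3$level, 1.0) # clipped
  expect_equal(need_drives(list(v3))[["hunger"]], 0)
  # linear decay to zero
  vs <- list(essential_variable("hunger", 1, 1, 0.01, c(food = 0.3)))
  for (i in 1:100) vs <- update_needs(vs)
  expect_equal(vs[[1]]$level, 0, tolerance = 1e-12)
  expect_error(update_needs(vs, "unobtainium"), "unknown outcome")
})

test_that("need levels stay in [0,1] and drives stay nonnegative", {
  set.seed(7)
  vs <- list(essential_variable("a", 0.5, 0.9, 0.05, c(food = 0.4)),
             essential_variable("b", 0.2, 0.6, 0.001, c(food = 0.05)))
  for (i in 1:300) {
    vs <- update_needs(vs, if (runif(1) < 0.3) "food" else character())
    for (v in vs) expect_true(v$level >= 0 && v$level <= 1)
    expect_true(all(need_drives(vs) >= 0))
  }
})

test_that("exosensing returns zeros in an empty arena and localized blocks", {
  a0 <- arena(10, 10)
  expect_equal(sense_exo(a0, agent_pose(5, 5, 0), 8, 10), numeric(0))
  a1 <- arena(10, 10, landmarks = list(
    list(id = "lm", pos = c(7, 5), features = c(1, 0, 0))))
  x <- sense_exo(a1, agent_pose(5, 5, 0), 8, 10)
  expect_length(x, 24)
  # landmark dead ahead: only the forward-ray block is nonzero
  expect_equal(x, c((1 - 2 / 10) * 1, rep(0, 23)))
})

test_that("rotating by one sector cyclically shifts the ray blocks", {
  a <- arena(20, 20, landmarks = list(
    list(id = "l1", pos = c(14, 11), features = c(1, 0, 0)),
    list(id = "l2", pos = c(6, 4), features = c(0, 1, 0))))
  n_rays <- 8
  p1 <- sense_exo(a, agent_pose(10, 10, 0.3), n_rays, 15)
  p2 <- sense_exo(a, agent_pose(10, 10, 0.3 + 2 * pi / n_rays), n_rays, 15)
  m1 <- matrix(p1, nrow = n_rays, byrow = TRUE)
  m2 <- matrix(p2, nrow = n_rays, byrow = TRUE)
  # heading advanced one sector: block r of p1 appears at ray r-1 of p2
  expect_equal(m2, m1[c(2:n_rays, 1), ], tolerance = 1e-12)
})

test_that("cue channels flag containment", {
  a <- arena(10, 10,
             landmarks = list(list(id = "lm", pos = c(9, 9), features = 1)),
             cues = list(list(id = "c1", pos = c(2, 2), radius = 1, channel = 1L)))
  inside <- sense_exo(a, agent_pose(2.5, 2, 0), 8, 10)
  outside <- sense_exo(a, agent_pose(5, 5, 0), 8, 10)
  expect_equal(inside[length(inside)], 1)
  expect_equal(outside[length(outside)], 0)
})

test_that("outcome triggering honours arming, radius, valence and refractory", {
  a <- arena(10, 10, outcome_sites = list(
    list(id = "s1", pos = c(5, 5), outcome_id = "food", radius = 0.8)))
  outs <- test_outcomes()
  st <- list(s1 = list(armed = TRUE, armed_by_agent = TRUE, refractory_until = -Inf))
  far <- trigger_outcome(a, agent_pose(1, 1, 0), outs, st, 1)
  expect_null(far$event)
  hit <- trigger_outcome(a, agent_pose(5.2, 5, 0), outs, st, 1)
  expect_equal(hit$event$outcome_id, "food")
  expect_equal(hit$event$valence, 1)
  expect_equal(hit$event$need_id, "hunger")
  # refractory: immediate second contact is silent
  again <- trigger_outcome(a, agent_pose(5.2, 5, 0), outs, hit$site_state, 2)
  expect_null(again$event)
  # devaluation propagates immediately to events
  outs2 <- devalue_outcome(outs, "food", -1)
  hit2 <- trigger_outcome(a, agent_pose(5, 5, 0), outs2, st, 1)
  expect_equal(hit2$event$valence, -1)
  expect_error(devalue_outcome(outs, "nope", 0), "unknown outcome")
})

test_that("arena validation catches bad fixtures", {
  expect_error(arena(10, 10, landmarks = list(
    list(id = "a", pos = c(1, 1), features = 1),
    list(id = "a", pos = c(2, 2), features = 1))), "duplicate")
  expect_error(arena(10, 10, landmarks = list(
    list(id = "a", pos = c(11, 1), features = 1))), "outside")
  expect_error(arena(10, 10, fields = list(f = affordance_field("f", list(
    list(center = c(1, 1), amplitude = 1, sigma = 0))))), "sigma")
})
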