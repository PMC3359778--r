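test_that("waves split at gaps longer than the refractory window", {
  inc <- make_incidents(agent_id = 1:6, t0 = c(0, 5, 10, 100, 104, 300))
  inc$wave_id <- NULL
  out <- assign_waves(inc, gap_frames = 48)
  expect_equal(out$wave_id, c(1L, 1L, 1L, 2L, 2L, 3L))
})

test_that("the nearest qualifying near neighbour becomes the trigger", {
  a <- as_agent_set(data.frame(x_mm = c(0, 20, 0, 0), y_mm = c(0, 0, 35, 70)))
  inc <- make_incidents(agent_id = c(2L, 3L, 4L, 1L), t0 = c(8, 9, 9, 10))
  inc <- assign_triggers(inc, a)
  k <- which(inc$agent_id == 1L)
  expect_equal(inc$trigger_id[k], 2L)          # 20 mm beats 35 mm (rule b)
  expect_equal(inc$dir_trig[k], 1L)            # trigger sits to the Right
  expect_equal(inc$role[k], "focus")
  # agent 4 is 70 mm away: outside the near neighbourhood of agent 1
})

test_that("incidents without a candidate within 5 frames are untriggered-active", {
  a <- as_agent_set(data.frame(x_mm = c(0, 20), y_mm = c(0, 0)))
  inc <- make_incidents(agent_id = c(2L, 1L), t0 = c(2, 10))  # lag 8 > 5
  inc <- assign_triggers(inc, a)
  expect_equal(inc$role[inc$agent_id == 1L], "untriggered-active")
  expect_true(is.na(inc$trigger_id[inc$agent_id == 1L]))
  # and a candidate at exactly 5 frames qualifies
  inc2 <- assign_triggers(make_incidents(agent_id = c(2L, 1L), t0 = c(5, 10)), a)
  expect_equal(inc2$trigger_id[inc2$agent_id == 1L], 2L)
})

test_that("trigger assignment is invariant to incident row order", {
  res <- big_res_p1()
  inc <- res$incidents[, c("agent_id", "t0", "t1", "peak_rel", "baseline",
                           "c_ws", "wave_id")]
  set.seed(99)
  shuf <- inc[sample(nrow(inc)), ]
  a1 <- assign_triggers(inc, big_lattice())
  a2 <- assign_triggers(shuf, big_lattice())
  a2 <- a2[match(a1$agent_id, a2$agent_id), ]
  expect_equal(a1$trigger_id, a2$trigger_id)
  expect_equal(a1$dir_trig, a2$dir_trig)
})

test_that("fully directed simulations recover >=95% of truth trigger edges", {
  sim <- big_sim_p1()
  res <- big_res_p1()
  tr <- sim$truth$incidents
  truth_map <- stats::setNames(tr$trigger_id, tr$agent_id)
  foc <- res$incidents[res$incidents$role == "focus", ]
  hit <- mean(foc$trigger_id == truth_map[as.character(foc$agent_id)],
              na.rm = TRUE)
  expect_gte(hit, 0.95)
})

test_that("the plane-wave fit recovers the simulated key direction", {
  for (d in c(2L, 3L)) {   # from Bottom to Top; from Left to Right
    sim <- simulate_wave(big_lattice(),
                         wave_params(dir_true = d, p_directed = 1,
                                     noise_sd = 0, seed = 30 + d))
    res <- run_pipeline(sim)
    defined <- res$wave_dirs[res$wave_dirs$defined, ]
    expect_equal(defined$dir_wav, d)
  }
})

test_that("degenerate waves are flagged undefined", {
  a <- as_agent_set(data.frame(x_mm = seq(0, 300, by = 25), y_mm = 0))
  inc <- make_incidents(agent_id = a$agent_id, t0 = rep(10L, nrow(a)))
  wd <- classify_wave_direction(inc, a)
  expect_false(wd$defined)
  expect_true(is.na(wd$dir_wav))
  # too few incidents is also undefined
  wd2 <- classify_wave_direction(inc[1:4, ], a)
  expect_false(wd2$defined)
  # a manual override is honoured
  wd3 <- classify_wave_direction(inc, a, override = c("1" = 4))
  expect_equal(wd3$dir_wav, 4L)
})
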