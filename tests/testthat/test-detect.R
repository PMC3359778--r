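step_trace <- function(n, at, len, height = 3, base = 1.08) {
  tr <- rep(base, n)
  tr[at + seq_len(len)] <- base + height  # 0-based frame `at` is pre-onset
  tr
}

test_that("a constant baseline trace yields no incidents", {
  expect_equal(nrow(detect_incidents(rep(1.08, 100), baseline = 1.08)), 0L)
  expect_equal(nrow(detect_incidents(rep(1.08, 3), baseline = 1.08)), 0L)
})

test_that("participation requires five successive supra-threshold frames", {
  four <- detect_incidents(step_trace(60, 20, 4), baseline = 1.08)
  five <- detect_incidents(step_trace(60, 20, 5), baseline = 1.08)
  expect_equal(nrow(four), 0L)
  expect_equal(nrow(five), 1L)
  expect_equal(five$t1, 20L)       # first supra frame
  expect_equal(five$t0, 19L)       # defined one frame before
  expect_equal(five$peak_rel, 1.08 + 3)
})

test_that("excursions below the participation threshold are ignored", {
  weak <- detect_incidents(step_trace(60, 20, 8, height = 0.9),
                           baseline = 1.08)
  expect_equal(nrow(weak), 0L)
})

test_that("runs inside the merge window fuse into one incident", {
  tr <- step_trace(200, 20, 6)
  tr[60 + 1:6] <- 1.08 + 5         # second run 40 frames later
  inc <- detect_incidents(tr, baseline = 1.08, merge_frames = 48)
  expect_equal(nrow(inc), 1L)
  expect_equal(inc$t0, 19L)
  expect_equal(inc$peak_rel, 6.08) # merged incident keeps the larger peak
  inc2 <- detect_incidents(tr, baseline = 1.08, merge_frames = 30)
  expect_equal(nrow(inc2), 2L)
  # invariant: no two incidents closer than the merge window
  expect_true(all(diff(inc2$t0) >= 30))
})

test_that("wave-strength categories use half-open level intervals", {
  b <- default_ws_bounds()
  expect_equal(categorize_ws(b[1] - 1e-9), 0L)   # below b1: non-participation
  expect_equal(categorize_ws(b[1]), 1L)          # exactly at b1
  expect_equal(categorize_ws(b[5]), 5L)
  expect_equal(categorize_ws(b[8] + 10), 8L)
  expect_error(categorize_ws(2, bounds = c(1, 2, 2, 3, 4, 5, 6, 7)),
               "increasing")
})

test_that("detected onsets match simulator truth", {
  sim <- big_sim_p1()
  det <- detect_all(sim$traces, agent_ids = sim$agents$agent_id)
  m <- merge(det[, c("agent_id", "t0")],
             sim$truth$incidents[, c("agent_id", "t0")],
             by = "agent_id", suffixes = c("_det", "_true"))
  hit <- mean(abs(m$t0_det - m$t0_true) <= sim$params$latency_frames)
  expect_gte(hit, 0.95)
})

test_that("default simulations put the strength mode at mid levels", {
  det <- detect_all(big_sim_p1()$traces,
                    agent_ids = big_sim_p1()$agents$agent_id)
  tab <- table(factor(det$c_ws, levels = 0:8))
  mode_level <- as.integer(names(tab)[which.max(tab)])
  expect_true(mode_level %in% 2:4)
})

test_that("repetition rate is the reciprocal median inter-onset interval", {
  inc <- data.frame(agent_id = rep(1:2, each = 3),
                    t0 = c(0, 50, 100, 10, 60, 110))
  rr <- repetition_rate(inc, fps = 60)
  expect_equal(rr$rate_hz, 1.2)        # 50-frame intervals at 60 fps
  expect_equal(rr$refractory_ms, 50 * 1000 / 60)
  single <- repetition_rate(data.frame(agent_id = 1:3, t0 = c(1, 5, 9)))
  expect_true(is.na(single$rate_hz))
  expect_true(is.na(single$refractory_ms))
})

test_that("saturation driving recovers the 800 ms refractory phase", {
  sim <- simulate_wave(big_lattice(),
                       wave_params(p_directed = 1, noise_sd = 0,
                                   n_waves = 4, seed = 3))
  det <- detect_all(sim$traces, agent_ids = sim$agents$agent_id)
  rr <- repetition_rate(det, fps = 60)
  expect_lte(abs(rr$refractory_ms - 800), 1000 / 60)  # within one frame
})
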