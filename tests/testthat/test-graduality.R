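four_chain_agents <- function() {
  as_agent_set(do.call(rbind, lapply(0:3, function(r)
    data.frame(x_mm = (0:4) * 30, y_mm = r * 200))))
}

test_that("identity coupling gives r = 1 and slope 1 in direct-sector mode", {
  a <- four_chain_agents()
  sim <- simulate_wave(a, wave_params(p_directed = 1, noise_sd = 0,
                                      k_couple = 1, passive_frac = 0,
                                      seed = 6))
  res <- run_pipeline(sim)
  fit <- sector_regression(res$incidents, a, mode = "ds")
  expect_gte(fit$n, 3)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$k, 1, tolerance = 1e-9)
})

test_that("shuffled pairing collapses the correlation to the permutation null", {
  fit <- sector_regression(big_res_p1()$incidents, big_lattice(), mode = "ds")
  p <- fit$pairs
  set.seed(31)
  null_r <- replicate(500, stats::cor(p$focus, sample(p$neighbour)))
  band <- stats::quantile(null_r, c(0.025, 0.975))
  r_shuf <- stats::cor(p$focus, sample(p$neighbour))
  expect_gte(r_shuf, band[1])
  expect_lte(r_shuf, band[2])
  # and the band is tight around zero at this sample size
  expect_lt(max(abs(band)), 0.25)
})

test_that("zero-variance strength series report a missing correlation", {
  a <- as_agent_set(data.frame(x_mm = c(0, 30, 60), y_mm = 0))
  inc <- make_incidents(agent_id = c(1L, 2L, 3L), t0 = c(0, 3, 6),
                        dir_trig = c(NA, 5L, 5L), trigger_id = c(NA, 1L, 2L),
                        role = c("untriggered-active", "focus", "focus"),
                        peak_rel = 4)
  fit <- sector_regression(inc, a, mode = "ds")
  expect_true(is.na(fit$r))
})

test_that("graduality summary squares r into the percent share", {
  res <- small_res()
  g <- res$graduality
  ok <- !is.na(g$table$r)
  expect_equal(g$table$percent_share[ok], 100 * g$table$r[ok]^2)
  expect_true(all(g$table$r[ok] >= -1 & g$table$r[ok] <= 1))
  expect_equal(graduality_share(0.16), 2.56)
})

test_that("mirror-symmetric activity gives identical ds/os series, t = 0, P = 1", {
  # isolated clusters: a focus bee flanked east and west by neighbours of
  # equal strength, so direct- and opposite-sector series coincide exactly
  rows <- list(); agents <- list(); id <- 0L
  for (lv in 2:3) {                      # two strength levels
    for (cl in 1:4) {                    # four clusters per level
      ox <- 1000 * cl; oy <- 1000 * lv
      agents[[length(agents) + 1]] <-
        data.frame(x_mm = ox + c(0, 50, -50), y_mm = oy)
      q <- 2 + 0.7 * cl + lv             # focus peak, varies across clusters
      p <- 1.5 + 0.5 * cl^1.3            # flank peak, not collinear with q
      rows[[length(rows) + 1]] <- make_incidents(
        agent_id = id + 1:3, t0 = c(10L, 5L, 5L),
        wave_id = 1L, dir_trig = c(1L, NA, NA), trigger_id = c(id + 2L, NA, NA),
        role = c("focus", "untriggered-active", "untriggered-active"),
        c_ws = lv, peak_rel = c(q, p, p))
      id <- id + 3L
    }
  }
  a <- as_agent_set(do.call(rbind, agents))
  inc <- do.call(rbind, rows)
  g <- graduality_summary(inc, a, c_ws_levels = 2:3)
  rds <- g$table$r[g$table$mode == "ds"]
  ros <- g$table$r[g$table$mode == "os"]
  expect_equal(rds, ros)
  expect_equal(g$t_test$statistic, 0)
  expect_equal(g$t_test$p.value, 1)
})

test_that("directional coupling raises r_ds above r_os", {
  incs <- list(); n_off <- 0
  for (s in 1:3) {
    sim <- simulate_wave(big_lattice(),
                         wave_params(p_directed = 0.5, k_couple = 0.8,
                                     seed = 60 + s))
    r <- run_pipeline(sim)
    inc <- r$incidents
    inc$t0 <- inc$t0 + n_off
    inc$wave_id <- inc$wave_id + 10 * s
    n_off <- n_off + 10000
    incs[[s]] <- inc
  }
  inc <- do.call(rbind, incs)
  ds <- sector_regression(inc, big_lattice(), mode = "ds")
  os <- sector_regression(inc, big_lattice(), mode = "os")
  expect_gte(ds$n, 30)
  expect_gte(os$n, 30)
  expect_gt(ds$r, os$r)
})

test_that("estimated slope recovers k_couple monotonically", {
  ks <- vapply(c(0, 0.5, 1), function(k) {
    sim <- simulate_wave(big_lattice(),
                         wave_params(p_directed = 1, noise_sd = 0,
                                     k_couple = k, passive_frac = 0,
                                     seed = 70))
    res <- run_pipeline(sim)
    sector_regression(res$incidents, big_lattice(), mode = "tn")$k
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_equal(ks, c(0, 0.5, 1), tolerance = 0.15)
})
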