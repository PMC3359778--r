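gauss_curve <- function(t_ms, center = 100, amp = 4, width = 60,
                        base = 1.08) {
  data.frame(t_ms = t_ms, mean = base + amp * exp(-((t_ms - center) / width)^2))
}

test_that("identical pulses synchronize with zero standard error", {
  n_frames <- 80
  pulse <- c(rep(1.08, 30), 1.08 + 3 * pulse_shape(12), rep(1.08, 80))[1:80]
  traces <- matrix(rep(pulse, 6), n_frames, 6)
  inc <- make_incidents(agent_id = 1:6, t0 = 29L, trigger_id = NA_integer_)
  cur <- synchronize(traces, inc, agent_ids = 1:6, c_ws_levels = 3)
  expect_equal(max(cur[["3"]]$fb$se), 0)
  expect_true(all(cur[["3"]]$fb$n == 6))
})

test_that("ensemble means equal the brute-force average at every grid point", {
  set.seed(13)
  traces <- matrix(stats::rnorm(100 * 4, 1.1, 0.2), 100, 4)
  t0s <- c(40L, 45L, 50L, 55L)
  inc <- make_incidents(agent_id = 1:4, t0 = t0s, trigger_id = NA_integer_)
  cur <- synchronize(traces, inc, agent_ids = 1:4, window_ms = c(-100, 100),
                     c_ws_levels = 3)
  fb <- cur[["3"]]$fb
  offs <- round(fb$t_ms * 60 / 1000)
  for (i in seq_along(offs)) {
    vals <- vapply(1:4, function(k) traces[t0s[k] + offs[i] + 1L, k],
                   numeric(1))
    expect_equal(fb$mean[i], mean(vals))
    expect_equal(fb$n[i], 4)
  }
})

test_that("a pure time shift is recovered exactly at every threshold", {
  t_ms <- seq(-200, 600, by = 1000 / 60)
  fb <- gauss_curve(t_ms, center = 150)
  nb <- gauss_curve(t_ms, center = 100)      # neighbour leads by 50 ms
  tt <- transfer_time(fb, nb)
  expect_equal(length(tt$per_threshold$threshold), 14)  # 1.0..2.3 by 0.1
  expect_equal(tt$dt_ms, 50, tolerance = 1e-6)
  expect_equal(tt$se_ms, 0, tolerance = 1e-6)
  expect_true(tt$reliable)
})

test_that("transfer time is invariant to a common time shift of both curves", {
  t_ms <- seq(-200, 600, by = 1000 / 60)
  tt1 <- transfer_time(gauss_curve(t_ms, 150), gauss_curve(t_ms, 100))
  tt2 <- transfer_time(gauss_curve(t_ms, 250), gauss_curve(t_ms, 200))
  expect_equal(tt1$dt_ms, tt2$dt_ms, tolerance = 1e-6)
})

test_that("uncrossed thresholds are excluded and flagged", {
  t_ms <- seq(-200, 600, by = 1000 / 60)
  fb <- gauss_curve(t_ms, amp = 0.15)   # peaks at 1.23: crosses two levels
  nb <- gauss_curve(t_ms, amp = 0.15, center = 50)
  tt <- transfer_time(fb, nb)
  expect_gt(tt$n_excluded, 0)
  expect_false(tt$reliable)             # fewer than 3 usable thresholds
})

test_that("the simulated hop latency is recovered within half a frame", {
  res <- big_res_k1()
  lat_ms <- big_sim_k1()$params$latency_frames * 1000 / 60
  dts <- vapply(res$transfer, function(t) t$dt_ms, numeric(1))
  expect_gte(length(dts), 2)
  expect_lt(abs(mean(dts) - lat_ms), 0.5 * 1000 / 60)
  # the cross-correlation estimator agrees at frame resolution
  xc <- vapply(res$transfer, function(t) t$xcorr_ms, numeric(1))
  expect_lt(abs(mean(xc) - lat_ms), 1000 / 60)
})

test_that("focus-bee curves build up passively before the onset", {
  e <- big_res_k1()$curves[["3"]]
  pre <- e$fb$mean[e$fb$t_ms >= -100 & e$fb$t_ms <= 0]
  expect_gt(pre[length(pre)], 1.08 + 0.1)   # above baseline just before t0
  expect_true(all(diff(pre) > -0.05))        # rising, not pulsing
  post_peak <- max(e$fb$mean)
  expect_gt(post_peak, pre[length(pre)] + 1) # the active flip dwarfs it
})

test_that("ensemble SE shrinks as 1/sqrt(n) on homogeneous ensembles", {
  set.seed(23)
  mk <- function(n) {
    traces <- matrix(stats::rnorm(60 * n, 1.1, 0.3), 60, n)
    inc <- make_incidents(agent_id = seq_len(n), t0 = 29L,
                          trigger_id = NA_integer_)
    cur <- synchronize(traces, inc, agent_ids = seq_len(n),
                       window_ms = c(-50, 50), c_ws_levels = 3)
    mean(cur[["3"]]$fb$se)
  }
  ratio <- mk(40) / mk(160)
  expect_equal(ratio, 2, tolerance = 0.35)
})

test_that("propagation speed divides distance by transfer time", {
  sp <- propagation_speed(62, 47.29)
  expect_equal(round(sp$speed_m_s, 3), 1.311)
  expect_equal(propagation_speed(100, 100)$speed_m_s, 1.0)
  expect_equal(propagation_speed(124, 47.29)$speed_m_s,
               2 * propagation_speed(62, 47.29)$speed_m_s)
  sp2 <- propagation_speed(62, 47.29, se_ms = 1.12)
  expect_equal(sp2$se_m_s, sp2$speed_m_s * 1.12 / 47.29)
  expect_error(propagation_speed(-1, 10))
})
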