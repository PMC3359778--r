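focus_incident_table <- function(dir_trig, dir_wav = 3L, c_ws = 3L) {
  make_incidents(agent_id = seq_along(dir_trig),
                 t0 = seq_along(dir_trig), dir_trig = dir_trig,
                 trigger_id = 999L, c_ws = c_ws, dir_wav = dir_wav)
}

test_that("a single populated trigger sector normalizes to 1 and 0 elsewhere", {
  inc <- focus_incident_table(rep(5L, 20))
  h <- suppressWarnings(linearity_histogram(inc))
  expect_equal(unname(h$rel_n_fb[1, ]), c(0, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(unname(h$counts[1, 5]), 20)
})

test_that("uniform triggers give a flat normalized histogram", {
  inc <- focus_incident_table(rep(1:8, each = 50))
  h <- suppressWarnings(linearity_histogram(inc))
  expect_equal(unname(h$rel_n_fb[1, ]), rep(1, 8))
})

test_that("pooling is restricted to focus incidents at c_ws 1..6", {
  inc <- rbind(focus_incident_table(rep(5L, 10)),
               focus_incident_table(rep(1L, 10), c_ws = 7L))
  extra <- focus_incident_table(rep(2L, 5))
  extra$role <- "untriggered-active"
  h <- suppressWarnings(linearity_histogram(rbind(inc, extra)))
  expect_equal(unname(h$counts[1, ]), c(0, 0, 0, 0, 10, 0, 0, 0))
})

test_that("coincidence demands above-median sectors inside the widened window", {
  flat <- rep(1, 8)
  expect_false(test_coincidence(flat, dir_wav = 3))  # nothing strictly above
  aligned <- c(0, 0, 0, 0, 1, 0, 0, 0)
  expect_true(test_coincidence(aligned, dir_wav = 3))
  # a flanking sector of the key direction still counts ...
  flank <- c(0, 0, 0, 0.8, 1, 0, 0, 0)
  expect_true(test_coincidence(flank, dir_wav = 3))
  # ... but an off-window peak breaks coincidence
  off <- c(1, 0, 0, 0, 0.9, 0, 0, 0)
  expect_false(test_coincidence(off, dir_wav = 3))
})

test_that("linearity estimates integrate excesses above fuzziness and median", {
  r <- c(1.0, 0.5, rep(0.4, 6))
  est <- estimate_linearity(r, dir_wav = 1, poly_min = 0.4)
  expect_equal(est$estimate_A, (0.6 + 0.1) / 3.9 * 100, tolerance = 1e-6)
  expect_equal(est$estimate_B, est$estimate_A, tolerance = 1e-6)
  flat <- estimate_linearity(rep(0.7, 8), dir_wav = 1)
  expect_equal(flat$estimate_A, 0, tolerance = 1e-6)
  expect_equal(flat$estimate_B, 0, tolerance = 1e-6)
})

test_that("estimate_B never exceeds estimate_A when the fit minimum is lower", {
  set.seed(17)
  for (i in 1:20) {
    r <- stats::runif(8)
    r <- r / max(r)
    est <- estimate_linearity(r, dir_wav = sample(1:4, 1))
    if (est$poly_min <= est$median_level)
      expect_lte(est$estimate_B, est$estimate_A + 1e-9)
  }
})

test_that("partially directed waves peak in the wave-origin sector", {
  sim <- simulate_wave(big_lattice(),
                       wave_params(p_directed = 0.5, seed = 51))
  res <- run_pipeline(sim)
  rel <- res$linearity$histogram$rel_n_fb
  expect_equal(unname(which.max(rel[1, ])),
               wave_key_sector(as.integer(rownames(rel)[1])))
})

test_that("histogram counts equal a brute-force scan on a small instance", {
  res <- small_res()
  inc <- res$incidents
  h <- suppressWarnings(linearity_histogram(inc))
  for (dw in rownames(h$counts)) {
    for (s in 1:8) {
      n_bf <- 0
      for (k in seq_len(nrow(inc))) {   # brute-force triple of conditions
        if (identical(inc$role[k], "focus") &&
            !is.na(inc$dir_wav[k]) && inc$dir_wav[k] == as.integer(dw) &&
            !is.na(inc$dir_trig[k]) && inc$dir_trig[k] == s &&
            inc$c_ws[k] %in% 1:6)
          n_bf <- n_bf + 1
      }
      expect_equal(unname(h$counts[dw, s]), n_bf)
    }
  }
})
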