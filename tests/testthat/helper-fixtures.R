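# shared fixtures, built lazily and memoised so expensive simulations run
# once per test session

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

big_lattice <- function() {
  fixture("big_lattice", function() build_lattice(c(600, 600), seed = 1))
}

# one clean bucket-bridging wave: fully directed, noise-free
big_sim_p1 <- function() {
  fixture("big_sim_p1", function()
    simulate_wave(big_lattice(), wave_params(p_directed = 1, noise_sd = 0,
                                             seed = 2)))
}

big_res_p1 <- function() {
  fixture("big_res_p1", function() run_pipeline(big_sim_p1()))
}

# identity strength coupling (every follower flips as hard as its trigger)
big_sim_k1 <- function() {
  fixture("big_sim_k1", function()
    simulate_wave(big_lattice(), wave_params(p_directed = 1, noise_sd = 0,
                                             k_couple = 1, seed = 5)))
}

big_res_k1 <- function() {
  fixture("big_res_k1", function() run_pipeline(big_sim_k1()))
}

# <= 50-agent instance for brute-force oracle comparisons
small_lattice <- function() {
  fixture("small_lattice", function() build_lattice(c(180, 160), seed = 7))
}

small_sim <- function() {
  fixture("small_sim", function()
    simulate_wave(small_lattice(), wave_params(p_directed = 0.7, seed = 8)))
}

small_res <- function() {
  fixture("small_res", function() run_pipeline(small_sim()))
}

# n agents in a row along +x, used for deterministic chain scenarios
line_agents <- function(n = 5, spacing = 30) {
  as_agent_set(data.frame(x_mm = (seq_len(n) - 1) * spacing, y_mm = 0))
}

# minimal hand-built incident table with the columns the neighbourhood and
# analysis stages expect
make_incidents <- function(agent_id, t0, wave_id = 1L, role = "focus",
                           dir_trig = NA_integer_, trigger_id = NA_integer_,
                           c_ws = 3L, peak_rel = 4, dir_wav = NA_integer_) {
  data.frame(agent_id = agent_id, t0 = t0, t1 = t0 + 1L,
             peak_rel = peak_rel, baseline = 1.08, c_ws = c_ws,
             wave_id = wave_id, trigger_id = trigger_id,
             dir_trig = dir_trig, role = role, dir_wav = dir_wav)
}
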