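#' Parameters of the shimmering-wave simulator
#'
#' Bundles the tunable parameters of the agent-based excitable-media
#' simulator.  The defaults describe the field conditions the pipeline is
#' designed for: 60 fps recording, an abdomen-flipping pulse of 200 ms,
#' a refractory phase of 800 ms, a quiescent motion-energy baseline of 1.08
#' on the 10^4-normalized scale, and per-agent peak excesses distributed so
#' that mid-level wave strengths dominate.
#'
#' `p_directed` is the probability that an agent joining the wave is driven
#' by classic bucket bridging (its nearest recently active near neighbour
#' triggers it with a fixed latency).  With probability `1 - p_directed` the
#' agent instead responds to a non-mechanical cue: its recorded trigger
#' direction is drawn uniformly over the 8 sectors and its join is delayed by
#' a random number of frames (up to `random_delay_frames`), which blurs the
#' wave front the way undirected participation does in the field.
#'
#' `k_couple` is the strength-coupling coefficient: an incident's peak excess
#' is `k_couple * (trigger peak excess) + (1 - k_couple) * (agent's own base
#' excess) + noise`, so `k_couple = 1` is identity transfer and `k_couple = 0`
#' is fully autonomous strength choice.
#'
#' @param dir_true key wave direction 1..4 (default 3, from Left to Right).
#' @param p_directed probability of a bucket-bridging (directed) join, in
#'   `[0, 1]`.
#' @param k_couple strength-coupling coefficient in `[0, 1]`.
#' @param latency_frames frames between a trigger's onset and the follower's
#'   onset (>= 1; default 3, i.e. 50 ms at 60 fps).
#' @param refractory_ms refractory phase after onset (default 800 ms; must
#'   exceed `pulse_ms`).
#' @param pulse_ms duration of the abdomen-flipping pulse (default 200 ms).
#' @param noise_sd baseline motion noise (sd, normalized units) applied both
#'   per frame and to peak amplitudes.
#' @param fps frame rate (default 60).
#' @param baseline quiescent normalized motion level (default 1.08).
#' @param amp_meanlog,amp_sdlog lognormal parameters of the per-agent base
#'   peak excess; the defaults centre the wave-strength levels at c_ws 2-4.
#' @param rise_ms duration of the sharp onset rise of the pulse (default
#'   40 ms: the peak is reached within 2-3 frames at 60 fps).
#' @param tail_frac amplitude fraction of the damped post-pulse oscillation
#'   (0 disables the tail).
#' @param passive_frac fraction of the mean near-neighbour pulse activity
#'   superimposed on every agent's trace as passive deflection of the bee
#'   curtain; produces the slow sub-threshold build-up preceding an onset
#'   (0 disables it).
#' @param random_delay_frames maximal extra join delay of undirected joiners.
#' @param n_waves number of generator bursts (waves) to simulate.
#' @param wave_interval_frames frames between generator bursts (default: the
#'   refractory period, i.e. saturation driving).
#' @param gen_band_mm width of the edge band whose agents act as generator
#'   cohort (default: the lattice spacing).
#' @param seed integer seed; every source of randomness in the simulator is
#'   governed by it.
#' @return a list of class `wave_params`.
#' @export
wave_params <- function(dir_true = 3L, p_directed = 0.35, k_couple = 0.3,
                        latency_frames = 3L, refractory_ms = 800,
                        pulse_ms = 200, noise_sd = 0.05, fps = 60,
                        baseline = 1.08, amp_meanlog = log(3),
                        amp_sdlog = 0.45, rise_ms = 40, tail_frac = 0.25,
                        passive_frac = 0.3,
                        random_delay_frames = 12L, n_waves = 1L,
                        wave_interval_frames = NULL, gen_band_mm = NULL,
                        seed = 1L) {
  stopifnot(dir_true %in% 1:4, p_directed >= 0, p_directed <= 1,
            k_couple >= 0, k_couple <= 1, latency_frames >= 1,
            refractory_ms > pulse_ms, fps > 0, n_waves >= 1)
  p <- list(dir_true = as.integer(dir_true), p_directed = p_directed,
            k_couple = k_couple, latency_frames = as.integer(latency_frames),
            refractory_ms = refractory_ms, pulse_ms = pulse_ms,
            noise_sd = noise_sd, fps = fps, baseline = baseline,
            amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
            rise_ms = rise_ms, tail_frac = tail_frac,
            passive_frac = passive_frac,
            random_delay_frames = as.integer(random_delay_frames),
            n_waves = as.integer(n_waves),
            wave_interval_frames = wave_interval_frames,
            gen_band_mm = gen_band_mm, seed = as.integer(seed))
  class(p) <- "wave_params"
  p
}

# abdomen-flip motion pulse sampled on frames: sharp rise peaking within
# ~40 ms, then a raised-cosine decay over the rest of the flip; the sampled
# maximum is exactly 1, so a simulated peak equals its nominal amplitude
pulse_shape <- function(n_frames, rise_frames = 2L, tail_frac = 0,
                        tail_frames = 0) {
  rise_frames <- max(1L, min(rise_frames, n_frames - 1L))
  decay_n <- n_frames - rise_frames
  s <- c((seq_len(rise_frames) / rise_frames)^0.3,
         0.5 * (1 + cos(pi * seq_len(decay_n) / decay_n)))
  if (tail_frac > 0 && tail_frames > 0) {
    tt <- seq_len(tail_frames)
    tail <- tail_frac * exp(-3 * tt / tail_frames) *
      sin(pi * tt / (n_frames / 2))^2
    s <- c(s, tail)
  }
  s
}

#' Promote a position table to an agent set
#'
#' @param df data.frame with columns `x_mm`, `y_mm` (and optionally
#'   `agent_id`, `z_mm`).
#' @param mm_per_px image scale for derived pixel positions.
#' @param spacing_mm nominal inter-agent spacing (used e.g. to size the
#'   generator band).
#' @return an `agent_set`.
#' @export
as_agent_set <- function(df, mm_per_px = 0.30, spacing_mm = 29) {
  stopifnot(all(c("x_mm", "y_mm") %in% names(df)))
  if (is.null(df$agent_id)) df$agent_id <- seq_len(nrow(df))
  if (is.null(df$z_mm)) df$z_mm <- 0
  df$x_px <- as.integer(round(df$x_mm / mm_per_px))
  df$y_px <- as.integer(round(df$y_mm / mm_per_px))
  attr(df, "mm_per_px") <- mm_per_px
  attr(df, "extent_mm") <- c(max(df$x_mm), max(df$y_mm))
  attr(df, "spacing_mm") <- spacing_mm
  class(df) <- c("agent_set", "data.frame")
  df
}

# rows of the generator cohort: agents within the band at the edge the wave
# comes from (dir 1 from Right -> right edge, 2 from Bottom -> bottom, ...)
generator_rows <- function(agents, dir_true, band_mm) {
  x <- agents$x_mm; y <- agents$y_mm
  switch(dir_true,
         which(x >= max(x) - band_mm),  # from Right
         which(y >= max(y) - band_mm),  # from Bottom
         which(x <= min(x) + band_mm),  # from Left
         which(y <= min(y) + band_mm))  # from Top
}

#' Simulate shimmering waves with known ground truth
#'
#' Discrete-time excitable-media simulation on an agent set.  A cohort of
#' generator agents on the edge the wave comes from fires in bursts; an
#' inactive, non-refractory agent joins the wave once a near neighbour
#' (r < 40 mm) fired `latency_frames` frames earlier.  With probability
#' `p_directed` the join is recorded as triggered by the nearest such
#' neighbour; otherwise the agent responds to an undirected cue: its recorded
#' trigger sector is uniform over 1..8 (the trigger agent being the nearest
#' far neighbour in that sector) and its onset is delayed by a uniform random
#' number of frames.  Each incident emits a raised-cosine motion pulse of
#' `pulse_ms` with an optional damped oscillation tail; the peak excess
#' couples to the trigger's peak through `k_couple`.  After its onset an
#' agent is refractory for `refractory_ms`.
#'
#' @param agents an `agent_set`.
#' @param params a `wave_params` list.
#' @return a `shimmer_sim` list: `traces` (frames x agents matrix of
#'   normalized motion energy), `agents`, `params`, `fps`, and `truth` with
#'   `incidents` (agent_id, t0 in 0-based frames, wave, amp, peak_rel,
#'   trigger_id, dir_trig, generator) and `dir_true`.  Waves that never leave
#'   the generator cohort are flagged via `truth$empty`.
#' @export
simulate_wave <- function(agents, params = wave_params()) {
  stopifnot(inherits(agents, "agent_set"))
  p <- params
  set.seed(p$seed)
  n <- nrow(agents)
  fpm <- p$fps / 1000
  refr <- as.integer(round(p$refractory_ms * fpm))
  npulse <- as.integer(round(p$pulse_ms * fpm))
  interval <- if (is.null(p$wave_interval_frames)) refr else
    as.integer(p$wave_interval_frames)
  band <- if (is.null(p$gen_band_mm)) attr(agents, "spacing_mm") else
    p$gen_band_mm
  spacing <- attr(agents, "spacing_mm")
  near <- neighbor_index(agents, 40)
  far <- neighbor_index(agents, 100)

  gens <- generator_rows(agents, p$dir_true, band)
  burn_in <- 10L
  hop <- p$latency_frames +
    ceiling((1 - p$p_directed) * p$random_delay_frames) + 1L
  travel <- (ceiling(max(attr(agents, "extent_mm")) / spacing) + 2L) * hop
  n_frames <- burn_in + (p$n_waves - 1L) * interval + travel + npulse +
    p$random_delay_frames + 2L * npulse + 20L

  base_amp <- stats::rlnorm(n, p$amp_meanlog, p$amp_sdlog)
  last_t0 <- rep(-1e9L, n)      # most recent onset frame per agent
  last_amp <- base_amp          # most recent incident peak excess
  pending <- rep(NA_integer_, n) # scheduled onset frame of delayed joiners
  pending_wave <- rep(NA_integer_, n)
  fired_at <- vector("list", n_frames)  # rows that fired per frame (1-based f)
  wave_of_last <- rep(NA_integer_, n)

  inc_agent <- integer(); inc_t0 <- integer(); inc_wave <- integer()
  inc_amp <- numeric(); inc_trig <- integer(); inc_dir <- integer()
  inc_gen <- logical()

  record <- function(i, f, wave, amp, trig, dir, gen) {
    inc_agent[[length(inc_agent) + 1L]] <<- agents$agent_id[i]
    inc_t0[[length(inc_t0) + 1L]] <<- f
    inc_wave[[length(inc_wave) + 1L]] <<- wave
    inc_amp[[length(inc_amp) + 1L]] <<- amp
    inc_trig[[length(inc_trig) + 1L]] <<- trig
    inc_dir[[length(inc_dir) + 1L]] <<- dir
    inc_gen[[length(inc_gen) + 1L]] <<- gen
    last_t0[i] <<- f
    last_amp[i] <<- amp
    wave_of_last[i] <<- wave
    if (f + 1L <= n_frames)
      fired_at[[f + 1L]] <<- c(fired_at[[f + 1L]], i)
  }

  gen_frames <- burn_in + (seq_len(p$n_waves) - 1L) * interval

  for (f in 0:(n_frames - 1L)) {
    # generator bursts
    w <- match(f, gen_frames)
    if (!is.na(w)) {
      for (i in gens) {
        if (f - last_t0[i] >= refr) {
          amp <- max(0, base_amp[i] + stats::rnorm(1, 0, p$noise_sd))
          record(i, f, w, amp, NA_integer_, NA_integer_, TRUE)
        }
      }
    }
    # delayed (undirected) joiners whose scheduled onset is now
    due <- which(!is.na(pending) & pending == f)
    for (i in due) {
      pending[i] <- NA_integer_
      if (f - last_t0[i] < refr) next
      s <- sample.int(8L, 1L)
      cand <- far[[i]]
      trig <- NA_integer_
      if (length(cand)) {
        secs <- sector_of(c(agents$x_mm[i], agents$y_mm[i]),
                          cbind(agents$x_mm[cand], agents$y_mm[cand]))
        pool <- cand[secs == s]
        if (!length(pool)) pool <- cand
        d <- (agents$x_mm[pool] - agents$x_mm[i])^2 +
          (agents$y_mm[pool] - agents$y_mm[i])^2
        trig <- pool[which.min(d)]
      }
      trig_amp <- if (!is.na(trig)) last_amp[trig] else base_amp[i]
      amp <- max(0, p$k_couple * trig_amp + (1 - p$k_couple) * base_amp[i] +
                   stats::rnorm(1, 0, p$noise_sd))
      record(i, f, pending_wave[i], amp,
             if (is.na(trig)) NA_integer_ else agents$agent_id[trig],
             s, FALSE)
    }
    # propagation: agents cued by neighbours that fired latency frames ago
    src_f <- f - p$latency_frames
    if (src_f >= 0 && src_f + 1L <= n_frames) {
      srcs <- fired_at[[src_f + 1L]]
      if (length(srcs)) {
        cands <- unique(unlist(near[srcs]))
        for (i in cands) {
          if (!is.na(pending[i])) next
          if (f - last_t0[i] < refr) next
          nb <- near[[i]]
          just <- nb[last_t0[nb] == src_f]
          if (!length(just)) next
          d <- (agents$x_mm[just] - agents$x_mm[i])^2 +
            (agents$y_mm[just] - agents$y_mm[i])^2
          j <- just[which.min(d)]
          if (stats::runif(1) < p$p_directed) {
            amp <- max(0, p$k_couple * last_amp[j] +
                         (1 - p$k_couple) * base_amp[i] +
                         stats::rnorm(1, 0, p$noise_sd))
            dir <- sector_of(c(agents$x_mm[i], agents$y_mm[i]),
                             c(agents$x_mm[j], agents$y_mm[j]))
            record(i, f, wave_of_last[j], amp, agents$agent_id[j], dir, FALSE)
          } else {
            pending[i] <- f +
              sample.int(p$random_delay_frames + 1L, 1L) - 1L
            pending_wave[i] <- wave_of_last[j]
          }
        }
      }
    }
  }

  truth <- data.frame(agent_id = inc_agent, t0 = inc_t0, wave = inc_wave,
                      amp = inc_amp, peak_rel = p$baseline + inc_amp,
                      trigger_id = inc_trig, dir_trig = inc_dir,
                      generator = inc_gen)
  empty <- !any(!truth$generator)
  if (empty && nrow(truth) == 0L)
    warning("no generator reachable: empty wave")

  # assemble traces: baseline + noise + active pulses + passive coupling
  shape <- pulse_shape(npulse, max(1L, as.integer(round(p$rise_ms * fpm))),
                       p$tail_frac, npulse)
  active <- matrix(0, n_frames, n)
  for (k in seq_len(nrow(truth))) {
    i <- match(truth$agent_id[k], agents$agent_id)
    # first pulse sample at frame t0+1 (matrix row t0+2): the onset frame t0
    # is, by definition, the frame before the sharp rise
    fr <- truth$t0[k] + 1L + seq_along(shape)
    keep <- fr <= n_frames
    active[fr[keep], i] <- active[fr[keep], i] + truth$amp[k] * shape[keep]
  }
  traces <- matrix(p$baseline, n_frames, n) + active
  if (p$passive_frac > 0) {
    for (i in seq_len(n)) {
      nb <- near[[i]]
      if (length(nb))
        traces[, i] <- traces[, i] +
          p$passive_frac * rowMeans(active[, nb, drop = FALSE])
    }
  }
  if (p$noise_sd > 0)
    traces <- traces + matrix(stats::rnorm(n_frames * n, 0, p$noise_sd),
                              n_frames, n)

  out <- list(traces = traces, agents = agents, params = p, fps = p$fps,
              truth = list(incidents = truth, dir_true = p$dir_true,
                           empty = empty, base_amp = base_amp,
                           generator_rows = gens))
  class(out) <- "shimmer_sim"
  out
}

#' @export
print.shimmer_sim <- function(x, ...) {
  tr <- x$truth$incidents
  cat(sprintf(
    "shimmer_sim: %d agents, %d frames at %g fps, dir_true=%d\n",
    ncol(x$traces), nrow(x$traces), x$fps, x$truth$dir_true))
  cat(sprintf("  %d incidents (%d generator, %d triggered), %d wave burst(s)\n",
              nrow(tr), sum(tr$generator), sum(!tr$generator),
              length(unique(tr$wave))))
  invisible(x)
}

#' Per-agent motion traces of a simulation as a long table
#'
#' @param sim a `shimmer_sim`.
#' @return data.frame with columns `frame` (0-based), `agent_id`, `rel_xymov`.
#' @export
sim_traces <- function(sim) {
  n_frames <- nrow(sim$traces)
  data.frame(
    frame = rep(0:(n_frames - 1L), times = ncol(sim$traces)),
    agent_id = rep(sim$agents$agent_id, each = n_frames),
    rel_xymov = as.vector(sim$traces))
}

#' Agent track table of a simulation
#'
#' Static thorax positions replicated per frame, in the CSV layout the
#' motion-metric stage expects.
#'
#' @param sim a `shimmer_sim`.
#' @return data.frame `(frame, agent_id, x_px, y_px, x_mm, y_mm, z_mm)`.
#' @export
sim_tracks <- function(sim) {
  n_frames <- nrow(sim$traces)
  a <- sim$agents
  data.frame(
    frame = rep(0:(n_frames - 1L), times = nrow(a)),
    agent_id = rep(a$agent_id, each = n_frames),
    x_px = rep(a$x_px, each = n_frames),
    y_px = rep(a$y_px, each = n_frames),
    x_mm = rep(a$x_mm, each = n_frames),
    y_mm = rep(a$y_mm, each = n_frames),
    z_mm = rep(a$z_mm, each = n_frames))
}
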