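#' Group incidents into waves by temporal clustering
#'
#' Incidents are sorted by onset; a gap larger than the refractory window
#' starts a new wave.
#'
#' @param incidents data.frame with `t0` (0-based frames).
#' @param gap_frames minimal inter-wave gap (default 48 frames = 800 ms at
#'   60 fps).
#' @return the incidents with a `wave_id` column (1-based, in time order).
#' @export
assign_waves <- function(incidents, gap_frames = 48L) {
  if (!nrow(incidents)) {
    incidents$wave_id <- integer()
    return(incidents)
  }
  o <- order(incidents$t0)
  w <- cumsum(c(TRUE, diff(incidents$t0[o]) > gap_frames))
  incidents$wave_id[o] <- w
  incidents
}

#' Assign the trigger neighbour of each incident
#'
#' Implements the three trigger rules: (a) a candidate trigger must have
#' joined the same wave at most `max_lag` frames (default 5, ~83 ms at
#' 60 fps) before the focus bee and strictly earlier; (b) among candidates in
#' the near neighbourhood (r < `near_mm`) the spatially closest is the
#' trigger; (c) the trigger direction is the angular sector (1..8) in which
#' the trigger neighbour is positioned.  Ties in distance are broken by
#' earlier onset, then lower agent_id.  Incidents without a candidate are
#' untriggered-active (members of an alternative spreading mechanism) and
#' carry no trigger direction.
#'
#' @param incidents data.frame with `agent_id`, `t0`, `wave_id`.
#' @param agents an `agent_set`.
#' @param near_mm near-neighbourhood radius (default 40).
#' @param max_lag maximal trigger lag in frames (default 5).
#' @return the incidents with columns `trigger_id`, `dir_trig`, `role`
#'   (`"focus"` or `"untriggered-active"`).
#' @export
assign_triggers <- function(incidents, agents, near_mm = 40, max_lag = 5L) {
  n <- nrow(incidents)
  incidents$trigger_id <- rep(NA_integer_, n)
  incidents$dir_trig <- rep(NA_integer_, n)
  incidents$role <- rep("untriggered-active", n)
  if (!n) return(incidents)
  ai <- match(incidents$agent_id, agents$agent_id)
  x <- agents$x_mm[ai]; y <- agents$y_mm[ai]
  for (k in seq_len(n)) {
    dt <- incidents$t0[k] - incidents$t0
    cand <- which(dt > 0 & dt <= max_lag &
                    incidents$wave_id == incidents$wave_id[k] &
                    incidents$agent_id != incidents$agent_id[k])
    if (!length(cand)) next
    d <- sqrt((x[cand] - x[k])^2 + (y[cand] - y[k])^2)
    cand <- cand[d < near_mm]
    d <- d[d < near_mm]
    if (!length(cand)) next
    o <- order(d, incidents$t0[cand], incidents$agent_id[cand])
    j <- cand[o[1]]
    incidents$trigger_id[k] <- incidents$agent_id[j]
    incidents$dir_trig[k] <- sector_of(c(x[k], y[k]), c(x[j], y[j]))
    incidents$role[k] <- "focus"
  }
  incidents
}

#' Classify the key direction of each wave
#'
#' Automated surrogate for the visual labelling of wave direction: a
#' least-squares plane `t0 ~ a + b*x + c*y` is fitted to the incident onsets;
#' the gradient `(b, c)` points towards later onsets, so the wave *comes
#' from* the opposite direction, which is snapped to the nearest of the four
#' key directions (1 from Right to Left, 2 from Bottom to Top, 3 from Left
#' to Right, 4 from Top to Bottom).  Waves with fewer than `min_incidents`
#' members, all-equal onsets or a vanishing gradient are flagged undefined.
#'
#' @param incidents data.frame with `agent_id`, `t0`, `wave_id`.
#' @param agents an `agent_set`.
#' @param min_incidents minimal wave size for a fit (default 10).
#' @param override optional named vector `wave_id -> dir` honouring a manual
#'   labelling.
#' @return data.frame `(wave_id, dir_wav, alpha_wav, n, defined)`;
#'   `alpha_wav` is the fitted source angle in degrees.
#' @export
classify_wave_direction <- function(incidents, agents, min_incidents = 10L,
                                    override = NULL) {
  ai <- match(incidents$agent_id, agents$agent_id)
  x <- agents$x_mm[ai]; y <- agents$y_mm[ai]
  waves <- sort(unique(incidents$wave_id))
  res <- lapply(waves, function(w) {
    sel <- incidents$wave_id == w
    nw <- sum(sel)
    if (!is.null(override) && as.character(w) %in% names(override))
      return(data.frame(wave_id = w,
                        dir_wav = as.integer(override[[as.character(w)]]),
                        alpha_wav = wave_angle(override[[as.character(w)]]),
                        n = nw, defined = TRUE))
    undef <- data.frame(wave_id = w, dir_wav = NA_integer_,
                        alpha_wav = NA_real_, n = nw, defined = FALSE)
    if (nw < min_incidents) return(undef)
    t0 <- incidents$t0[sel]
    if (length(unique(t0)) == 1L) return(undef)
    fit <- stats::lm.fit(cbind(1, x[sel], y[sel]), t0)
    b <- fit$coefficients[2]; c <- fit$coefficients[3]
    if (!is.finite(b) || !is.finite(c) || (b^2 + c^2) < 1e-12) return(undef)
    src <- atan2(-c, -b) * 180 / pi        # direction the wave comes from
    dir <- (round((src %% 360) / 90) %% 4) + 1L
    data.frame(wave_id = w, dir_wav = as.integer(dir),
               alpha_wav = src %% 360, n = nw, defined = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Attach wave directions to incidents
#'
#' @param incidents incidents with `wave_id`.
#' @param wave_dirs output of [classify_wave_direction()].
#' @return incidents with a `dir_wav` column (`NA` for undefined waves).
#' @export
attach_wave_direction <- function(incidents, wave_dirs) {
  incidents$dir_wav <-
    wave_dirs$dir_wav[match(incidents$wave_id, wave_dirs$wave_id)]
  incidents
}
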