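#' Pipeline configuration
#'
#' Collects every tunable physical and analysis parameter with the field
#' defaults: 60 fps recording (16.67 ms frame interval), 0.30 mm/px image
#' scale, 60 x 60 px ROI, 40/100 mm near/far neighbourhood radii, a
#' participation threshold of +1.0 normalized units held for 5 frames, the
#' 800 ms refractory merge window, an 83 ms (5-frame) trigger lag, and a
#' 250 ms pre-onset activity window.
#'
#' @param fps frame rate.
#' @param mm_per_px image scale.
#' @param roi_px ROI side length in px.
#' @param near_mm,far_mm neighbourhood radii in mm.
#' @param thresh participation threshold (normalized units above baseline).
#' @param min_run minimal supra-threshold run (frames).
#' @param refractory_ms refractory phase; also the incident-merge and
#'   wave-splitting window.
#' @param max_lag trigger-rule lag in frames.
#' @param pre_window_frames pre-onset activity window (frames).
#' @param ws_bounds wave-strength level boundaries.
#' @param window_ms ensemble synchronization window.
#' @param thresholds transfer-time threshold grid.
#' @param poly_degree degree of the linearity fuzziness polynomial.
#' @param quiescent_frames optional 0-based frames declared quiescent for
#'   baseline estimation (NULL: per-trace median).
#' @param seed integer seed for any stochastic step.
#' @return list of class `shimmer_config`.
#' @export
shimmer_config <- function(fps = 60, mm_per_px = 0.30, roi_px = 60,
                           near_mm = 40, far_mm = 100, thresh = 1.0,
                           min_run = 5L, refractory_ms = 800, max_lag = 5L,
                           pre_window_frames = 15L,
                           ws_bounds = default_ws_bounds(),
                           window_ms = c(-200, 600),
                           thresholds = seq(1.0, 2.3, by = 0.1),
                           poly_degree = 4L, quiescent_frames = NULL,
                           seed = 1L) {
  stopifnot(fps > 0, mm_per_px > 0, roi_px > 0, near_mm > 0,
            far_mm > near_mm, thresh > 0, min_run >= 1, refractory_ms > 0)
  cfg <- list(fps = fps, mm_per_px = mm_per_px, roi_px = roi_px,
              near_mm = near_mm, far_mm = far_mm, thresh = thresh,
              min_run = as.integer(min_run), refractory_ms = refractory_ms,
              max_lag = as.integer(max_lag),
              pre_window_frames = as.integer(pre_window_frames),
              ws_bounds = ws_bounds, window_ms = window_ms,
              thresholds = thresholds, poly_degree = as.integer(poly_degree),
              quiescent_frames = quiescent_frames, seed = as.integer(seed))
  cfg$frame_ms <- 1000 / fps
  cfg$merge_frames <- as.integer(round(refractory_ms * fps / 1000))
  class(cfg) <- "shimmer_config"
  cfg
}

# FNV-1a hash of the serialized configuration, so every output can declare
# the configuration that produced it
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL, version = 2))
  a <- 1; b <- 0
  for (x in bytes) {
    a <- (a + x) %% 65521
    b <- (b + a) %% 65521
  }
  sprintf("%04x%04x", b, a)
}

#' Run the full single-agent shimmering analysis
#'
#' Orchestrates metric -> detection -> wave grouping -> trigger assignment ->
#' direction classification -> linearity / continuity / graduality /
#' time-course analyses.  Input is either a `shimmer_sim` (its trace matrix
#' is used directly), a list with `traces` (matrix or long table) and
#' `agents`, or a list with `frames` (stack), `tracks` and `agents`, in
#' which case the motion metric is computed first.
#'
#' @param input see above.
#' @param config a [shimmer_config()].
#' @return list of class `shimmer_result`: `incidents`, `wave_dirs`,
#'   `linearity` (histogram, coincidence, estimates), `continuity`,
#'   `graduality`, `curves`, `transfer` (per stratum + pooled), `speed`,
#'   `hallmarks`, `counts`, `config_hash`.
#' @export
run_pipeline <- function(input, config = shimmer_config()) {
  cfg <- config
  set.seed(cfg$seed)
  if (inherits(input, "shimmer_sim")) {
    traces <- input$traces
    agents <- input$agents
  } else if (!is.null(input$traces)) {
    traces <- input$traces
    if (is.data.frame(traces)) traces <- trace_matrix(traces)
    agents <- input$agents
  } else if (!is.null(input$frames)) {
    if (is.null(input$tracks) || is.null(input$agents))
      stop("stage 'metric' is missing inputs: frames require tracks and agents")
    long <- compute_traces(input$frames, input$tracks, roi_px = cfg$roi_px)
    traces <- trace_matrix(long)
    agents <- input$agents
  } else {
    stop("stage 'metric' is missing inputs: provide a simulation, traces or frames")
  }
  if (is.null(agents)) stop("stage 'detect' is missing inputs: agents")
  if (is.null(colnames(traces))) colnames(traces) <- agents$agent_id

  incidents <- detect_all(traces, ws_bounds = cfg$ws_bounds,
                          thresh = cfg$thresh, min_run = cfg$min_run,
                          merge_frames = cfg$merge_frames,
                          quiescent_frames = cfg$quiescent_frames)
  incidents <- assign_waves(incidents, gap_frames = cfg$merge_frames)
  incidents <- assign_triggers(incidents, agents, near_mm = cfg$near_mm,
                               max_lag = cfg$max_lag)
  wave_dirs <- classify_wave_direction(incidents, agents)
  incidents <- attach_wave_direction(incidents, wave_dirs)

  lin_hist <- suppressWarnings(linearity_histogram(incidents))
  coincidence <- test_coincidence(lin_hist)
  lin_est <- estimate_linearity(lin_hist, degree = cfg$poly_degree)
  continuity <- continuity_profile(incidents, agents, far_mm = cfg$far_mm,
                                   window_frames = cfg$pre_window_frames)
  graduality <- graduality_summary(incidents, agents, far_mm = cfg$far_mm,
                                   window_frames = cfg$pre_window_frames)
  curves <- synchronize(traces, incidents,
                        agent_ids = as.integer(colnames(traces)),
                        window_ms = cfg$window_ms, fps = cfg$fps)
  transfer <- lapply(curves, function(e) {
    if (is.null(e$nb)) return(NULL)
    transfer_time(e$fb, e$nb, thresholds = cfg$thresholds)
  })
  transfer <- transfer[!vapply(transfer, is.null, logical(1))]
  dts <- vapply(transfer, function(t) t$dt_ms, numeric(1))
  pooled_dt <- if (length(dts)) mean(dts, na.rm = TRUE) else NA_real_

  # mean focus-to-trigger distance for the propagation-speed estimate
  foc <- incidents[incidents$role == "focus", , drop = FALSE]
  dist_mm <- if (nrow(foc)) {
    fi <- match(foc$agent_id, agents$agent_id)
    ti <- match(foc$trigger_id, agents$agent_id)
    mean(sqrt((agents$x_mm[fi] - agents$x_mm[ti])^2 +
                (agents$y_mm[fi] - agents$y_mm[ti])^2))
  } else NA_real_
  speed <- if (is.finite(pooled_dt) && is.finite(dist_mm) && pooled_dt > 0)
    propagation_speed(dist_mm, pooled_dt) else
      list(speed_m_s = NA_real_, se_m_s = NA_real_)

  counts <- list(
    n_agents = nrow(agents),
    n_active = length(unique(incidents$agent_id[incidents$c_ws >= 1])),
    n_incidents = nrow(incidents),
    n_focus = sum(incidents$role == "focus"),
    n_untriggered = sum(incidents$role == "untriggered-active"))
  participation_pct <- 100 * counts$n_active / counts$n_agents
  focus_pct <- if (counts$n_incidents)
    100 * counts$n_focus / counts$n_incidents else NA_real_
  cs <- incidents$c_ws[incidents$role == "focus"]
  strength_pct <- if (length(cs)) c(
    weak = 100 * mean(cs == 1),
    mid = 100 * mean(cs %in% 2:3),
    strong = 100 * mean(cs >= 4)) else c(weak = NA, mid = NA, strong = NA)
  hallmarks <- hallmarks_report(
    participation_pct = participation_pct, focus_pct = focus_pct,
    linearity_pct = if (nrow(lin_est)) mean(lin_est$estimate_B) else NA_real_,
    continuity_pct = continuity$excess_rate,
    mid_pct = strength_pct[["mid"]], weak_pct = strength_pct[["weak"]],
    strong_pct = strength_pct[["strong"]])

  structure(list(incidents = incidents, wave_dirs = wave_dirs,
                 linearity = list(histogram = lin_hist,
                                  coincidence = coincidence,
                                  estimates = lin_est),
                 continuity = continuity, graduality = graduality,
                 curves = curves, transfer = transfer,
                 transfer_pooled_ms = pooled_dt,
                 mean_trigger_distance_mm = dist_mm, speed = speed,
                 counts = counts, hallmarks = hallmarks,
                 config = cfg, config_hash = config_hash(cfg)),
            class = "shimmer_result")
}

#' @export
print.shimmer_result <- function(x, ...) {
  cat(sprintf("shimmer_result (config %s)\n", x$config_hash))
  cat(sprintf("  %d incidents on %d agents; %d focus, %d untriggered-active\n",
              x$counts$n_incidents, x$counts$n_agents, x$counts$n_focus,
              x$counts$n_untriggered))
  def <- x$wave_dirs[x$wave_dirs$defined, ]
  cat(sprintf("  %d wave(s), directions: %s\n", nrow(x$wave_dirs),
              paste(def$dir_wav, collapse = " ")))
  if (nrow(x$linearity$estimates))
    cat(sprintf("  linearity estimate_B = %.2f%%; continuity excess = %.2f%%\n",
                mean(x$linearity$estimates$estimate_B),
                x$continuity$excess_rate))
  if (is.finite(x$transfer_pooled_ms))
    cat(sprintf("  transfer time %.2f ms over %.1f mm -> %.3f m/s\n",
                x$transfer_pooled_ms, x$mean_trigger_distance_mm,
                x$speed$speed_m_s))
  invisible(x)
}

#' Chain two percentage shares
#'
#' `chain_pct(a, b)` is the share of the whole covered by `b` percent of a
#' subset that itself covers `a` percent of the whole.
#'
#' @param a,b percentages.
#' @return percentage of the whole.
#' @examples
#' chain_pct(53.06, 75.72)  # 40.18 -- focus bees as a share of all surface bees
#' @export
chain_pct <- function(a, b) a * b / 100

#' Hallmark shares of bucket bridging
#'
#' Chains the pipeline's percentages into shares of all surface bees by
#' exact multiplication: the participation share, the focus-bee share of
#' participants, and from their product the linearity, continuity and
#' strength-class shares.
#'
#' @param participation_pct percent of identified agents participating
#'   (above-threshold strength).
#' @param focus_pct percent of participants triggered by a near neighbour.
#' @param linearity_pct directed share of focus incidents (estimate B).
#' @param continuity_pct active-neighbour excess rate in the trigger
#'   direction.
#' @param mid_pct,weak_pct,strong_pct strength-class shares of focus bees.
#' @return data.frame `(quantity, pct_of_subset, pct_of_all)` of class
#'   `hallmarks_report`.
#' @export
hallmarks_report <- function(participation_pct, focus_pct, linearity_pct,
                             continuity_pct, mid_pct = NA, weak_pct = NA,
                             strong_pct = NA) {
  focus_of_all <- chain_pct(participation_pct, focus_pct)
  out <- data.frame(
    quantity = c("participation", "focus", "linearity", "continuity",
                 "mid_strength", "weak_strength", "strong_strength"),
    pct_of_subset = c(participation_pct, focus_pct, linearity_pct,
                      continuity_pct, mid_pct, weak_pct, strong_pct),
    pct_of_all = c(participation_pct, focus_of_all,
                   chain_pct(focus_of_all, linearity_pct),
                   chain_pct(focus_of_all, continuity_pct),
                   chain_pct(focus_of_all, mid_pct),
                   chain_pct(focus_of_all, weak_pct),
                   chain_pct(focus_of_all, strong_pct)))
  class(out) <- c("hallmarks_report", "data.frame")
  out
}

#' @export
print.hallmarks_report <- function(x, digits = 2, ...) {
  cat("Hallmarks of bucket bridging (shares of all surface bees):\n")
  y <- as.data.frame(x)
  y$pct_of_subset <- round(y$pct_of_subset, digits)
  y$pct_of_all <- round(y$pct_of_all, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
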