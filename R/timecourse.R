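# ensemble of trace segments aligned at per-incident reference frames
ensemble_curve <- function(traces, cols, ref_frames, window_frames, fps) {
  offs <- window_frames[1]:window_frames[2]
  n_frames <- nrow(traces)
  m <- matrix(NA_real_, length(offs), length(cols))
  for (k in seq_along(cols)) {
    fr <- ref_frames[k] + offs + 1L    # 0-based frame -> matrix row
    ok <- fr >= 1 & fr <= n_frames
    m[ok, k] <- traces[fr[ok], cols[k]]
  }
  n <- rowSums(!is.na(m))
  mean_v <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, stats::sd, na.rm = TRUE)
  data.frame(t_ms = offs * 1000 / fps, mean = mean_v,
             se = ifelse(n > 1, sdv / sqrt(n), 0), n = n)
}

#' Ensemble time courses of focus bees and their trigger neighbours
#'
#' Synchronizes every focus incident at its own time zero and averages the
#' motion traces on a common relative grid (default -200..+600 ms), per
#' wave-strength level.  The trigger-neighbour curve of a stratum is built
#' from the traces of the assigned trigger neighbours, also aligned to the
#' *focus bee's* time zero, and restricted to trigger incidents of the same
#' wave-strength level as the focus bee.
#'
#' @param traces frames x agents matrix (columns in `agent_ids` order).
#' @param incidents incidents with `agent_id`, `t0`, `role`, `trigger_id`,
#'   `wave_id`, `c_ws`.
#' @param agent_ids agent ids of the trace columns.
#' @param window_ms relative window (default `c(-200, 600)`).
#' @param fps frame rate (default 60).
#' @param c_ws_levels strata (default 1..6).
#' @return list of class `ensemble_curves`: per stratum a list with `fb` and
#'   `nb` curve data.frames `(t_ms, mean, se, n)`.
#' @export
synchronize <- function(traces, incidents, agent_ids = NULL,
                        window_ms = c(-200, 600), fps = 60,
                        c_ws_levels = 1:6) {
  if (is.null(agent_ids)) {
    agent_ids <- if (!is.null(colnames(traces)))
      as.integer(colnames(traces)) else seq_len(ncol(traces))
  }
  wf <- round(window_ms * fps / 1000)
  out <- lapply(c_ws_levels, function(lv) {
    foc <- incidents[incidents$role == "focus" & incidents$c_ws == lv, ,
                     drop = FALSE]
    if (!nrow(foc)) return(NULL)
    fb <- ensemble_curve(traces, match(foc$agent_id, agent_ids), foc$t0,
                         wf, fps)
    # trigger incidents at the same strength level, aligned to focus t0
    nb_cols <- integer(0); nb_ref <- integer(0)
    for (k in seq_len(nrow(foc))) {
      j <- which(incidents$agent_id == foc$trigger_id[k] &
                   incidents$wave_id == foc$wave_id[k] &
                   incidents$t0 < foc$t0[k])
      if (!length(j)) next
      j <- j[which.max(incidents$t0[j])]
      if (incidents$c_ws[j] != lv) next
      nb_cols <- c(nb_cols, match(foc$trigger_id[k], agent_ids))
      nb_ref <- c(nb_ref, foc$t0[k])
    }
    nb <- if (length(nb_cols))
      ensemble_curve(traces, nb_cols, nb_ref, wf, fps) else NULL
    list(c_ws = lv, fb = fb, nb = nb, n_fb = nrow(foc), n_nb = length(nb_cols))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  names(out) <- vapply(out, function(e) as.character(e$c_ws), character(1))
  structure(out, class = "ensemble_curves")
}

#' @export
print.ensemble_curves <- function(x, ...) {
  cat("Ensemble time courses per wave-strength level:\n")
  for (e in x)
    cat(sprintf("  c_ws = %d: %d focus incidents, %d trigger-neighbour pairs\n",
                e$c_ws, e$n_fb, e$n_nb))
  invisible(x)
}

# time of the last upward crossing of `thresh` before the curve maximum,
# by linear interpolation; NA if the curve never crosses on the rise
crossing_time <- function(t_ms, v, thresh) {
  peak <- which.max(v)
  if (peak < 2 || v[peak] < thresh) return(NA_real_)
  below <- which(v[1:(peak - 1)] < thresh)
  if (!length(below)) return(NA_real_)
  i <- max(below)
  t_ms[i] + (thresh - v[i]) / (v[i + 1] - v[i]) * (t_ms[i + 1] - t_ms[i])
}

#' Transfer time between neighbour and focus-bee curves
#'
#' For each threshold level the rising-phase crossing times of both ensemble
#' curves are found by linear interpolation; the transfer time is the mean
#' (+/- SE) over thresholds of the focus crossing minus the neighbour
#' crossing.  Thresholds that either curve does not cross are excluded and
#' counted.  A cross-correlation lag of the two mean curves is reported as
#' an independent cross-check.
#'
#' @param fb_curve,nb_curve data.frames `(t_ms, mean)` as produced by
#'   [synchronize()].
#' @param thresholds threshold grid (default `seq(1.0, 2.3, by = 0.1)`, the
#'   14 levels of the normalized motion scale).
#' @return list `(dt_ms, se_ms, n_used, n_excluded, per_threshold,
#'   xcorr_ms, reliable)`; `reliable` is `FALSE` with fewer than 3 usable
#'   thresholds.
#' @export
transfer_time <- function(fb_curve, nb_curve,
                          thresholds = seq(1.0, 2.3, by = 0.1)) {
  dts <- vapply(thresholds, function(th) {
    tf <- crossing_time(fb_curve$t_ms, fb_curve$mean, th)
    tn <- crossing_time(nb_curve$t_ms, nb_curve$mean, th)
    tf - tn
  }, numeric(1))
  ok <- !is.na(dts)
  n <- sum(ok)
  step <- stats::median(diff(fb_curve$t_ms))
  cc <- stats::ccf(fb_curve$mean, nb_curve$mean,
                   lag.max = min(30, nrow(fb_curve) - 2), plot = FALSE)
  xcorr_ms <- cc$lag[which.max(cc$acf)] * step
  list(dt_ms = if (n) mean(dts[ok]) else NA_real_,
       se_ms = if (n > 1) stats::sd(dts[ok]) / sqrt(n) else 0,
       n_used = n, n_excluded = sum(!ok),
       per_threshold = data.frame(threshold = thresholds, dt_ms = dts),
       xcorr_ms = xcorr_ms,
       reliable = n >= 3)
}

#' Propagation speed from distance and transfer time
#'
#' @param distance_mm mean focus-to-neighbour distance in mm.
#' @param transfer_ms transfer time in ms.
#' @param se_ms standard error of the transfer time (propagated to the
#'   speed by the delta method).
#' @return list `(speed_m_s, se_m_s)`.
#' @examples
#' propagation_speed(62, 47.29)  # ~1.311 m/s
#' @export
propagation_speed <- function(distance_mm, transfer_ms, se_ms = 0) {
  stopifnot(distance_mm > 0, transfer_ms > 0)
  speed <- distance_mm / transfer_ms        # mm/ms == m/s
  list(speed_m_s = speed, se_m_s = speed * se_ms / transfer_ms)
}
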