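#' Detect wave incidents in a motion trace
#'
#' A wave incident is a supra-threshold abdomen-flipping episode: the
#' supra-baseline excess of the motion trace must exceed the participation
#' threshold for at least `min_run` successive frames (default 5, which
#' excludes noise-triggered crossings).  `t1` is the first frame of the run
#' and the onset `t0` is defined one frame before it (`t0 = t1 - 1`).  Runs
#' closer together than the merge window (default the 800 ms refractory
#' phase) are merged into one incident.
#'
#' @param trace numeric vector of normalized motion energy (`rel_xymov`),
#'   sample `i` corresponding to 0-based frame `i - 1 + frame0`.
#' @param baseline quiescent level of this trace; `NULL` estimates it as the
#'   median over `quiescent_frames` (or of the whole trace), falling back to
#'   the global quiescent value 1.08 if no samples are available.
#' @param thresh participation threshold on the supra-baseline excess,
#'   in normalized units (default 1.0, i.e. 10^4 raw-sum units).
#' @param min_run minimal run length in frames (default 5).
#' @param merge_frames runs with onsets closer than this are merged
#'   (default 48 frames = 800 ms at 60 fps).
#' @param frame0 0-based frame index of the first sample (default 0).
#' @param quiescent_frames optional 0-based frame indices declared quiescent,
#'   used for the baseline estimate.
#' @return data.frame `(t0, t1, peak_rel, baseline)`, one row per incident
#'   (0-based frames); zero rows for an all-baseline trace.
#' @export
detect_incidents <- function(trace, baseline = NULL, thresh = 1.0,
                             min_run = 5L, merge_frames = 48L, frame0 = 0L,
                             quiescent_frames = NULL) {
  ok <- !is.na(trace)
  if (sum(ok) < min_run + 1L) return(empty_incidents())
  if (is.null(baseline)) {
    q <- if (is.null(quiescent_frames)) trace[ok] else
      trace[ok & (seq_along(trace) - 1L + frame0) %in% quiescent_frames]
    baseline <- if (length(q)) stats::median(q) else 1.08
  }
  supra <- !is.na(trace) & (trace - baseline > thresh)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(empty_incidents())
  t1 <- starts[keep] - 1L + frame0            # 0-based first supra frame
  peak <- mapply(function(s, e) max(trace[s:e]), starts[keep], ends[keep])
  # merge runs closer than the refractory/merge window
  o <- order(t1)
  t1 <- t1[o]; peak <- peak[o]
  grp <- cumsum(c(TRUE, diff(t1) >= merge_frames))
  t1m <- tapply(t1, grp, min)
  peakm <- tapply(peak, grp, max)
  data.frame(t0 = as.integer(t1m) - 1L, t1 = as.integer(t1m),
             peak_rel = as.numeric(peakm), baseline = baseline)
}

empty_incidents <- function() {
  data.frame(t0 = integer(), t1 = integer(), peak_rel = numeric(),
             baseline = numeric())
}

#' Detect incidents for every agent of a trace matrix
#'
#' @param traces frames x agents matrix (e.g. `sim$traces`) or a long table
#'   `(frame, agent_id, rel_xymov)`.
#' @param agent_ids agent ids of the matrix columns (default: column names
#'   or 1..n).
#' @param ... passed to [detect_incidents()].
#' @return data.frame `(agent_id, t0, t1, peak_rel, baseline, c_ws)` with
#'   wave-strength levels from [categorize_ws()] using the default bounds.
#' @param ws_bounds strength-level boundaries for [categorize_ws()].
#' @export
detect_all <- function(traces, agent_ids = NULL,
                       ws_bounds = default_ws_bounds(), ...) {
  if (is.data.frame(traces)) traces <- trace_matrix(traces)
  if (is.null(agent_ids)) {
    agent_ids <- if (!is.null(colnames(traces)))
      as.integer(colnames(traces)) else seq_len(ncol(traces))
  }
  res <- lapply(seq_len(ncol(traces)), function(j) {
    inc <- detect_incidents(traces[, j], ...)
    if (!nrow(inc)) return(NULL)
    cbind(agent_id = agent_ids[j], inc)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- cbind(agent_id = integer(), empty_incidents())
  out$c_ws <- categorize_ws(out$peak_rel, ws_bounds)
  rownames(out) <- NULL
  out
}

#' Default wave-strength level boundaries
#'
#' Eight strictly increasing boundaries expressed as multiples of the
#' quiescent level; an incident whose peak falls into the half-open interval
#' `[b_i, b_{i+1})` gets level `c_ws = i`, below `b_1` level 0
#' (non-participation), at or above `b_8` level 8.  The default multiples
#' place default simulations' mode at mid levels (c_ws 2-4).
#'
#' @param quiescent quiescent normalized level (default 1.08).
#' @param multiples eight increasing multipliers.
#' @return numeric vector of 8 boundaries.
#' @export
default_ws_bounds <- function(quiescent = 1.08,
                              multiples = c(1.5, 2, 3, 4.5, 6.5, 9, 12, 16)) {
  stopifnot(length(multiples) == 8, all(diff(multiples) > 0))
  quiescent * multiples
}

#' Wave-strength category of a peak value
#'
#' @param peak_rel peak normalized motion energy of the incident(s).
#' @param bounds 8 strictly increasing level boundaries
#'   (default [default_ws_bounds()]).
#' @return integer level(s) 0..8.
#' @export
categorize_ws <- function(peak_rel, bounds = default_ws_bounds()) {
  if (length(bounds) != 8 || any(diff(bounds) <= 0))
    stop("ws bounds must be 8 strictly increasing values")
  findInterval(peak_rel, bounds)
}

#' Repetition rate and refractory-phase estimate
#'
#' Under saturation driving, agents rejoin as soon as their refractory phase
#' ends, so the repetition rate is the reciprocal of the typical inter-onset
#' interval and the minimum observed interval estimates the refractory phase.
#'
#' @param incidents data.frame with `agent_id` and `t0` (0-based frames).
#' @param fps frame rate (default 60).
#' @return list `(rate_hz, refractory_ms, n_intervals)`; `NA`s when no agent
#'   has two or more incidents.
#' @export
repetition_rate <- function(incidents, fps = 60) {
  iv <- unlist(lapply(split(incidents$t0, incidents$agent_id), function(t) {
    if (length(t) < 2) return(NULL)
    diff(sort(t))
  }))
  if (is.null(iv) || !length(iv))
    return(list(rate_hz = NA_real_, refractory_ms = NA_real_,
                n_intervals = 0L))
  ms <- iv * 1000 / fps
  list(rate_hz = 1000 / stats::median(ms),
       refractory_ms = min(ms),
       n_intervals = length(iv))
}
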