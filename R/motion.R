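#' Pixel-wise difference image of two frames
#'
#' Absolute per-pixel luminance difference of two 8-bit grayscale frames,
#' the primitive behind the motion-energy metric: 0 means no change, 255 a
#' full black-to-white flip.
#'
#' @param frame_prev,frame_curr integer matrices of equal dimensions with
#'   values in 0..255 (rows = y, columns = x).
#' @return integer matrix of the same dimensions, values in 0..255.
#' @export
diff_image <- function(frame_prev, frame_curr) {
  if (!identical(dim(frame_prev), dim(frame_curr)))
    stop("frame dimensions differ")
  abs(frame_curr - frame_prev)
}

#' Motion energy over a region of interest
#'
#' Sums the difference image over a square ROI (default 60 x 60 px, i.e.
#' 18 x 18 mm at 0.30 mm/px) centred on an agent's thorax, and normalizes
#' by 10^4 so that the quiescent level of ~3 per pixel sums to
#' `rel_xymov = 1.08`.
#'
#' @param diff a difference image (integer matrix, rows = y).
#' @param center_px numeric length-2 `(x, y)` thorax position in 0-based
#'   pixel coordinates.
#' @param roi_px side length of the ROI in pixels (default 60).
#' @return list with `raw_sum` (integer) and `rel_xymov` (`raw_sum / 1e4`);
#'   `NULL` if the ROI is not fully inside the frame (edge agents are not
#'   evaluated).
#' @export
roi_motion <- function(diff, center_px, roi_px = 60) {
  half <- roi_px %/% 2
  x0 <- round(center_px[1]) - half + 1  # 1-based column range
  y0 <- round(center_px[2]) - half + 1
  x1 <- x0 + roi_px - 1
  y1 <- y0 + roi_px - 1
  if (x0 < 1 || y0 < 1 || x1 > ncol(diff) || y1 > nrow(diff))
    return(NULL)
  s <- sum(diff[y0:y1, x0:x1])
  list(raw_sum = s, rel_xymov = s / 1e4)
}

#' Per-agent motion traces from a frame stack
#'
#' Applies `diff_image` to each consecutive frame pair and `roi_motion` at
#' each agent's tracked position, yielding one motion trace per agent.  The
#' ROI is centred on the position at the *later* frame of each pair (the
#' frame on which onsets are defined).  Trace sample at frame `i` (0-based,
#' `i >= 1`) derives from frames `(i-1, i)`.
#'
#' @param stack list of frames (integer matrices, rows = y) or a 3-d array
#'   `[y, x, frame]`.
#' @param tracks data.frame with columns `frame` (0-based), `agent_id`,
#'   `x_px`, `y_px`.
#' @param roi_px ROI side length (default 60).
#' @param noise_floor optional per-pixel threshold subtracted from the
#'   difference image before summation (default 0 = off).
#' @return data.frame `(frame, agent_id, raw_sum, rel_xymov)`; samples with
#'   missing positions or ROIs clipped by the frame border are `NA`.
#' @export
compute_traces <- function(stack, tracks, roi_px = 60, noise_floor = 0) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  n_frames <- length(stack)
  stopifnot(n_frames >= 2)
  ids <- sort(unique(tracks$agent_id))
  out <- vector("list", n_frames - 1L)
  for (f in 1:(n_frames - 1L)) {
    d <- diff_image(stack[[f]], stack[[f + 1L]])
    if (noise_floor > 0) d <- pmax(d - noise_floor, 0)
    pos <- tracks[tracks$frame == f, , drop = FALSE]  # later frame, 0-based f
    raw <- rep(NA_real_, length(ids))
    for (k in seq_along(ids)) {
      r <- pos[pos$agent_id == ids[k], , drop = FALSE]
      if (nrow(r) != 1L) next
      m <- roi_motion(d, c(r$x_px, r$y_px), roi_px)
      if (!is.null(m)) raw[k] <- m$raw_sum
    }
    out[[f]] <- data.frame(frame = f, agent_id = ids, raw_sum = raw,
                           rel_xymov = raw / 1e4)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wide matrix view of a long trace table
#'
#' @param traces data.frame with `frame`, `agent_id` and a value column.
#' @param value name of the value column (default `rel_xymov`).
#' @return matrix frames x agents (rownames = frame, colnames = agent_id).
#' @export
trace_matrix <- function(traces, value = "rel_xymov") {
  ids <- sort(unique(traces$agent_id))
  frames <- sort(unique(traces$frame))
  m <- matrix(NA_real_, length(frames), length(ids),
              dimnames = list(frames, ids))
  m[cbind(match(traces$frame, frames), match(traces$agent_id, ids))] <-
    traces[[value]]
  m
}
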