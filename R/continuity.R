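#' Active-neighbour profile around the trigger direction
#'
#' For every focus incident, counts the far neighbours (r < `far_mm`) that
#' were active in the same wave before the focus bee (onset earlier by at
#' most `window_frames`), binned by the deviation of their sector from the
#' trigger sector (`delta_alpha` in 45-degree steps, -135..180).  Counts are
#' averaged per wave-strength level, normalized to a maximum of 1 per level,
#' and summarized into an excess rate: the relative surplus of neighbours in
#' the trigger sector over the mean of its two flanking sectors.
#'
#' @param incidents data.frame with `agent_id`, `t0`, `wave_id`, `role`,
#'   `dir_trig`, `c_ws`.
#' @param agents an `agent_set`.
#' @param far_mm far-neighbourhood radius (default 100).
#' @param window_frames pre-onset activity window (default 15 frames =
#'   250 ms at 60 fps).
#' @param c_ws_levels strength strata to profile (default 1..5).
#' @return list of class `continuity_profile`: `delta_alpha` (bin centres),
#'   `mean_n` (strata x 8 matrix of mean neighbour counts), `rel_n_nh`
#'   (normalized to max 1 per stratum), `pooled` (all strata), `excess_rate`
#'   (percent), `n_focus`.
#' @export
continuity_profile <- function(incidents, agents, far_mm = 100,
                               window_frames = 15L, c_ws_levels = 1:5) {
  sel <- which(incidents$role == "focus" & !is.na(incidents$dir_trig))
  ai <- match(incidents$agent_id, agents$agent_id)
  x <- agents$x_mm[ai]; y <- agents$y_mm[ai]
  bins <- c(-135, -90, -45, 0, 45, 90, 135, 180)
  counts <- matrix(0, length(c_ws_levels), 8,
                   dimnames = list(c_ws = c_ws_levels, delta_alpha = bins))
  nfoc <- stats::setNames(numeric(length(c_ws_levels)), c_ws_levels)
  pooled <- stats::setNames(numeric(8), bins)
  n_pooled <- 0
  for (k in sel) {
    nb <- which(incidents$wave_id == incidents$wave_id[k] &
                  incidents$t0 < incidents$t0[k] &
                  incidents$t0 >= incidents$t0[k] - window_frames &
                  incidents$agent_id != incidents$agent_id[k])
    if (length(nb)) {
      d <- sqrt((x[nb] - x[k])^2 + (y[nb] - y[k])^2)
      nb <- nb[d < far_mm]
    }
    h <- numeric(8)
    if (length(nb)) {
      sec <- sector_of(c(x[k], y[k]), cbind(x[nb], y[nb]))
      off <- sector_offset_deg(sec, incidents$dir_trig[k])
      h <- vapply(bins, function(b) sum(off == b), numeric(1))
    }
    lv <- match(incidents$c_ws[k], c_ws_levels)
    if (!is.na(lv)) {
      counts[lv, ] <- counts[lv, ] + h
      nfoc[lv] <- nfoc[lv] + 1
    }
    pooled <- pooled + h
    n_pooled <- n_pooled + 1
  }
  mean_n <- counts / pmax(nfoc, 1)
  rel <- mean_n / pmax(apply(mean_n, 1, max), 1e-12)
  pooled_mean <- pooled / max(n_pooled, 1)
  peak <- pooled_mean["0"]
  adj <- mean(pooled_mean[c("-45", "45")])
  excess <- if (peak > 0) 100 * (peak - adj) / peak else NA_real_
  structure(list(delta_alpha = bins, mean_n = mean_n, rel_n_nh = rel,
                 pooled = pooled_mean, excess_rate = as.numeric(excess),
                 n_focus = nfoc),
            class = "continuity_profile")
}

#' @export
print.continuity_profile <- function(x, digits = 2, ...) {
  cat("Active-neighbour profile (rel_n_Nh, rows = c_ws):\n")
  print(round(x$rel_n_nh, digits))
  cat(sprintf("excess rate in trigger direction: %.1f%% (n_focus = %d)\n",
              x$excess_rate, sum(x$n_focus)))
  invisible(x)
}
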