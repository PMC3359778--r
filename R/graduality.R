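#' Strength regression on sector neighbours or the trigger neighbour
#'
#' Pairs each focus incident's peak motion strength with a summary of the
#' strengths of its previously active far neighbours in a chosen sector:
#' the trigger sector (`mode = "ds"`, direct-sector analysis), the sector
#' 180 degrees opposite (`mode = "os"`), or the single assigned trigger
#' neighbour in the near neighbourhood (`mode = "tn"`).  The neighbour
#' statistic is the mean of the qualifying neighbours' peaks; qualifying
#' means active in the same wave before the focus onset, within the pre-onset
#' window, and inside the far neighbourhood (for `"tn"`, simply the trigger's
#' own incident).  Reports the Pearson correlation and the least-squares
#' slope of focus peak on neighbour peak.
#'
#' @param incidents data.frame with `agent_id`, `t0`, `wave_id`, `role`,
#'   `dir_trig`, `trigger_id`, `peak_rel`, `c_ws`.
#' @param agents an `agent_set`.
#' @param mode `"ds"`, `"os"` or `"tn"`.
#' @param far_mm far-neighbourhood radius (default 100).
#' @param window_frames pre-onset window in frames (default 15; applied to
#'   both `ds` and `os`).
#' @param subset optional logical vector selecting incidents (e.g. one
#'   strength level).
#' @return list `(mode, n, r, k, intercept, pairs)`; `r` is `NA` when fewer
#'   than 3 pairs exist or either variable has zero variance.
#' @export
sector_regression <- function(incidents, agents, mode = c("ds", "os", "tn"),
                              far_mm = 100, window_frames = 15L,
                              subset = NULL) {
  mode <- match.arg(mode)
  keep <- incidents$role == "focus" & !is.na(incidents$dir_trig)
  if (!is.null(subset)) keep <- keep & subset
  sel <- which(keep)
  ai <- match(incidents$agent_id, agents$agent_id)
  x <- agents$x_mm[ai]; y <- agents$y_mm[ai]
  fx <- numeric(0); nx <- numeric(0)
  for (k in sel) {
    if (mode == "tn") {
      j <- which(incidents$agent_id == incidents$trigger_id[k] &
                   incidents$wave_id == incidents$wave_id[k] &
                   incidents$t0 < incidents$t0[k])
      if (!length(j)) next
      j <- j[which.max(incidents$t0[j])]
      nb_stat <- incidents$peak_rel[j]
    } else {
      target <- if (mode == "ds") incidents$dir_trig[k] else
        opposite_sector(incidents$dir_trig[k])
      nb <- which(incidents$wave_id == incidents$wave_id[k] &
                    incidents$t0 < incidents$t0[k] &
                    incidents$t0 >= incidents$t0[k] - window_frames &
                    incidents$agent_id != incidents$agent_id[k])
      if (!length(nb)) next
      d <- sqrt((x[nb] - x[k])^2 + (y[nb] - y[k])^2)
      nb <- nb[d < far_mm]
      if (!length(nb)) next
      sec <- sector_of(c(x[k], y[k]), cbind(x[nb], y[nb]))
      nb <- nb[sec == target]
      if (!length(nb)) next
      nb_stat <- mean(incidents$peak_rel[nb])
    }
    fx <- c(fx, incidents$peak_rel[k])
    nx <- c(nx, nb_stat)
  }
  n <- length(fx)
  if (n < 3 || stats::sd(fx) == 0 || stats::sd(nx) == 0)
    return(list(mode = mode, n = n, r = NA_real_, k = NA_real_,
                intercept = NA_real_,
                pairs = data.frame(focus = fx, neighbour = nx)))
  fit <- stats::lm(fx ~ nx)
  list(mode = mode, n = n,
       r = stats::cor(fx, nx),
       k = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pairs = data.frame(focus = fx, neighbour = nx))
}

#' Graduality summary across strength levels
#'
#' Runs the direct-sector and opposite-sector regressions per wave-strength
#' level, converts each correlation into the share of agents governed by
#' gradual transfer (`100 * r^2`), and compares the matched `r_ds` and
#' `r_os` series with a paired t-test.
#'
#' @param incidents,agents as in [sector_regression()].
#' @param c_ws_levels strength levels to analyse (default 1..6).
#' @param ... passed to [sector_regression()].
#' @return list of class `graduality_summary`: `table` (per level: n, r, k,
#'   r_squared, percent_share for both modes), `mean_r_ds`, `mean_r_os`
#'   (+ standard errors), `t_test` (paired, on levels where both defined).
#' @export
graduality_summary <- function(incidents, agents, c_ws_levels = 1:6, ...) {
  rows <- lapply(c_ws_levels, function(lv) {
    sub <- incidents$c_ws == lv
    res <- lapply(c("ds", "os"), function(m) {
      fit <- sector_regression(incidents, agents, mode = m, subset = sub, ...)
      data.frame(c_ws = lv, mode = m, n = fit$n, r = fit$r, k = fit$k,
                 r_squared = fit$r^2, percent_share = 100 * fit$r^2)
    })
    do.call(rbind, res)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  rds <- tab$r[tab$mode == "ds"]
  ros <- tab$r[tab$mode == "os"]
  ok <- !is.na(rds) & !is.na(ros)
  tt <- NULL
  if (sum(ok) >= 2) {
    d <- rds[ok] - ros[ok]
    if (stats::sd(d) > 0) {
      ht <- stats::t.test(rds[ok], ros[ok], paired = TRUE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
                 df = unname(ht$parameter))
    } else {
      # degenerate but well-defined: identical series differ by a constant
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 p.value = if (mean(d) == 0) 1 else 0,
                 df = sum(ok) - 1)
    }
  }
  se <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  structure(list(table = tab,
                 mean_r_ds = mean(rds, na.rm = TRUE), se_r_ds = se(rds),
                 mean_r_os = mean(ros, na.rm = TRUE), se_r_os = se(ros),
                 t_test = tt),
            class = "graduality_summary")
}

#' @export
print.graduality_summary <- function(x, digits = 3, ...) {
  cat("Graduality (focus vs neighbour strength), per wave-strength level:\n")
  print(cbind(x$table[1:3],
              round(x$table[4:7], digits)))
  cat(sprintf("mean r_ds = %.4f +/- %.4f; mean r_os = %.4f +/- %.4f\n",
              x$mean_r_ds, x$se_r_ds, x$mean_r_os, x$se_r_os))
  if (!is.null(x$t_test))
    cat(sprintf("paired t-test ds vs os: t = %.3f, P = %.4f\n",
                x$t_test$statistic, x$t_test$p.value))
  else cat("paired t-test ds vs os: not enough matched levels\n")
  invisible(x)
}

#' Share of agents explained by gradual transfer
#'
#' The coefficient of determination of the strength regression, as a
#' percentage of the selected agents: `100 * r^2`.
#'
#' @param r Pearson correlation coefficient(s).
#' @return percent share(s).
#' @examples
#' graduality_share(0.16)  # 2.56
#' @export
graduality_share <- function(r) 100 * r^2
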