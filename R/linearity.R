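#' Trigger-direction histogram per wave direction
#'
#' Counts focus-bee incidents per (wave direction, trigger sector), pooling
#' wave-strength levels 1..6, and normalizes within each wave direction by
#' its maximum count, so the best-populated trigger sector of each wave
#' direction has `rel_n_fb = 1`.
#'
#' @param incidents data.frame with `role`, `dir_wav`, `dir_trig`, `c_ws`.
#' @param c_ws_levels pooled strength levels (default 1..6).
#' @return list of class `linearity_histogram`: `counts` and `rel_n_fb`
#'   (matrices, rows = wave direction present, cols = 8 trigger sectors).
#'   Empty wave-direction strata are omitted with a warning.
#' @export
linearity_histogram <- function(incidents, c_ws_levels = 1:6) {
  sel <- incidents$role == "focus" & !is.na(incidents$dir_wav) &
    !is.na(incidents$dir_trig) & incidents$c_ws %in% c_ws_levels
  inc <- incidents[sel, , drop = FALSE]
  dirs <- sort(unique(inc$dir_wav))
  if (length(dirs) < 4)
    warning(sprintf("wave-direction strata missing: only %s present",
                    paste(dirs, collapse = ",")))
  if (!length(dirs)) {
    m <- matrix(numeric(0), 0, 8, dimnames = list(NULL, 1:8))
    return(structure(list(counts = m, rel_n_fb = m, n = numeric(0)),
                     class = "linearity_histogram"))
  }
  counts <- t(vapply(dirs, function(d) {
    tabulate(inc$dir_trig[inc$dir_wav == d], nbins = 8L)
  }, numeric(8)))
  dimnames(counts) <- list(dir_wav = dirs, dir_trig = 1:8)
  rel <- counts / pmax(apply(counts, 1, max), 1)
  structure(list(counts = counts, rel_n_fb = rel,
                 n = rowSums(counts)),
            class = "linearity_histogram")
}

#' @export
print.linearity_histogram <- function(x, digits = 2, ...) {
  cat("Trigger-direction histogram (rel_n_fb, rows = dir_WAV):\n")
  print(round(x$rel_n_fb, digits))
  invisible(x)
}

#' Coincidence of trigger and wave direction
#'
#' Tests, per wave-direction stratum, whether the trigger-direction
#' histogram is anchored at the wave's origin once the directional window is
#' widened to `alpha_WAV +/- 45` degrees (the key sector plus its two
#' flanking sectors).  A stratum is coincident iff (a) at least one sector
#' lies strictly above the stratum median (a flat histogram can never be
#' coincident), (b) the best-populated trigger sector falls inside the
#' widened window, and (c) the majority condition holds: the summed rate
#' inside the window exceeds the summed rate in the opposite window, i.e.
#' more focus bees are triggered from where the wave comes from than from
#' where it spreads to.
#'
#' A literal subset rule ("every above-median sector inside the window")
#' would be almost surely false for any continuous 8-sector histogram, since
#' exactly four of eight untied values exceed their median while the window
#' holds three sectors; the majority/minority comparison above is the
#' operational form of the criterion.
#'
#' @param hist a `linearity_histogram`, or a numeric length-8 vector of
#'   `rel_n_fb` values for a single stratum.
#' @param dir_wav wave direction(s) 1..4 (required when `hist` is a vector;
#'   defaults to the histogram's strata otherwise).
#' @return named logical vector, one element per stratum.
#' @export
test_coincidence <- function(hist, dir_wav = NULL) {
  if (inherits(hist, "linearity_histogram")) {
    rel <- hist$rel_n_fb
    if (is.null(dir_wav)) dir_wav <- as.integer(rownames(rel))
  } else {
    rel <- matrix(hist, nrow = 1)
    if (is.null(dir_wav)) stop("dir_wav required for a bare vector")
  }
  out <- vapply(seq_along(dir_wav), function(k) {
    r <- rel[k, ]
    if (!any(r > stats::median(r))) return(FALSE)   # ties: strictly above
    key <- wave_key_sector(dir_wav[k])
    window <- ((key - 1L + c(-1L, 0L, 1L)) %% 8L) + 1L
    opposite <- ((key - 1L + 3:5) %% 8L) + 1L
    which.max(r) %in% window && sum(r[window]) > sum(r[opposite])
  }, logical(1))
  names(out) <- dir_wav
  out
}

# fit a polynomial of rel_n_fb over the trigger angle; angles are rotated so
# the wave's source angle sits at 180 degrees (the fit is not periodic, so
# the peak must not sit on the domain edge); returns the fitted minimum
poly_fuzziness_min <- function(rel, dir_wav, degree = 4) {
  ang <- sector_angle(1:8)
  rot <- (ang - wave_angle(dir_wav) + 180) %% 360
  fit <- stats::lm(rel ~ stats::poly(rot, degree = degree, raw = TRUE))
  grid <- seq(min(rot), max(rot), length.out = 721)
  pred <- stats::predict(fit, data.frame(rot = grid))
  max(0, min(pred))
}

#' Linearity estimates from the trigger-direction histogram
#'
#' Two shares of directed participation per wave direction: `estimate_A`
#' integrates the normalized rates above the fuzziness level (the minimum of
#' a polynomial fitted over the trigger angle), `estimate_B` those above the
#' stratum median.  Both are percentages of the stratum's summed normalized
#' rates; `estimate_B <= estimate_A` whenever the polynomial minimum does not
#' exceed the median.
#'
#' @param hist a `linearity_histogram`, or a length-8 `rel_n_fb` vector.
#' @param dir_wav wave direction(s); required for a bare vector.
#' @param degree degree of the fuzziness polynomial (default 4).
#' @param poly_min optional externally supplied fuzziness level(s), bypassing
#'   the fit (negative values are clipped to 0).
#' @return data.frame `(dir_wav, poly_min, median_level, estimate_A,
#'   estimate_B)`, estimates in percent.
#' @export
estimate_linearity <- function(hist, dir_wav = NULL, degree = 4,
                               poly_min = NULL) {
  if (inherits(hist, "linearity_histogram")) {
    rel <- hist$rel_n_fb
    if (is.null(dir_wav)) dir_wav <- as.integer(rownames(rel))
  } else {
    rel <- matrix(hist, nrow = 1)
    if (is.null(dir_wav)) stop("dir_wav required for a bare vector")
  }
  if (!length(dir_wav))
    return(data.frame(dir_wav = integer(), poly_min = numeric(),
                      median_level = numeric(), estimate_A = numeric(),
                      estimate_B = numeric()))
  res <- lapply(seq_along(dir_wav), function(k) {
    r <- rel[k, ]
    pm <- if (is.null(poly_min))
      poly_fuzziness_min(r, dir_wav[k], degree) else
        max(0, poly_min[min(k, length(poly_min))])
    med <- stats::median(r)
    tot <- sum(r)
    data.frame(dir_wav = dir_wav[k], poly_min = pm, median_level = med,
               estimate_A = 100 * sum(pmax(0, r - pm)) / tot,
               estimate_B = 100 * sum(pmax(0, r - med)) / tot)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
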