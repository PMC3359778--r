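#' Build a jittered hexagonal lattice of agent bees
#'
#' Generates thorax positions for a quasi-planar sheet of surface bees.
#' Agents sit on a hexagonal lattice (row pitch `spacing_mm * sqrt(3)/2`,
#' alternate rows offset by half a spacing) clipped to the rectangular extent,
#' with optional Gaussian positional jitter.  The default spacing of 29 mm
#' gives an interior agent 6 lattice neighbours inside the 40 mm near
#' neighbourhood (4-7 with jitter) and roughly 40 inside the 100 mm far
#' neighbourhood.
#'
#' Coordinates follow the image convention: x rightward, y downward, origin
#' top-left; `z_mm` is 0 for the surface sheet.  Pixel positions are derived
#' from the mm positions by the image scale and rounded to integers.
#'
#' @param extent_mm numeric length-2 `(W, H)` of the field in mm.
#' @param spacing_mm lattice constant in mm (default 29).
#' @param jitter_sd standard deviation of the Gaussian positional jitter in
#'   mm (default 2).
#' @param mm_per_px image scale used to derive pixel positions (default 0.30).
#' @param seed optional integer seed for the jitter.
#' @return An `agent_set`: a data.frame with columns `agent_id`, `x_mm`,
#'   `y_mm`, `z_mm`, `x_px`, `y_px` and attributes `mm_per_px`, `extent_mm`,
#'   `spacing_mm`.
#' @examples
#' a <- build_lattice(c(300, 300), seed = 1)
#' nrow(a)
#' @export
build_lattice <- function(extent_mm, spacing_mm = 29, jitter_sd = 2,
                          mm_per_px = 0.30, seed = NULL) {
  stopifnot(length(extent_mm) == 2, all(extent_mm > 0), spacing_mm > 0,
            jitter_sd >= 0, mm_per_px > 0)
  if (!is.null(seed)) set.seed(seed)
  W <- extent_mm[1]; H <- extent_mm[2]
  dy <- spacing_mm * sqrt(3) / 2
  rows <- 0:floor(H / dy)
  pos <- do.call(rbind, lapply(rows, function(r) {
    x0 <- (r %% 2) * spacing_mm / 2
    xs <- seq(x0, W, by = spacing_mm)
    if (!length(xs)) return(NULL)
    cbind(x = xs, y = r * dy)
  }))
  x <- pos[, 1]; y <- pos[, 2]
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, jitter_sd)
    y <- y + stats::rnorm(length(y), 0, jitter_sd)
    x <- pmin(pmax(x, 0), W)
    y <- pmin(pmax(y, 0), H)
  }
  agents <- data.frame(
    agent_id = seq_along(x),
    x_mm = x, y_mm = y, z_mm = 0,
    x_px = as.integer(round(x / mm_per_px)),
    y_px = as.integer(round(y / mm_per_px))
  )
  if (nrow(agents) == 1L)
    warning("extent smaller than spacing: single-agent set")
  attr(agents, "mm_per_px") <- mm_per_px
  attr(agents, "extent_mm") <- extent_mm
  attr(agents, "spacing_mm") <- spacing_mm
  class(agents) <- c("agent_set", "data.frame")
  agents
}

#' @export
print.agent_set <- function(x, ...) {
  cat(sprintf("agent_set: %d agents on %.0f x %.0f mm (spacing %.1f mm, %.2f mm/px)\n",
              nrow(x), attr(x, "extent_mm")[1], attr(x, "extent_mm")[2],
              attr(x, "spacing_mm"), attr(x, "mm_per_px")))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Neighbours of a focus agent within a radius
#'
#' In-plane (x, y) distances; the bound is strict (`< radius_mm`), so a
#' neighbour at exactly the radius is excluded, and the focus agent itself is
#' never returned.  The defaults 40 mm and 100 mm are the near and far
#' neighbourhoods of the focus-bee analyses.
#'
#' @param agents an `agent_set`.
#' @param focus agent_id of the focus bee.
#' @param radius_mm neighbourhood radius in mm.
#' @return integer vector of neighbour agent_ids.
#' @export
neighbors <- function(agents, focus, radius_mm = 40) {
  stopifnot(radius_mm > 0)
  i <- match(focus, agents$agent_id)
  if (is.na(i)) stop("unknown focus agent_id")
  d <- sqrt((agents$x_mm - agents$x_mm[i])^2 + (agents$y_mm - agents$y_mm[i])^2)
  agents$agent_id[d < radius_mm & agents$agent_id != focus]
}

# neighbour index lists for all agents at once (used by the simulator and
# trigger assignment); returns list indexed by row, entries are row indices
neighbor_index <- function(agents, radius_mm) {
  n <- nrow(agents)
  xs <- agents$x_mm; ys <- agents$y_mm
  lapply(seq_len(n), function(i) {
    d2 <- (xs - xs[i])^2 + (ys - ys[i])^2
    which(d2 < radius_mm^2 & seq_len(n) != i)
  })
}
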