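# filled-ellipse rasterizer: sets pixels inside the ellipse to `value`
draw_ellipse <- function(img, cx, cy, rx, ry, value) {
  x0 <- max(1L, floor(cx - rx)); x1 <- min(ncol(img), ceiling(cx + rx))
  y0 <- max(1L, floor(cy - ry)); y1 <- min(nrow(img), ceiling(cy + ry))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  m <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[m] <- value
  img[ys, xs] <- sub
  img
}

#' Render a simulation as 8-bit grayscale frames
#'
#' Draws each agent as a bright body ellipse with an abdomen ellipse below
#' it whose tip displaces upward proportionally to the instantaneous
#' supra-baseline motion strength, mimicking the abdomen flip as seen by the
#' camera.  The abdomen glyph is ~20 px wide, the pixel footprint of a 6 mm
#' abdomen at 0.30 mm/px.  With zero background noise, frames with identical
#' strength values are bit-identical.
#'
#' @param agents an `agent_set` (pixel positions are used).
#' @param strengths frames x agents matrix of normalized motion strength
#'   (e.g. `sim$traces`).
#' @param baseline strength level mapped to zero displacement (default 1.08).
#' @param gain_px_per_unit abdomen tip displacement in px per strength unit
#'   (default 3).
#' @param frame_px optional `(width, height)`; default fits all ROIs.
#' @param bg_level,body_level,abdomen_level gray levels 0..255.
#' @param bg_noise_sd per-pixel Gaussian background noise sd (default 0).
#' @param abdomen_px abdomen glyph width in px (default 20).
#' @param seed seed for the background noise.
#' @return list of integer matrices (rows = y), one per frame.
#' @export
render_frames <- function(agents, strengths, baseline = 1.08,
                          gain_px_per_unit = 3, frame_px = NULL,
                          bg_level = 40, body_level = 140,
                          abdomen_level = 220, bg_noise_sd = 0,
                          abdomen_px = 20, seed = 1L) {
  stopifnot(ncol(strengths) == nrow(agents))
  if (is.null(frame_px))
    frame_px <- c(max(agents$x_px) + 40, max(agents$y_px) + 60)
  if (any(agents$x_px < 31) || any(agents$y_px < 31))
    message("agents near the frame border: their ROIs will be clipped")
  set.seed(seed)
  w <- frame_px[1]; h <- frame_px[2]
  rx_b <- abdomen_px / 2        # body half-width
  frames <- vector("list", nrow(strengths))
  for (f in seq_len(nrow(strengths))) {
    img <- matrix(bg_level, h, w)
    if (bg_noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, bg_noise_sd), h, w)
    for (i in seq_len(nrow(agents))) {
      cx <- agents$x_px[i] + 1  # 0-based px -> 1-based matrix
      cy <- agents$y_px[i] + 1
      disp <- round(gain_px_per_unit * max(0, strengths[f, i] - baseline))
      img <- draw_ellipse(img, cx, cy, rx_b, 15, body_level)      # thorax+body
      img <- draw_ellipse(img, cx, cy + 12 - disp, rx_b, 7,
                          abdomen_level)                           # abdomen
    }
    frames[[f]] <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
  }
  frames
}

#' Write / read a frame stack as numbered PNG files
#'
#' @param frames list of integer matrices (0..255, rows = y).
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; files are `prefix_000000.png`, ...
#' @return invisibly, the written file paths.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix,
                                  seq_along(frames) - 1L))
  for (k in seq_along(frames))
    png::writePNG(frames[[k]] / 255, paths[k])
  invisible(paths)
}

#' @rdname write_frames_png
#' @param paths PNG file paths in frame order.
#' @export
read_frames_png <- function(paths) {
  lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
}
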