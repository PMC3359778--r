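#' Angular sectors and key wave directions
#'
#' The neighbourhood of a focus bee is partitioned into eight 45-degree
#' sectors labelled by the direction the activity comes *from*: sector 1 is
#' "from Right" (centre angle 0 degrees), sector 3 "from Bottom" (90), sector 5
#' "from Left" (180), sector 7 "from Top" (270).  Angles use image
#' coordinates: x rightward, y downward, so "Bottom" is +y.  Sectors are
#' half-open: the boundary angle centre + 22.5 degrees belongs to the next
#' sector.  The four key wave directions map onto the odd sectors:
#' dir 1 (from Right to Left) <-> sector 1, dir 2 (from Bottom to Top) <->
#' sector 3, dir 3 (from Left to Right) <-> sector 5, dir 4 (from Top to
#' Bottom) <-> sector 7.
#'
#' @param focus_pos numeric length-2 (x, y) position of the focus bee.
#' @param other_pos numeric length-2 (x, y) position of the neighbour, or a
#'   two-column matrix of positions.
#' @return Integer sector id(s) in 1..8.
#' @examples
#' sector_of(c(0, 0), c(10, 0))   # from Right -> 1
#' sector_of(c(0, 0), c(0, 10))   # from Bottom (y down) -> 3
#' @export
sector_of <- function(focus_pos, other_pos) {
  if (is.matrix(other_pos)) {
    dx <- other_pos[, 1] - focus_pos[1]
    dy <- other_pos[, 2] - focus_pos[2]
  } else {
    dx <- other_pos[1] - focus_pos[1]
    dy <- other_pos[2] - focus_pos[2]
  }
  if (any(dx == 0 & dy == 0))
    stop("sector undefined for coincident positions")
  sector_of_angle(atan2(dy, dx) * 180 / pi)
}

#' Sector containing an angle
#'
#' @param angle_deg angle(s) in degrees, any range; image convention
#'   (0 = rightward, 90 = downward).
#' @return integer sector id(s) 1..8; half-open bins so exactly 22.5 degrees
#'   falls into sector 2.
#' @export
sector_of_angle <- function(angle_deg) {
  a <- (angle_deg + 22.5) %% 360
  as.integer(floor(a / 45)) + 1L
}

#' Centre angle of a sector
#' @param sector integer 1..8
#' @return centre angle in degrees (0, 45, ..., 315)
#' @export
sector_angle <- function(sector) (as.integer(sector) - 1L) * 45

#' Key sector and angle of a wave direction
#'
#' @param dir_wav integer 1..4 (1 from_R_to_L, 2 from_B_to_T, 3 from_L_to_R,
#'   4 from_T_to_B)
#' @return the neighbourhood sector (1, 3, 5, 7) the wave comes from
#' @export
wave_key_sector <- function(dir_wav) 2L * as.integer(dir_wav) - 1L

#' @rdname wave_key_sector
#' @export
wave_angle <- function(dir_wav) (as.integer(dir_wav) - 1L) * 90

#' Signed sector offset
#'
#' Circular difference between two sectors expressed in degrees, wrapped to
#' (-180, 180].  Used for the continuity profile's deviation-from-trigger-angle
#' axis.
#'
#' @param sector,ref integer sector ids 1..8
#' @return offset in degrees, one of -135, -90, ..., 135, 180
#' @export
sector_offset_deg <- function(sector, ref) {
  d <- (as.integer(sector) - as.integer(ref)) * 45
  w <- ((d + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

#' Sector opposite to a given sector (180 degrees away)
#' @param sector integer 1..8
#' @export
opposite_sector <- function(sector) ((as.integer(sector) - 1L + 4L) %% 8L) + 1L

# in-plane (x, y) euclidean distance between two position matrices/vectors
plane_dist <- function(a, b) {
  sqrt((a[, 1] - b[1])^2 + (a[, 2] - b[2])^2)
}

#' Image scale, glyph size, and frame-timing helpers
#'
#' Small conversions used throughout: the metric scale of the recording
#' (field width in mm over its width in pixels), the pixel footprint of a
#' structure of known metric size, the number of frames spanned by a pulse of
#' given duration, and the frame interval.
#'
#' @param field_mm,field_px recorded field width in mm and pixels
#' @return `px_scale`: mm per pixel.
#' @examples
#' px_scale(700, 2352)          # ~0.30 mm/px
#' glyph_px(6, 0.2976)          # abdomen of 6 mm -> ~20 px
#' pulse_frames(200, 60)        # 200 ms flip at 60 fps -> 12 frames
#' @export
px_scale <- function(field_mm, field_px) field_mm / field_px

#' @rdname px_scale
#' @param size_mm metric size of the imaged structure
#' @param mm_per_px image scale
#' @export
glyph_px <- function(size_mm, mm_per_px) round(size_mm / mm_per_px)

#' @rdname px_scale
#' @param duration_ms pulse duration in ms
#' @param fps frame rate
#' @export
pulse_frames <- function(duration_ms, fps) round(duration_ms * fps / 1000)

#' @rdname px_scale
#' @export
frame_interval_ms <- function(fps) 1000 / fps
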