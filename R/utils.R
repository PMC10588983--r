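#' Wrap angles to (-180, 180]
#'
#' All headings and angular differences in this package live on the
#' half-open interval (-180, 180] degrees, counterclockwise positive.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped to (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 540, 180))
#' @export
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Quadrant index of arena positions
#'
#' The four quadrants are the 90-degree sectors delimited by the arena
#' diagonals, indexed counterclockwise starting from the sector centered on
#' the +x axis: quadrant 1 covers polar angles in [-45, 45), quadrant 2
#' [45, 135), quadrant 3 [135, 180] and (-180, -135), quadrant 4 [-135, -45).
#'
#' @param x_mm,y_mm Arena-centered coordinates in mm.
#' @return Integer vector in 1..4 (NA where x = y = 0).
#' @export
quadrant_of <- function(x_mm, y_mm) {
  theta <- rad2deg(atan2(y_mm, x_mm))
  q <- (floor((theta + 45) / 90) %% 4) + 1L
  q[x_mm == 0 & y_mm == 0] <- NA_integer_
  as.integer(q)
}

# lead within groups: value of x at the next row when that row belongs to the
# same (movie, fly) series, NA at each series' last row
lead_within <- function(x, same_next) {
  out <- c(x[-1], NA)
  out[!same_next] <- NA
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
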