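#' Per-frame kinematics of a track set
#'
#' Derives, for every frame of every fly:
#' \describe{
#'   \item{`r_mm`}{radial distance from the arena center.}
#'   \item{`norm_index`}{the area-normalized distance-from-center index
#'     `(r / radius)^2`. The area of an annulus grows as r^2, so under
#'     uniform occupancy this index is uniform on \[0, 1\] with mean 1/2 and
#'     RMS of `r/R` equal to 1/sqrt(2).}
#'   \item{`alpha_deg`}{signed angle between the body heading and the upwind
#'     direction, wrapped to (-180, 180]; 0 = facing upwind, +/-180 = facing
#'     the center (for inward wind). With `wind_mode = "inward"` the upwind
#'     bearing at (x, y) is the outward radial direction `atan2(y, x)`; with
#'     `"reversed"` it is the inward radial direction; with `"off"` the angle
#'     is undefined (NA). At r = 0 the bearing is undefined and the frame is
#'     flagged NA rather than raising an error.}
#'   \item{`cos_alpha`}{cosine of `alpha_deg`.}
#'   \item{`dtheta_deg`}{wrapped forward first difference of heading
#'     (frame k to k+1, CCW positive); NA at each fly's last frame.}
#'   \item{`ang_vel_dps`}{unsigned angular speed, `|dtheta| * frame_rate`.}
#'   \item{`speed_mm_s`}{raw translational speed over the forward step.}
#'   \item{`fwd_speed_mm_s`}{forward walking speed: the forward displacement
#'     projected on the unit heading vector at frame k, times the frame rate.
#'     Negative values mean backing; purely sideways drift scores 0.}
#' }
#' No smoothing is applied; differentiation is plain forward differencing.
#'
#' @param ts A [track_set()].
#' @return A data frame with one row per input frame (same order as
#'   `ts$data`): identifiers, `t_s`, `valid`, and the columns above.
#' @export
kinematics <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  d <- ts$data
  cfg <- ts$cfg
  n <- nrow(d)
  key <- paste(d$movie_id, d$fly_id, sep = "\r")
  same_next <- if (n > 1) c(key[-1] == key[-n], FALSE) else logical(n)

  r <- sqrt(d$x_mm^2 + d$y_mm^2)
  norm_index <- (r / cfg$radius_mm)^2

  if (cfg$wind_mode == "off") {
    alpha <- rep(NA_real_, n)
  } else {
    bearing <- rad2deg(atan2(d$y_mm, d$x_mm))
    if (cfg$wind_mode == "reversed") bearing <- bearing + 180
    alpha <- wrap_angle(bearing - d$heading_deg)
    alpha[r == 0] <- NA_real_
  }

  dth <- wrap_angle(lead_within(d$heading_deg, same_next) - d$heading_deg)
  dx <- lead_within(d$x_mm, same_next) - d$x_mm
  dy <- lead_within(d$y_mm, same_next) - d$y_mm
  hx <- cos(deg2rad(d$heading_deg))
  hy <- sin(deg2rad(d$heading_deg))

  data.frame(
    movie_id = d$movie_id,
    fly_id = d$fly_id,
    frame = d$frame,
    t_s = d$t_s,
    valid = d$valid,
    r_mm = r,
    norm_index = norm_index,
    alpha_deg = alpha,
    cos_alpha = cos(deg2rad(alpha)),
    dtheta_deg = dth,
    ang_vel_dps = abs(dth) * cfg$frame_rate_hz,
    speed_mm_s = sqrt(dx^2 + dy^2) * cfg$frame_rate_hz,
    fwd_speed_mm_s = (dx * hx + dy * hy) * cfg$frame_rate_hz,
    stringsAsFactors = FALSE
  )
}
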