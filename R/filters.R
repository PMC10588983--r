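#' Flag tracking errors in a track set
#'
#' A single-frame step is a tracking artifact when the displacement exceeds
#' `max_jump_mm` (default 5 mm) or the wrapped heading change exceeds
#' `max_turn_deg` (default 180 degrees). Wrapped per-frame heading changes
#' live in (-180, 180], so with the default threshold the only angular
#' trigger is a change of exactly 180 degrees -- the sign-ambiguous head/tail
#' flip -- which is always treated as an artifact.
#'
#' Exclusion granularity: rather than discarding a fly's whole movie, the
#' artifact invalidates the analysis window (segment) containing it. Segments
#' are delimited by `breaks_s`; by default the breaks are the schedule's
#' effective onsets, so an artifact knocks out the fly's data within the
#' epoch where it occurred. With no schedule and no breaks the whole
#' trajectory is one segment. The operation is idempotent.
#'
#' @param ts A [track_set()].
#' @param max_jump_mm Displacement threshold per frame, mm.
#' @param max_turn_deg Wrapped heading-change threshold per frame, degrees.
#' @param breaks_s Optional numeric vector of segment boundaries (seconds).
#' @return `ts` with `valid` flags updated and a `filter_report` list stored
#'   in `ts$provenance$filter_report` (input/excluded frame counts and a
#'   per-track breakdown).
#' @export
flag_tracking_errors <- function(ts, max_jump_mm = 5, max_turn_deg = 180,
                                 breaks_s = NULL) {
  stopifnot(inherits(ts, "track_set"))
  d <- ts$data
  n <- nrow(d)
  if (n < 2) return(ts)
  if (is.null(breaks_s) && !is.null(ts$schedule))
    breaks_s <- sort(unique(ts$schedule$effective_onset_s))

  key <- paste(d$movie_id, d$fly_id, sep = "\r")
  same_next <- c(key[-1] == key[-n], FALSE)

  dx <- lead_within(d$x_mm, same_next) - d$x_mm
  dy <- lead_within(d$y_mm, same_next) - d$y_mm
  jump <- sqrt(dx^2 + dy^2)
  dth <- abs(wrap_angle(lead_within(d$heading_deg, same_next) - d$heading_deg))

  # step k -> k+1 is an artifact; both endpoint frames are implicated.
  # A wrapped change of (numerically) exactly 180 is the sign-ambiguous
  # head/tail flip and always triggers.
  bad_step <- !is.na(jump) &
    (jump > max_jump_mm | dth > max_turn_deg | abs(dth - 180) < 1e-9)
  bad_frame <- bad_step | c(FALSE, bad_step[-n])

  seg <- if (length(breaks_s)) findInterval(d$t_s, sort(breaks_s)) else 0L
  segkey <- paste(key, seg, sep = "\r")
  bad_seg <- unique(segkey[bad_frame])
  newly_invalid <- segkey %in% bad_seg

  was_valid <- d$valid
  d$valid <- d$valid & !newly_invalid
  ts$data <- d

  per_track <- stats::aggregate(
    cbind(n_artifact_steps = bad_step,
          n_excluded = was_valid & newly_invalid),
    by = list(movie_id = d$movie_id, fly_id = d$fly_id), FUN = sum)
  ts$provenance$filter_report <- list(
    n_input_frames = n,
    n_artifact_steps = sum(bad_step),
    n_excluded_error = sum(was_valid & newly_invalid),
    max_jump_mm = max_jump_mm,
    max_turn_deg = max_turn_deg,
    breaks_s = breaks_s,
    per_track = per_track
  )
  ts
}

#' Arena-edge gate
#'
#' Flies too close to the arena wall are excluded from single-trajectory
#' analyses: a fly passes the gate when its distance from the wall,
#' `radius - r`, is at least `min_wall_mm` (inclusive; default 3 mm).
#'
#' @param r_mm Radial distance(s) from the arena center, mm.
#' @param cfg An [arena_config()].
#' @param min_wall_mm Minimum wall distance, mm.
#' @return Logical vector, `TRUE` where the fly is analyzable.
#' @examples
#' edge_gate(c(0, 47, 48), arena_config())
#' @export
edge_gate <- function(r_mm, cfg, min_wall_mm = 3) {
  stopifnot(inherits(cfg, "arena_config"))
  (cfg$radius_mm - r_mm) >= min_wall_mm
}

#' Initial-orientation gate for onset-turning analyses
#'
#' Selects flies oriented broadside-to-downwind at stimulus onset: the gate
#' passes when the absolute initial angle to upwind lies in
#' `[lower, upper]` = [90, 150] degrees (either side). Flies facing straight
#' up- or downwind give no information about turn direction choice, hence
#' the two-sided band.
#'
#' @param alpha0_deg Signed initial angle(s) to upwind, degrees in
#'   (-180, 180].
#' @param lower,upper Band edges in degrees (defaults 90 and 150, inclusive).
#' @return Logical vector.
#' @examples
#' orientation_gate(c(-120, 0, 170))
#' @export
orientation_gate <- function(alpha0_deg, lower = 90, upper = 150) {
  a <- abs(wrap_angle(alpha0_deg))
  !is.na(a) & a >= lower & a <= upper
}
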