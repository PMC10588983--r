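#' Arena configuration
#'
#' Geometry, frame rate and airflow bookkeeping for a four-quadrant circular
#' olfactometer arena. Air enters through four peripheral arms and is pulled
#' out through a central suction hole, so with `wind_mode = "inward"` the wind
#' at any point blows radially inward and the *upwind* direction is radially
#' outward; facing the center is +/-180 degrees to upwind.
#'
#' @param radius_mm Arena radius in mm (default 50).
#' @param frame_rate_hz Video frame rate in Hz (default 30).
#' @param wind_mode One of `"inward"` (default; flow from periphery to center),
#'   `"reversed"` (flow from center to periphery) or `"off"` (no airflow;
#'   upwind angles are undefined).
#' @param arm_flow_ml_min Inflow rate of each of the four arms, mL/min
#'   (default 100 each).
#' @param suction_flow_ml_min Central suction rate, mL/min (default 400). For
#'   the default rig this must equal the summed arm inflow (mass balance).
#' @param odor_onset_latency_s Delay between the solenoid valve switch and
#'   odor arriving in the arena, seconds (default 3.5). Applied to odor
#'   events only; LED events are taken as instantaneous.
#' @param quadrant_odor Optional named list/character vector mapping quadrant
#'   index ("1".."4") to an odor label.
#' @param check_flow_balance If `TRUE` (default), [validate_arena_config()]
#'   enforces suction = sum(arm inflow).
#' @return An object of class `"arena_config"`.
#' @seealso [validate_arena_config()], [epoch_schedule()]
#' @examples
#' cfg <- arena_config()
#' cfg$radius_mm
#' @export
arena_config <- function(radius_mm = 50,
                         frame_rate_hz = 30,
                         wind_mode = c("inward", "reversed", "off"),
                         arm_flow_ml_min = rep(100, 4),
                         suction_flow_ml_min = 400,
                         odor_onset_latency_s = 3.5,
                         quadrant_odor = NULL,
                         check_flow_balance = TRUE) {
  wind_mode <- match.arg(wind_mode)
  cfg <- structure(
    list(
      radius_mm = as.numeric(radius_mm),
      frame_rate_hz = as.numeric(frame_rate_hz),
      wind_mode = wind_mode,
      arm_flow_ml_min = as.numeric(arm_flow_ml_min),
      suction_flow_ml_min = as.numeric(suction_flow_ml_min),
      odor_onset_latency_s = as.numeric(odor_onset_latency_s),
      quadrant_odor = quadrant_odor,
      check_flow_balance = isTRUE(check_flow_balance)
    ),
    class = "arena_config"
  )
  validate_arena_config(cfg)
}

#' Validate an arena configuration
#'
#' Checks geometry and rate invariants and, unless disabled, the rig's mass
#' balance: total arm inflow must equal the central suction rate.
#'
#' @param cfg An [arena_config()] object.
#' @return `cfg`, invisibly unchanged, with attribute `total_inflow_ml_min`
#'   set to the computed total inflow.
#' @export
validate_arena_config <- function(cfg) {
  stopifnot(inherits(cfg, "arena_config"))
  if (!is.finite(cfg$radius_mm) || cfg$radius_mm <= 0)
    stop("invalid arena_config: radius_mm must be > 0", call. = FALSE)
  if (!is.finite(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0)
    stop("invalid arena_config: frame_rate_hz must be > 0", call. = FALSE)
  if (length(cfg$arm_flow_ml_min) != 4 || any(cfg$arm_flow_ml_min < 0))
    stop("invalid arena_config: arm_flow_ml_min must be 4 non-negative rates",
         call. = FALSE)
  if (cfg$suction_flow_ml_min < 0)
    stop("invalid arena_config: suction_flow_ml_min must be >= 0", call. = FALSE)
  if (cfg$odor_onset_latency_s < 0)
    stop("invalid arena_config: odor_onset_latency_s must be >= 0", call. = FALSE)
  total <- sum(cfg$arm_flow_ml_min)
  if (cfg$check_flow_balance &&
      abs(total - cfg$suction_flow_ml_min) > 1e-9) {
    stop(sprintf(
      "invalid arena_config: mass imbalance, total arm inflow %g mL/min != suction %g mL/min",
      total, cfg$suction_flow_ml_min), call. = FALSE)
  }
  attr(cfg, "total_inflow_ml_min") <- total
  cfg
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> radius %g mm, %g fps, wind %s\n",
              x$radius_mm, x$frame_rate_hz, x$wind_mode))
  cat(sprintf("  arm inflow %s mL/min, suction %g mL/min, odor latency %g s\n",
              paste(x$arm_flow_ml_min, collapse = "/"),
              x$suction_flow_ml_min, x$odor_onset_latency_s))
  invisible(x)
}

#' Convert a frame count to milliseconds
#'
#' @param n_frames Non-negative frame count.
#' @param frame_rate_hz Frame rate in Hz.
#' @return Duration in integer milliseconds, `round(1000 * n_frames / rate)`.
#'   Ten frames at 30 fps is reported as 333 ms.
#' @examples
#' frames_to_ms(10, 30)
#' @export
frames_to_ms <- function(n_frames, frame_rate_hz) {
  stopifnot(all(n_frames >= 0))
  if (any(frame_rate_hz <= 0)) stop("frame_rate_hz must be > 0", call. = FALSE)
  round(1000 * n_frames / frame_rate_hz)
}

#' Area ratio of two annuli
#'
#' Ratio of the areas of the annuli `lo1 < r < hi1` and `lo2 < r < hi2`.
#' Because area grows as r^2, the outer 40-50 mm ring of a 50-mm arena is
#' nine times larger than the central 0-10 mm disk -- the geometric fact that
#' motivates the area-normalized radial index (r/R)^2.
#'
#' @param lo1,hi1 Inner/outer radii of the first annulus (mm).
#' @param lo2,hi2 Inner/outer radii of the second annulus (mm).
#' @return `(hi1^2 - lo1^2) / (hi2^2 - lo2^2)`.
#' @examples
#' annulus_area_ratio(40, 50, 0, 10) # 9
#' @export
annulus_area_ratio <- function(lo1, hi1, lo2, hi2) {
  stopifnot(lo1 >= 0, lo2 >= 0, hi1 > lo1)
  if (hi2 <= lo2) stop("degenerate reference annulus: hi2 must exceed lo2",
                       call. = FALSE)
  (hi1^2 - lo1^2) / (hi2^2 - lo2^2)
}

#' Stimulus epoch schedule
#'
#' Valve/LED events of one recording. Odor arrives in the arena with a delay
#' after the solenoid valve switch, so each event carries both the hardware
#' time (`valve_on_s`) and, once [effective_onsets()] has been applied, the
#' analysis-effective onset.
#'
#' @param kind Character vector of event kinds; `"odor_*"` events (e.g.
#'   `"odor_PA"`, `"odor_EL"`) receive the odor latency, `"LED"` events do not.
#' @param valve_on_s Valve/LED switch-on times, seconds from movie start.
#' @param duration_s Event durations, seconds.
#' @return A data frame of class `"epoch_schedule"` with columns `kind`,
#'   `valve_on_s`, `duration_s` and `effective_onset_s` (NA until filled).
#' @examples
#' epoch_schedule("odor_PA", 30, 10)
#' @export
epoch_schedule <- function(kind, valve_on_s, duration_s) {
  stopifnot(length(kind) == length(valve_on_s),
            length(kind) == length(duration_s),
            all(valve_on_s >= 0), all(duration_s > 0))
  sch <- data.frame(
    kind = as.character(kind),
    valve_on_s = as.numeric(valve_on_s),
    duration_s = as.numeric(duration_s),
    effective_onset_s = NA_real_,
    stringsAsFactors = FALSE
  )
  # events of a kind must not overlap
  for (k in unique(sch$kind)) {
    e <- sch[sch$kind == k, , drop = FALSE]
    e <- e[order(e$valve_on_s), , drop = FALSE]
    if (nrow(e) > 1 &&
        any(e$valve_on_s[-1] < (e$valve_on_s + e$duration_s)[-nrow(e)]))
      stop(sprintf("overlapping '%s' events in schedule", k), call. = FALSE)
  }
  class(sch) <- c("epoch_schedule", "data.frame")
  sch
}

is_odor_event <- function(kind) startsWith(kind, "odor")

#' Fill effective stimulus onsets
#'
#' Odor events become effective `odor_onset_latency_s` after the valve
#' switch (default 3.5 s, compensating valve-to-arena delivery plus arena
#' filling); LED events are effective at switch-on.
#'
#' @param schedule An [epoch_schedule()].
#' @param cfg An [arena_config()] supplying the odor latency.
#' @return The schedule with `effective_onset_s` filled.
#' @export
effective_onsets <- function(schedule, cfg) {
  stopifnot(inherits(schedule, "epoch_schedule"), inherits(cfg, "arena_config"))
  lat <- ifelse(is_odor_event(schedule$kind), cfg$odor_onset_latency_s, 0)
  schedule$effective_onset_s <- schedule$valve_on_s + lat
  schedule
}

#' Read an arena configuration (and optional schedule) from YAML or JSON
#'
#' The file holds a top-level `arena` mapping with [arena_config()] fields
#' (units fixed: mm, s, mL/min, Hz) and an optional `schedule` list of events
#' with `kind`, `valve_on_s`, `duration_s`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `cfg` ([arena_config()]) and `schedule`
#'   ([epoch_schedule()] with effective onsets filled, or `NULL`).
#' @export
read_arena_config <- function(path) {
  if (!nzchar(path) || !file.exists(path))
    stop("config file not found: '", path, "'", call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  a <- raw$arena %||% raw
  cfg <- arena_config(
    radius_mm = a$radius_mm %||% 50,
    frame_rate_hz = a$frame_rate_hz %||% 30,
    wind_mode = a$wind_mode %||% "inward",
    arm_flow_ml_min = unlist(a$arm_flow_ml_min %||% rep(100, 4)),
    suction_flow_ml_min = a$suction_flow_ml_min %||% 400,
    odor_onset_latency_s = a$odor_onset_latency_s %||% 3.5,
    quadrant_odor = a$quadrant_odor,
    check_flow_balance = a$check_flow_balance %||% TRUE
  )
  schedule <- NULL
  if (!is.null(raw$schedule)) {
    ev <- raw$schedule
    if (is.data.frame(ev)) {
      schedule <- epoch_schedule(ev$kind, ev$valve_on_s, ev$duration_s)
    } else {
      schedule <- epoch_schedule(
        vapply(ev, function(e) e$kind, ""),
        vapply(ev, function(e) as.numeric(e$valve_on_s), 0),
        vapply(ev, function(e) as.numeric(e$duration_s), 0)
      )
    }
    schedule <- effective_onsets(schedule, cfg)
  }
  list(cfg = cfg, schedule = schedule)
}
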