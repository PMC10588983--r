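#' Simulation parameters for the synthetic fly-walk generator
#'
#' Defaults emulate the study conditions the analysis assumes: groups of
#' ~20 flies per movie, 60-s recordings, a correlated random walk at roughly
#' 10 mm/s with a transient angular-speed startle in the first 10 frames
#' (~333 ms) of each stimulus. Gains are zero by default, i.e. the default
#' fly is a control genotype: startled by the stimulus but with no
#' orientation-dependent turn or speed modulation, no post-offset attraction
#' and no spatial bias. The statistical-structure knobs:
#'
#' \describe{
#'   \item{`upwind_turn_gain`}{degrees/frame of stimulus-gated turning per
#'     unit `sin(alpha)` -- zero when facing up- or downwind, maximal
#'     broadside, always rotating toward upwind for positive gain.}
#'   \item{`speed_mod_gain`}{mm/s of stimulus-gated forward-speed change per
#'     unit `cos(alpha)` (faster when heading upwind for positive gain).}
#'   \item{`startle_gain_deg`}{scale of the extra unsigned turning during the
#'     first `startle_window_frames` frames of each stimulus.}
#'   \item{`startle_upwind_bias`}{in `[0, 1]`: fraction of startle rotation
#'     directed toward upwind (0 = non-directional, as in control flies).}
#'   \item{`return_gain`}{degrees/frame of post-offset turning toward the
#'     location occupied at stimulus offset, active for `return_window_s`.}
#'   \item{`quadrant_bias_gain`}{degrees/frame of stimulus-independent
#'     turning toward the nearer of the `bias_quadrants` centers -- a spatial
#'     position-bias field used to validate reciprocal PI averaging.}
#' }
#'
#' @param n_flies Flies per movie (default 20).
#' @param n_movies Movies (default 1).
#' @param duration_s Movie length, seconds (default 60).
#' @param base_speed_mm_s,speed_sd_mm_s Mean and per-frame SD of walking
#'   speed (defaults 10 and 3 mm/s).
#' @param heading_noise_deg Per-frame SD of heading noise (default 8).
#' @param upwind_turn_gain,speed_mod_gain,startle_gain_deg,startle_upwind_bias,return_gain,quadrant_bias_gain
#'   Behavior gains, see above.
#' @param startle_window_frames Startle duration in frames (default 10).
#' @param return_window_s Post-offset attraction window, seconds (default 15).
#' @param bias_quadrants Quadrant pair attracting the spatial bias.
#' @param wall_mode `"turn_away"` (default: heading reflected off the wall
#'   tangent, position clamped just inside) or `"reflect"` (specular position
#'   bounce; used for uniform-occupancy null checks).
#' @param artifact_rate Expected tracking artifacts per fly per minute, used
#'   by [inject_artifacts()] (default 1).
#' @param seed Integer master seed; identical (params, cfg, schedule, seed)
#'   give byte-identical output. Per-movie random streams are derived
#'   deterministically from it.
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(n_flies = 20, n_movies = 1, duration_s = 60,
                       base_speed_mm_s = 10, speed_sd_mm_s = 3,
                       heading_noise_deg = 8,
                       upwind_turn_gain = 0, speed_mod_gain = 0,
                       startle_gain_deg = 15, startle_window_frames = 10,
                       startle_upwind_bias = 0,
                       return_gain = 0, return_window_s = 15,
                       quadrant_bias_gain = 0, bias_quadrants = c(1, 3),
                       wall_mode = c("turn_away", "reflect"),
                       artifact_rate = 1, seed = 1) {
  wall_mode <- match.arg(wall_mode)
  p <- list(n_flies = as.integer(n_flies), n_movies = as.integer(n_movies),
            duration_s = duration_s,
            base_speed_mm_s = base_speed_mm_s, speed_sd_mm_s = speed_sd_mm_s,
            heading_noise_deg = heading_noise_deg,
            upwind_turn_gain = upwind_turn_gain,
            speed_mod_gain = speed_mod_gain,
            startle_gain_deg = startle_gain_deg,
            startle_window_frames = as.integer(startle_window_frames),
            startle_upwind_bias = startle_upwind_bias,
            return_gain = return_gain, return_window_s = return_window_s,
            quadrant_bias_gain = quadrant_bias_gain,
            bias_quadrants = as.integer(bias_quadrants),
            wall_mode = wall_mode,
            artifact_rate = artifact_rate, seed = as.integer(seed))
  stopifnot(p$n_flies >= 1, p$n_movies >= 1, p$duration_s > 0,
            p$artifact_rate >= 0,
            p$startle_upwind_bias >= 0, p$startle_upwind_bias <= 1,
            all(vapply(p[c("upwind_turn_gain", "speed_mod_gain",
                           "startle_gain_deg", "return_gain",
                           "quadrant_bias_gain")], is.finite, TRUE)))
  class(p) <- "sim_params"
  p
}

movie_seed <- function(seed, m) as.integer((seed + (m - 1) * 100003) %% 2147483629L + 1L)

#' Sample positions uniformly over the arena disk
#'
#' Area-uniform sampling (`r = R * sqrt(u)`): the null spatial distribution
#' of flies. Under it the area-normalized index `(r/R)^2` is uniform on
#' \[0, 1\] (mean 1/2) and the RMS of `r/R` is `1/sqrt(2)`.
#'
#' @param n Number of points.
#' @param cfg An [arena_config()].
#' @param seed Optional integer seed.
#' @return Data frame with `x_mm`, `y_mm`.
#' @export
uniform_positions <- function(n, cfg, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- cfg$radius_mm * sqrt(stats::runif(n))
  th <- stats::runif(n, -pi, pi)
  data.frame(x_mm = r * cos(th), y_mm = r * sin(th))
}

#' Simulate arena fly-walk trajectories
#'
#' Agent-based correlated random walk, stepped at the arena frame rate.
#' Per frame, each fly's heading changes by Gaussian noise plus, while a
#' stimulus is on, `upwind_turn_gain * sin(alpha)` (alpha = angle to upwind)
#' plus a startle term in the first `startle_window_frames` frames of each
#' stimulus; the fly then advances by `base_speed + speed_mod_gain *
#' cos(alpha)` (stimulus-gated, floored at 0) along its heading. After each
#' stimulus offset the fly is attracted back toward the location it occupied
#' at offset (`return_gain`, for `return_window_s`). Flies are initialized
#' uniformly over the arena with uniform headings; wall contact is handled
#' per `wall_mode`. Fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param cfg An [arena_config()].
#' @param schedule An [epoch_schedule()] (effective onsets filled if absent);
#'   all events gate the stimulus terms. May be `NULL` for stimulus-free
#'   walks.
#' @return A [track_set()]; provenance records the parameters.
#' @export
simulate_flies <- function(params, cfg, schedule = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(cfg, "arena_config"))
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "epoch_schedule"))
    if (anyNA(schedule$effective_onset_s))
      schedule <- effective_onsets(schedule, cfg)
  }
  dt <- 1 / cfg$frame_rate_hz
  N <- as.integer(round(params$duration_s * cfg$frame_rate_hz))
  n <- params$n_flies
  R <- cfg$radius_mm
  on_s <- if (is.null(schedule)) numeric(0) else schedule$effective_onset_s
  off_s <- if (is.null(schedule)) numeric(0) else on_s + schedule$duration_s
  startle_len <- params$startle_window_frames * dt
  bias_centers <- deg2rad((params$bias_quadrants - 1) * 90)

  movies <- vector("list", params$n_movies)
  for (m in seq_len(params$n_movies)) {
    set.seed(movie_seed(params$seed, m))
    p0 <- uniform_positions(n, cfg)
    x <- p0$x_mm
    y <- p0$y_mm
    h <- stats::runif(n, -180, 180)
    X <- Y <- H <- matrix(NA_real_, N, n)
    X[1, ] <- x; Y[1, ] <- y; H[1, ] <- h
    ret_x <- ret_y <- rep(NA_real_, n)

    for (k in 2:N) {
      t <- (k - 2) * dt  # time of the state being advanced
      stim <- any(t >= on_s & t < off_s)
      startle <- any(t >= on_s & t < on_s + startle_len)
      # capture the offset location when crossing an offset
      just_off <- off_s[t >= off_s & t - dt < off_s]
      if (length(just_off)) { ret_x <- x; ret_y <- y }
      ret_on <- params$return_gain != 0 && length(off_s) &&
        any(t >= off_s & t < off_s + params$return_window_s) &&
        !anyNA(ret_x)

      r <- sqrt(x^2 + y^2)
      bearing <- atan2(y, x)                       # outward radial, radians
      if (cfg$wind_mode == "reversed") bearing <- bearing + pi
      alpha <- deg2rad(wrap_angle(rad2deg(bearing) - h))
      sin_a <- ifelse(r == 0 | cfg$wind_mode == "off", 0, sin(alpha))
      cos_a <- ifelse(r == 0 | cfg$wind_mode == "off", 0, cos(alpha))

      dh <- stats::rnorm(n, 0, params$heading_noise_deg)
      if (stim) dh <- dh + params$upwind_turn_gain * sin_a
      if (startle && params$startle_gain_deg != 0) {
        mag <- abs(stats::rnorm(n, 0, params$startle_gain_deg))
        toward <- ifelse(sin_a == 0, sample(c(-1, 1), n, replace = TRUE),
                         sign(sin_a))
        dir <- ifelse(stats::runif(n) < (1 + params$startle_upwind_bias) / 2,
                      toward, -toward)
        dh <- dh + mag * dir
      }
      if (ret_on) {
        tb <- atan2(ret_y - y, ret_x - x)
        dh <- dh + params$return_gain * sin(deg2rad(wrap_angle(rad2deg(tb) - h)))
      }
      if (params$quadrant_bias_gain != 0) {
        # turn toward the nearer preferred-quadrant center (at radius R/2)
        d2 <- sapply(bias_centers, function(c0)
          (R / 2 * cos(c0) - x)^2 + (R / 2 * sin(c0) - y)^2)
        c0 <- bias_centers[apply(as.matrix(d2), 1, which.min)]
        tb <- atan2(R / 2 * sin(c0) - y, R / 2 * cos(c0) - x)
        dh <- dh + params$quadrant_bias_gain *
          sin(deg2rad(wrap_angle(rad2deg(tb) - h)))
      }
      h <- wrap_angle(h + dh)

      sp <- pmax(stats::rnorm(n, params$base_speed_mm_s, params$speed_sd_mm_s), 0)
      if (stim && params$speed_mod_gain != 0)
        sp <- pmax(sp + params$speed_mod_gain * cos_a, 0)
      x <- x + sp * dt * cos(deg2rad(h))
      y <- y + sp * dt * sin(deg2rad(h))

      rr <- sqrt(x^2 + y^2)
      outside <- rr > R
      if (any(outside)) {
        phi <- rad2deg(atan2(y[outside], x[outside]))
        h[outside] <- wrap_angle(2 * phi + 180 - h[outside])
        scale <- if (params$wall_mode == "reflect")
          (2 * R - rr[outside]) / rr[outside] else (R * 0.999) / rr[outside]
        x[outside] <- x[outside] * scale
        y[outside] <- y[outside] * scale
      }
      X[k, ] <- x; Y[k, ] <- y; H[k, ] <- h
    }

    movies[[m]] <- data.frame(
      movie_id = sprintf("movie%02d", m),
      fly_id = rep(sprintf("fly%02d", seq_len(n)), each = N),
      frame = rep(0:(N - 1), times = n),
      x_mm = as.numeric(X), y_mm = as.numeric(Y),
      heading_deg = as.numeric(H),
      stringsAsFactors = FALSE
    )
  }
  track_set(do.call(rbind, movies), cfg, schedule = schedule,
            provenance = list(sim_params = unclass(params)))
}

#' Inject tracking artifacts into a track set
#'
#' Adds the two artifact classes the tracking-error filter targets, at
#' Poisson-sampled frames (`artifact_rate` expected events per fly per
#' minute): single-frame position jumps of 7-10 mm, and head/tail heading
#' flips (the frame's heading set exactly 180 degrees from the previous
#' frame). Ground-truth artifact frames are recorded in
#' `provenance$artifacts` so filter recall can be scored.
#'
#' @param ts A [track_set()].
#' @param artifact_rate Events per fly per minute; defaults to the rate in
#'   the simulation parameters stored in provenance, else 1.
#' @param seed Integer seed (default derived from stored sim seed, else 1).
#' @return `ts` with perturbed frames and ground truth in provenance.
#' @export
inject_artifacts <- function(ts, artifact_rate = NULL, seed = NULL) {
  stopifnot(inherits(ts, "track_set"))
  sp <- ts$provenance$sim_params
  if (is.null(artifact_rate)) artifact_rate <- sp$artifact_rate %||% 1
  if (is.null(seed)) seed <- (sp$seed %||% 0) + 777L
  stopifnot(artifact_rate >= 0)
  if (artifact_rate == 0) {
    ts$provenance$artifacts <- data.frame(movie_id = character(0),
                                          fly_id = character(0),
                                          frame = integer(0),
                                          type = character(0))
    return(ts)
  }
  set.seed(as.integer(seed %% 2147483647))
  d <- ts$data
  R <- ts$cfg$radius_mm
  rate_hz <- ts$cfg$frame_rate_hz
  fkey <- paste(d$movie_id, d$fly_id, sep = "\r")
  gt <- list()
  for (f in split(seq_len(nrow(d)), fkey)) {
    nf <- length(f)
    if (nf < 5) next
    dur_min <- nf / rate_hz / 60
    n_art <- stats::rpois(1, artifact_rate * dur_min)
    if (n_art == 0) next
    cand <- 3:(nf - 2)
    frames <- sort(sample(cand, min(n_art, length(cand))))
    # keep artifacts >= 3 frames apart so ground truth stays unambiguous
    frames <- frames[c(TRUE, diff(frames) >= 3)]
    for (i in frames) {
      row <- f[i]
      if (stats::runif(1) < 0.5) {
        len <- stats::runif(1, 7, 10)
        r_here <- sqrt(d$x_mm[row]^2 + d$y_mm[row]^2)
        ang <- if (r_here > R - 12) {
          atan2(-d$y_mm[row], -d$x_mm[row]) + stats::runif(1, -1, 1)
        } else stats::runif(1, -pi, pi)
        d$x_mm[row] <- d$x_mm[row] + len * cos(ang)
        d$y_mm[row] <- d$y_mm[row] + len * sin(ang)
        type <- "jump"
      } else {
        d$heading_deg[row] <- wrap_angle(d$heading_deg[f[i - 1]] + 180)
        type <- "flip"
      }
      gt[[length(gt) + 1]] <- data.frame(
        movie_id = d$movie_id[row], fly_id = d$fly_id[row],
        frame = d$frame[row], type = type, stringsAsFactors = FALSE)
    }
  }
  ts$data <- d
  ts$provenance$artifacts <- if (length(gt)) do.call(rbind, gt) else
    data.frame(movie_id = character(0), fly_id = character(0),
               frame = integer(0), type = character(0))
  ts
}
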