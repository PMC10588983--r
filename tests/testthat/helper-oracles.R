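# Shared fixtures and independent brute-force oracles.
# The oracles are deliberately scalar, frame-by-frame re-implementations of
# the definitions, kept free of the vectorized code paths they check.

make_cfg <- function(...) arena_config(...)

led_schedule <- function(on_s = 10, duration_s = 10, cfg = make_cfg()) {
  effective_onsets(epoch_schedule("LED", on_s, duration_s), cfg)
}

# hand-built single-fly track_set; rate defaults to 1 Hz for frame-level
# constructions
manual_ts <- function(x, y, heading, cfg = arena_config(frame_rate_hz = 1),
                      schedule = NULL, fly = "f1", movie = "m1") {
  track_set(data.frame(movie_id = movie, fly_id = fly,
                       frame = seq_along(x) - 1L,
                       x_mm = x, y_mm = y, heading_deg = heading),
            cfg, schedule = schedule)
}

# Frame-by-frame oracle for the tracking-error filter: marks, per fly, the
# segments (delimited by breaks_s) containing any artifact step.
oracle_flag_valid <- function(ts, max_jump_mm = 5, max_turn_deg = 180,
                              breaks_s = NULL) {
  d <- ts$data
  if (is.null(breaks_s) && !is.null(ts$schedule))
    breaks_s <- sort(unique(ts$schedule$effective_onset_s))
  seg_of <- function(t) if (length(breaks_s)) findInterval(t, sort(breaks_s)) else 0L
  valid <- d$valid
  for (fk in unique(paste(d$movie_id, d$fly_id))) {
    rows <- which(paste(d$movie_id, d$fly_id) == fk)
    bad_segs <- integer(0)
    for (j in seq_len(length(rows) - 1)) {
      a <- rows[j]; b <- rows[j + 1]
      jump <- sqrt((d$x_mm[b] - d$x_mm[a])^2 + (d$y_mm[b] - d$y_mm[a])^2)
      turn <- abs(wrap_angle(d$heading_deg[b] - d$heading_deg[a]))
      if (jump > max_jump_mm || turn > max_turn_deg || abs(turn - 180) < 1e-9)
        bad_segs <- union(bad_segs, c(seg_of(d$t_s[a]), seg_of(d$t_s[b])))
    }
    if (length(bad_segs))
      valid[rows][seg_of(d$t_s[rows]) %in% bad_segs] <- FALSE
  }
  valid
}

# Per-frame oracle for the return/revisit definition for one fly.
oracle_return_one <- function(x, y, valid, frames, rate_hz,
                              away_mm = 10, back_mm = 3, window_s = 15) {
  W <- round(window_s * rate_hz)
  n_total <- max(frames) + 1
  out <- data.frame(frame0 = integer(0), ret = logical(0))
  for (i in seq_along(x)) {
    if (frames[i] > n_total - W) next
    if (i + 1 > length(x)) next
    if (!valid[i]) next
    moved_away <- FALSE
    ret <- FALSE
    for (j in (i + 1):min(length(x), i + W)) {
      if (!valid[j]) next
      dd <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
      if (dd > away_mm) moved_away <- TRUE
      if (moved_away && dd <= back_mm) { ret <- TRUE; break }
    }
    out <- rbind(out, data.frame(frame0 = frames[i], ret = ret))
  }
  out
}

oracle_return_profile <- function(ts, away_mm = 10, back_mm = 3, window_s = 15) {
  d <- ts$data
  rate <- ts$cfg$frame_rate_hz
  res <- list()
  for (fk in unique(paste(d$movie_id, d$fly_id))) {
    rows <- paste(d$movie_id, d$fly_id) == fk
    res[[fk]] <- oracle_return_one(d$x_mm[rows], d$y_mm[rows], d$valid[rows],
                                   d$frame[rows], rate,
                                   away_mm, back_mm, window_s)
  }
  all <- do.call(rbind, res)
  agg <- aggregate(ret ~ frame0, all, function(v) c(mean(v), length(v)))
  data.frame(time0_s = agg$frame0 / rate,
             p_return = agg$ret[, 1], n = agg$ret[, 2])
}

# rotate a track_set's arena frame by angle_deg (positions and headings)
rotate_ts <- function(ts, angle_deg) {
  th <- angle_deg * pi / 180
  d <- ts$data
  x <- d$x_mm * cos(th) - d$y_mm * sin(th)
  y <- d$x_mm * sin(th) + d$y_mm * cos(th)
  d$x_mm <- x
  d$y_mm <- y
  d$heading_deg <- wrap_angle(d$heading_deg + angle_deg)
  ts$data <- d[, setdiff(names(d), "t_s")]
  track_set(ts$data, ts$cfg, schedule = ts$schedule,
            provenance = ts$provenance)
}

# reflect a track_set across the x axis
reflect_ts <- function(ts) {
  d <- ts$data
  d$y_mm <- -d$y_mm
  d$heading_deg <- wrap_angle(-d$heading_deg)
  track_set(d[, setdiff(names(d), "t_s")], ts$cfg, schedule = ts$schedule)
}
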