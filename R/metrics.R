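# Resolve an epoch argument: an index into ts$schedule, or a list with
# onset_s (already effective) and duration_s.
resolve_epoch <- function(ts, epoch) {
  if (is.list(epoch) && !is.null(epoch$onset_s))
    return(list(onset_s = epoch$onset_s, duration_s = epoch$duration_s %||% NA_real_))
  if (is.null(ts$schedule))
    stop("track_set has no schedule; pass epoch = list(onset_s=, duration_s=)",
         call. = FALSE)
  sch <- ts$schedule
  i <- as.integer(epoch)
  stopifnot(i >= 1, i <= nrow(sch))
  list(onset_s = sch$effective_onset_s[i], duration_s = sch$duration_s[i],
       kind = sch$kind[i])
}

frame_of <- function(t_s, cfg) as.integer(round(t_s * cfg$frame_rate_hz))

# mean of x over valid flies per (movie, frame); returns df movie_id, frame, m, n
pop_mean_by_frame <- function(kin, x) {
  ok <- kin$valid & !is.na(x)
  g <- paste(kin$movie_id[ok], kin$frame[ok], sep = "\r")
  s <- rowsum(x[ok], g)
  n <- rowsum(rep(1L, sum(ok)), g)
  parts <- strsplit(rownames(s), "\r", fixed = TRUE)
  data.frame(
    movie_id = vapply(parts, `[`, "", 1),
    frame = as.integer(vapply(parts, `[`, "", 2)),
    mean = as.numeric(s) / as.numeric(n),
    n = as.integer(n),
    stringsAsFactors = FALSE
  )
}

#' Onset-subtracted upwind displacement
#'
#' The arena's wind-directional response measure: the population mean of the
#' area-normalized distance-from-center index `(r/R)^2` at each time point,
#' minus its value at the effective stimulus onset. Positive values mean net
#' movement toward the periphery, i.e. upwind under inward flow.
#'
#' @param ts A [track_set()] with a schedule (or pass `epoch` as a list).
#' @param epoch Event index into the schedule, or `list(onset_s=, duration_s=)`.
#' @param at_s Endpoint offset after onset, seconds (default 10, the stimulus
#'   length used in activation experiments).
#' @param by `"movie"` (default; the movie is the unit of replication, each
#'   movie's fly-mean is one series) or `"fly"` (per-trajectory series for
#'   trial-level dot plots).
#' @return A list with `series` (data frame: unit ids, `frame`, `t_s`,
#'   `t_rel_s`, `delta_index`), `endpoint` (delta at `onset + at_s` per unit)
#'   and `onset_s`.
#' @export
upwind_displacement <- function(ts, epoch = 1, at_s = 10,
                                by = c("movie", "fly")) {
  by <- match.arg(by)
  ep <- resolve_epoch(ts, epoch)
  cfg <- ts$cfg
  f0 <- frame_of(ep$onset_s, cfg)
  kin <- kinematics(ts)

  if (by == "movie") {
    m <- pop_mean_by_frame(kin, kin$norm_index)
    base <- m[m$frame == f0, c("movie_id", "mean")]
    if (nrow(base) == 0 || all(is.na(base$mean)))
      stop("no valid flies at stimulus onset", call. = FALSE)
    names(base)[2] <- "baseline"
    m <- merge(m, base, by = "movie_id", all.x = TRUE)
    m$delta_index <- m$mean - m$baseline
    m <- m[order(m$movie_id, m$frame), ]
    series <- data.frame(movie_id = m$movie_id, frame = m$frame,
                         t_s = m$frame / cfg$frame_rate_hz,
                         n = m$n, delta_index = m$delta_index,
                         stringsAsFactors = FALSE)
  } else {
    ok0 <- kin$valid & kin$frame == f0
    base <- kin[ok0, c("movie_id", "fly_id", "norm_index")]
    if (nrow(base) == 0) stop("no valid flies at stimulus onset", call. = FALSE)
    names(base)[3] <- "baseline"
    m <- merge(kin[kin$valid, c("movie_id", "fly_id", "frame", "norm_index")],
               base, by = c("movie_id", "fly_id"))
    m$delta_index <- m$norm_index - m$baseline
    m <- m[order(m$movie_id, m$fly_id, m$frame), ]
    series <- data.frame(movie_id = m$movie_id, fly_id = m$fly_id,
                         frame = m$frame, t_s = m$frame / cfg$frame_rate_hz,
                         delta_index = m$delta_index, stringsAsFactors = FALSE)
  }
  series$t_rel_s <- series$t_s - ep$onset_s
  f_end <- frame_of(ep$onset_s + at_s, cfg)
  endpoint <- series[series$frame == f_end, , drop = FALSE]
  rownames(series) <- rownames(endpoint) <- NULL
  list(series = series, endpoint = endpoint, onset_s = ep$onset_s, at_s = at_s)
}

#' Population mean cosine of the upwind angle
#'
#' Per-frame mean, over valid flies, of cos(angle to upwind): +1 when all
#' flies face upwind, -1 when all face the arena center (inward wind), 0 for
#' uniformly distributed headings.
#'
#' @param ts A [track_set()]; `wind_mode` must not be `"off"`.
#' @param epoch Optional epoch (as in [upwind_displacement()]) used only to
#'   add an onset-relative time column.
#' @return Data frame: `movie_id`, `frame`, `t_s`, `n`, `mean_cos` and, when
#'   `epoch` is given, `t_rel_s`.
#' @export
mean_cos_upwind <- function(ts, epoch = NULL) {
  if (ts$cfg$wind_mode == "off")
    stop("upwind angle is undefined with wind_mode = 'off'", call. = FALSE)
  kin <- kinematics(ts)
  m <- pop_mean_by_frame(kin, kin$cos_alpha)
  out <- data.frame(movie_id = m$movie_id, frame = m$frame,
                    t_s = m$frame / ts$cfg$frame_rate_hz,
                    n = m$n, mean_cos = m$mean, stringsAsFactors = FALSE)
  if (!is.null(epoch)) {
    ep <- resolve_epoch(ts, epoch)
    out$t_rel_s <- out$t_s - ep$onset_s
  }
  out[order(out$movie_id, out$frame), ]
}

#' Cumulative turning over an onset window
#'
#' For each fly, sums the wrapped per-frame heading changes over `n_frames`
#' consecutive frames starting at `t0_s` (the default 10 frames at 30 fps is
#' a 333 ms window). `signed_deg` is the net rotation, CCW positive.
#' `toward_upwind_deg` folds the signed sum by the sign of the initial angle
#' to upwind, `signed_deg * sign(alpha0)`, so positive values mean net
#' rotation toward the upwind bearing regardless of which side the fly
#' started on; a fly exactly facing upwind (alpha0 = 0) scores 0 by
#' convention.
#'
#' @param ts A [track_set()].
#' @param t0_s Window start time, seconds.
#' @param n_frames Number of per-frame heading changes summed (default 10).
#' @return Data frame, one row per fly: `movie_id`, `fly_id`, `alpha0_deg`,
#'   `r0_mm`, `signed_deg`, `toward_upwind_deg`, `n_valid` (valid frames among
#'   the `n_frames + 1` touched) and `complete` (all frames present & valid).
#' @export
cumulative_turn <- function(ts, t0_s, n_frames = 10) {
  cfg <- ts$cfg
  f0 <- frame_of(t0_s, cfg)
  kin <- kinematics(ts)
  win <- kin[kin$frame >= f0 & kin$frame <= f0 + n_frames, , drop = FALSE]
  if (nrow(win) == 0) stop("t0 outside the recording", call. = FALSE)

  fkey <- paste(win$movie_id, win$fly_id, sep = "\r")
  flies <- unique(fkey)
  idx0 <- win$frame == f0
  # per-fly summaries
  sum_turn <- rowsum(ifelse(win$frame < f0 + n_frames & !is.na(win$dtheta_deg),
                            win$dtheta_deg, 0), fkey)
  n_valid <- rowsum(as.integer(win$valid), fkey)
  n_present <- rowsum(rep(1L, nrow(win)), fkey)
  ord <- rownames(sum_turn)

  a0 <- r0 <- setNames(rep(NA_real_, length(ord)), ord)
  a0[fkey[idx0]] <- win$alpha_deg[idx0]
  r0[fkey[idx0]] <- win$r_mm[idx0]

  parts <- strsplit(ord, "\r", fixed = TRUE)
  signed <- as.numeric(sum_turn)
  toward <- signed * sign(a0[ord])
  data.frame(
    movie_id = vapply(parts, `[`, "", 1),
    fly_id = vapply(parts, `[`, "", 2),
    alpha0_deg = as.numeric(a0[ord]),
    r0_mm = as.numeric(r0[ord]),
    signed_deg = signed,
    toward_upwind_deg = toward,
    n_valid = as.integer(n_valid),
    complete = as.integer(n_present) == (n_frames + 1) &
      as.integer(n_valid) == (n_frames + 1),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-fly onset response metrics
#'
#' Combines, for the `n_frames` window starting at an epoch's effective
#' onset: cumulative turning ([cumulative_turn()]), mean forward walking
#' speed, the initial angle to upwind, and the two single-trajectory gates
#' (arena-edge distance at onset, initial-orientation band).
#'
#' @param ts A [track_set()].
#' @param epoch Epoch spec as in [upwind_displacement()].
#' @param n_frames Window length in frames (default 10).
#' @param min_wall_mm Edge-gate threshold, mm (default 3).
#' @return Data frame per fly: turning columns as in [cumulative_turn()],
#'   plus `fwd_speed_mm_s` (window mean), `edge_ok`, `gate_ok`.
#' @export
onset_metrics <- function(ts, epoch = 1, n_frames = 10, min_wall_mm = 3) {
  ep <- resolve_epoch(ts, epoch)
  cfg <- ts$cfg
  f0 <- frame_of(ep$onset_s, cfg)
  out <- cumulative_turn(ts, ep$onset_s, n_frames)

  kin <- kinematics(ts)
  win <- kin[kin$frame >= f0 & kin$frame < f0 + n_frames & kin$valid &
               !is.na(kin$fwd_speed_mm_s), , drop = FALSE]
  fkey <- paste(win$movie_id, win$fly_id, sep = "\r")
  fs <- rowsum(win$fwd_speed_mm_s, fkey) / as.integer(rowsum(rep(1L, nrow(win)), fkey))
  key_out <- paste(out$movie_id, out$fly_id, sep = "\r")
  out$fwd_speed_mm_s <- as.numeric(fs[match(key_out, rownames(fs))])
  out$edge_ok <- edge_gate(out$r0_mm, cfg, min_wall_mm)
  out$gate_ok <- orientation_gate(out$alpha0_deg)
  out
}

#' Onset response binned by initial angle to upwind
#'
#' Smooths per-fly onset metrics against the initial angle to upwind with a
#' sliding circular window of +/- `halfwidth_deg` (default 30): at each grid
#' angle the metric is averaged over flies whose initial angle falls within
#' the window. Only flies passing the edge gate with a complete onset window
#' contribute.
#'
#' @param ts A [track_set()].
#' @param epoch Epoch spec as in [upwind_displacement()].
#' @param metric `"cumulative_turn"` (signed turning, degrees) or
#'   `"forward_speed"` (mm/s).
#' @param n_frames Onset window, frames (default 10).
#' @param halfwidth_deg Circular bin half-width, degrees (default 30).
#' @param grid_deg Bin centers; default every 5 degrees over (-180, 180].
#' @param min_wall_mm Edge-gate threshold (default 3 mm).
#' @return Data frame of class `"onset_response_curve"`:
#'   `initial_angle_deg`, `metric_mean`, `metric_sem`, `n_per_bin`
#'   (means are `NA` for empty bins).
#' @export
binned_onset_response <- function(ts, epoch = 1,
                                  metric = c("cumulative_turn", "forward_speed"),
                                  n_frames = 10, halfwidth_deg = 30,
                                  grid_deg = seq(-175, 180, by = 5),
                                  min_wall_mm = 3) {
  metric <- match.arg(metric)
  om <- onset_metrics(ts, epoch, n_frames, min_wall_mm)
  om <- om[om$complete & om$edge_ok & !is.na(om$alpha0_deg), , drop = FALSE]
  val <- if (metric == "cumulative_turn") om$signed_deg else om$fwd_speed_mm_s
  binned_curve(om$alpha0_deg, val, grid_deg, halfwidth_deg)
}

# circular sliding-window binning shared by curve builders
binned_curve <- function(angle_deg, value, grid_deg, halfwidth_deg) {
  out <- data.frame(initial_angle_deg = grid_deg,
                    metric_mean = NA_real_, metric_sem = NA_real_,
                    n_per_bin = 0L)
  for (i in seq_along(grid_deg)) {
    inwin <- abs(wrap_angle(angle_deg - grid_deg[i])) <= halfwidth_deg
    v <- value[inwin & !is.na(value)]
    out$n_per_bin[i] <- length(v)
    if (length(v)) {
      out$metric_mean[i] <- mean(v)
      if (length(v) > 1) out$metric_sem[i] <- stats::sd(v) / sqrt(length(v))
    }
  }
  class(out) <- c("onset_response_curve", "data.frame")
  out
}

#' Return (revisit) probability profile
#'
#' A fly is considered to revisit its location at reference time `time0` if,
#' within the following `window_s` seconds, it first moves more than
#' `away_mm` from that location and then comes back to within `back_mm` of it
#' (excursion strictly before return, both inside the window). The profile
#' reports, for each `time0` on the grid, the fraction of flies that revisit.
#' For 60-s movies and the default 15-s window, `time0` ranges over 0-45 s.
#'
#' @param ts A [track_set()].
#' @param away_mm Excursion threshold (default 10 mm, exclusive).
#' @param back_mm Return threshold (default 3 mm, inclusive).
#' @param window_s Look-ahead window, seconds (default 15).
#' @param time0_step_s Grid step for `time0`; default one frame.
#' @return Data frame of class `"return_profile"`: `time0_s`, `p_return`,
#'   `n` (flies valid at `time0`); thresholds kept as attributes.
#' @export
return_probability <- function(ts, away_mm = 10, back_mm = 3, window_s = 15,
                               time0_step_s = NULL) {
  cfg <- ts$cfg
  d <- ts$data
  W <- as.integer(round(window_s * cfg$frame_rate_hz))
  n_frames_total <- max(d$frame) + 1L  # movie length in frames
  if (n_frames_total < W)
    stop("return window longer than the recording", call. = FALSE)
  step <- if (is.null(time0_step_s)) 1L else
    max(1L, as.integer(round(time0_step_s * cfg$frame_rate_hz)))
  a2 <- away_mm^2
  b2 <- back_mm^2

  fkey <- paste(d$movie_id, d$fly_id, sep = "\r")
  res <- vector("list", length(unique(fkey)))
  j <- 0L
  for (f in split(seq_len(nrow(d)), fkey)) {
    x <- d$x_mm[f]; y <- d$y_mm[f]; v <- d$valid[f]; fr <- d$frame[f]
    nf <- length(f)
    t0_idx <- seq(1L, nf, by = step)
    t0_idx <- t0_idx[fr[t0_idx] <= n_frames_total - W & (t0_idx + 1L) <= nf]
    if (!length(t0_idx)) next
    ret <- rep(NA, length(t0_idx))
    for (k in seq_along(t0_idx)) {
      i <- t0_idx[k]
      if (!v[i]) next
      w <- (i + 1L):min(nf, i + W)
      w <- w[v[w]]
      if (!length(w)) { ret[k] <- FALSE; next }
      d2 <- (x[w] - x[i])^2 + (y[w] - y[i])^2
      away <- d2 > a2
      back <- d2 <= b2
      # excursion strictly before return
      ret[k] <- any(back & c(FALSE, cummax(away)[-length(away)] > 0))
    }
    j <- j + 1L
    res[[j]] <- data.frame(frame0 = fr[t0_idx], ret = ret)
  }
  all <- do.call(rbind, res[seq_len(j)])
  all <- all[!is.na(all$ret), , drop = FALSE]
  if (nrow(all) == 0) stop("no valid flies for return profile", call. = FALSE)
  p <- rowsum(as.integer(all$ret), all$frame0)
  n <- rowsum(rep(1L, nrow(all)), all$frame0)
  out <- data.frame(
    time0_s = as.integer(rownames(p)) / cfg$frame_rate_hz,
    p_return = as.numeric(p) / as.numeric(n),
    n = as.integer(n)
  )
  out <- out[order(out$time0_s), ]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(away_mm = away_mm, back_mm = back_mm,
                                  window_s = window_s)
  class(out) <- c("return_profile", "data.frame")
  out
}

#' Quadrant preference index
#'
#' Per frame, `PI(t) = (N_odor1 - N_other) / N_total` over flies with valid
#' positions, where `N_odor1` counts flies inside the two diagonal quadrants
#' carrying odor one. The result is the mean PI over the test window,
#' computed per movie and then averaged across movies. The same machinery
#' serves LED-quadrant preference (quadrants lit vs dark).
#'
#' @param ts A [track_set()].
#' @param odor_one_quadrants Integer pair of diagonal quadrants (default
#'   `c(1, 3)`); see [quadrant_of()] for the indexing convention.
#' @param window_s Length-2 numeric, the averaging window in seconds
#'   (default `c(30, 60)`: the final 30 s of a 60-s test, half-open
#'   `[from, to)`).
#' @return List of class `"preference_result"`: `pi` (across-movie mean),
#'   `per_movie`, `per_frame` data frames, `window_s`, `quadrants`.
#' @export
preference_index <- function(ts, odor_one_quadrants = c(1, 3),
                             window_s = c(30, 60)) {
  stopifnot(length(odor_one_quadrants) == 2, length(window_s) == 2)
  d <- ts$data
  sel <- d$valid & d$t_s >= window_s[1] & d$t_s < window_s[2]
  d <- d[sel, , drop = FALSE]
  if (nrow(d) == 0) stop("no valid flies in the test window", call. = FALSE)
  q <- quadrant_of(d$x_mm, d$y_mm)
  s <- ifelse(is.na(q), 0L, ifelse(q %in% odor_one_quadrants, 1L, -1L))
  g <- paste(d$movie_id, d$frame, sep = "\r")
  num <- rowsum(s, g)
  den <- rowsum(rep(1L, nrow(d)), g)
  parts <- strsplit(rownames(num), "\r", fixed = TRUE)
  per_frame <- data.frame(
    movie_id = vapply(parts, `[`, "", 1),
    frame = as.integer(vapply(parts, `[`, "", 2)),
    pi = as.numeric(num) / as.numeric(den),
    n = as.integer(den),
    stringsAsFactors = FALSE
  )
  per_frame <- per_frame[order(per_frame$movie_id, per_frame$frame), ]
  rownames(per_frame) <- NULL
  per_movie <- stats::aggregate(pi ~ movie_id, per_frame, mean)
  structure(list(pi = mean(per_movie$pi),
                 per_movie = per_movie,
                 per_frame = per_frame,
                 window_s = window_s,
                 quadrants = odor_one_quadrants),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("<preference_result> PI = %+.3f toward quadrants {%s}, window %g-%g s, %d movie(s)\n",
              x$pi, paste(x$quadrants, collapse = ","),
              x$window_s[1], x$window_s[2], nrow(x$per_movie)))
  invisible(x)
}

#' Reciprocal average of paired preference experiments
#'
#' In reciprocal experiments the two odors swap quadrants between runs; both
#' PIs are measured toward the *same physical quadrant pair*, with the CS+
#' odor occupying that pair in experiment A and the opposite pair in
#' experiment B. Averaging `(pi_a - pi_b) / 2` expresses preference toward
#' CS+ while cancelling any position bias and innate odor preference common
#' to the two runs.
#'
#' @param pi_a,pi_b [preference_index()] results (or bare numbers), both
#'   signed toward the same quadrant pair, with odor roles swapped in B.
#' @return List of class `"reciprocal_pi"`: `pi_a`, `pi_b`,
#'   `reciprocal_mean` (signed toward CS+).
#' @export
reciprocal_average <- function(pi_a, pi_b) {
  va <- if (inherits(pi_a, "preference_result")) pi_a$pi else as.numeric(pi_a)
  vb <- if (inherits(pi_b, "preference_result")) pi_b$pi else as.numeric(pi_b)
  if (inherits(pi_a, "preference_result") &&
      inherits(pi_b, "preference_result") &&
      !isTRUE(all.equal(pi_a$window_s, pi_b$window_s)))
    stop("mismatched test windows between reciprocal experiments", call. = FALSE)
  structure(list(pi_a = va, pi_b = vb, reciprocal_mean = (va - vb) / 2),
            class = "reciprocal_pi")
}

#' @export
print.reciprocal_pi <- function(x, ...) {
  cat(sprintf("<reciprocal_pi> toward CS+: %+.3f (A %+.3f, B %+.3f)\n",
              x$reciprocal_mean, x$pi_a, x$pi_b))
  invisible(x)
}

#' Learning rate from single vs repeated training
#'
#' Ratio of the response after a single training cycle to the peak response
#' after ninefold training. Values near 1 mean one cycle saturates the
#' behavior (fast learning); values near 0 mean the behavior needs repeated
#' training to build up.
#'
#' @param resp_after_1 Response (e.g. upwind displacement) after 1x training.
#' @param resp_peak_9x Peak response after 9x training.
#' @return `resp_after_1 / resp_peak_9x`; `NA` with a warning when the peak
#'   response is zero.
#' @export
learning_rate <- function(resp_after_1, resp_peak_9x) {
  if (any(resp_peak_9x == 0)) {
    warning("zero peak response: learning rate undefined")
    return(ifelse(resp_peak_9x == 0, NA_real_, resp_after_1 / resp_peak_9x))
  }
  resp_after_1 / resp_peak_9x
}
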