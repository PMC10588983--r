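#' The five activation-screen parameters
#'
#' Parameter names used throughout the screen pipeline, in fixed order:
#' onset-subtracted upwind displacement, mean cosine of the upwind angle,
#' angular velocity, forward walking speed, and return probability.
#' @export
SCREEN_PARAMETERS <- c("upwind_displacement", "cos_upwind",
                       "angular_velocity", "forward_speed", "p_return")

#' Behavioral parameter time courses for one driver line
#'
#' Summarizes one line's recordings into the five screen parameters
#' ([SCREEN_PARAMETERS]) over consecutive 2-s time bins spanning the
#' pre-stimulation, stimulation and post-stimulation periods. By default the
#' bins tile `[onset - pre_bins*bin_s, onset + duration + post_s)` -- for a
#' 10-s stimulation: 2 bins before, 5 during, 5 after. Bin values are means
#' over the frames in the bin (pooled over valid flies); `p_return` is the
#' mean return probability over reference times `time0` falling in the bin.
#'
#' @param ts A [track_set()] for one driver line (any number of movies).
#' @param epoch Stimulation epoch (index or list, see
#'   [upwind_displacement()]).
#' @param bin_s Bin width in seconds (default 2).
#' @param pre_bins,post_bins Number of bins before onset / after offset
#'   (defaults 2 and 5).
#' @param time0_step_s Grid step for the return-probability reference times
#'   (default 0.5 s).
#' @return Data frame: `parameter`, `bin` (label, `"T-2"..` pre-onset,
#'   `"T1".."Tk"` from onset), `t_start_s`, `t_end_s`, `during` (logical),
#'   `value`.
#' @export
parameter_timecourses <- function(ts, epoch = 1, bin_s = 2,
                                  pre_bins = 2, post_bins = 5,
                                  time0_step_s = 0.5) {
  ep <- resolve_epoch(ts, epoch)
  if (is.na(ep$duration_s))
    stop("stimulation epoch needs a duration", call. = FALSE)
  cfg <- ts$cfg
  during_bins <- ceiling(ep$duration_s / bin_s)
  starts <- ep$onset_s + bin_s * seq(-pre_bins, during_bins + post_bins - 1)
  ends <- starts + bin_s
  if (min(starts) < 0 || max(ends) > (max(ts$data$frame) + 1) / cfg$frame_rate_hz)
    stop("recording shorter than the binning span", call. = FALSE)
  rel <- seq(-pre_bins, during_bins + post_bins - 1)
  labels <- ifelse(rel < 0, paste0("T", rel), paste0("T", rel + 1))
  during <- rel >= 0 & rel < during_bins

  kin <- kinematics(ts)
  ud <- upwind_displacement(ts, epoch, at_s = ep$duration_s, by = "movie")$series
  rp <- return_probability(ts, time0_step_s = time0_step_s)

  bin_mean <- function(t, v) {
    vapply(seq_along(starts), function(i) {
      sel <- t >= starts[i] & t < ends[i] & !is.na(v)
      if (any(sel)) mean(v[sel]) else NA_real_
    }, 0)
  }
  okk <- kin$valid
  values <- rbind(
    upwind_displacement = bin_mean(ud$t_s, ud$delta_index),
    cos_upwind = bin_mean(kin$t_s[okk], kin$cos_alpha[okk]),
    angular_velocity = bin_mean(kin$t_s[okk], kin$ang_vel_dps[okk]),
    forward_speed = bin_mean(kin$t_s[okk], kin$fwd_speed_mm_s[okk]),
    p_return = bin_mean(rp$time0_s, rp$p_return)
  )
  data.frame(
    parameter = rep(SCREEN_PARAMETERS, each = length(starts)),
    bin = rep(labels, times = length(SCREEN_PARAMETERS)),
    t_start_s = rep(starts, times = length(SCREEN_PARAMETERS)),
    t_end_s = rep(ends, times = length(SCREEN_PARAMETERS)),
    during = rep(during, times = length(SCREEN_PARAMETERS)),
    value = as.numeric(t(values[SCREEN_PARAMETERS, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

#' Z-score matrix across driver lines
#'
#' Standardizes raw (line x parameter x bin) screen values across lines:
#' for every (parameter, bin) cell, `z = (value - mean) / sd` where mean and
#' sd are taken over all driver lines (including the empty-driver control)
#' and sd is the sample standard deviation (n - 1). Cells with zero spread
#' get z = 0 and are flagged.
#'
#' @param raw Data frame with columns `line`, `parameter`, `bin`, `value`
#'   (e.g. stacked [parameter_timecourses()] outputs with a `line` column).
#' @return Object of class `"screen_matrix"`: list with `table` (the input
#'   plus `z` and `zero_spread`), `lines`, `parameters`, `bins`, and
#'   `cell_stats` (per-cell mean/sd, enough to reconstruct raw from z), plus
#'   `standardization` metadata.
#' @export
zscore_matrix <- function(raw) {
  stopifnot(all(c("line", "parameter", "bin", "value") %in% names(raw)))
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  lines <- unique(raw$line)
  if (length(lines) < 2)
    stop("z-scores need >= 2 driver lines; report raw values for a single line",
         call. = FALSE)
  cell <- paste(raw$parameter, raw$bin, sep = "\r")
  mu <- tapply(raw$value, cell, mean)
  sdv <- tapply(raw$value, cell, stats::sd)
  m <- as.numeric(mu[cell])
  s <- as.numeric(sdv[cell])
  zero <- !is.na(s) & s == 0
  z <- (raw$value - m) / s
  z[zero] <- 0
  raw$z <- z
  raw$zero_spread <- zero
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  cell_stats <- data.frame(
    parameter = vapply(parts, `[`, "", 1),
    bin = vapply(parts, `[`, "", 2),
    mean = as.numeric(mu),
    sd = as.numeric(sdv),
    stringsAsFactors = FALSE
  )
  structure(list(
    table = raw,
    lines = lines,
    parameters = unique(raw$parameter),
    bins = unique(raw$bin),
    cell_stats = cell_stats,
    standardization = list(population = "across driver lines per (parameter, bin)",
                           sd = "sample (n - 1)")
  ), class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> %d lines x %d parameters x %d bins (z across lines, sample SD)\n",
              length(x$lines), length(x$parameters), length(x$bins)))
  invisible(x)
}

#' Rank driver lines by screen z-score
#'
#' Orders lines by their mean z-score for one parameter over a set of time
#' bins (descending); lines whose mean z exceeds `threshold` are flagged as
#' hits. Ranking is descriptive triage, not a significance call. Ties keep
#' the input line order (stable sort).
#'
#' @param m A [zscore_matrix()] result.
#' @param parameter One of the screen parameters.
#' @param bins Bin labels to average over; default all stimulation
#'   (`during`) bins.
#' @param threshold Hit threshold in z units (default 2).
#' @return Data frame ordered by `mean_z`: `line`, `mean_z`, `hit`.
#' @export
rank_hits <- function(m, parameter, bins = NULL, threshold = 2) {
  stopifnot(inherits(m, "screen_matrix"))
  if (!parameter %in% m$parameters)
    stop("unknown parameter: ", parameter, call. = FALSE)
  tab <- m$table[m$table$parameter == parameter, , drop = FALSE]
  if (is.null(bins)) {
    bins <- if (!is.null(tab$during)) unique(tab$bin[tab$during]) else m$bins
  }
  if (!all(bins %in% tab$bin))
    stop("unknown bin label(s): ", paste(setdiff(bins, tab$bin), collapse = ", "),
         call. = FALSE)
  tab <- tab[tab$bin %in% bins, , drop = FALSE]
  mz <- tapply(tab$z, tab$line, mean)
  # keep input line order for ties
  mz <- mz[match(m$lines, names(mz))]
  ord <- order(-as.numeric(mz))
  data.frame(line = m$lines[ord],
             mean_z = as.numeric(mz)[ord],
             hit = as.numeric(mz)[ord] > threshold,
             stringsAsFactors = FALSE,
             row.names = NULL)
}
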