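test_that("upwind displacement is onset-subtracted and spans [-1, 1]", {
  cfg1 <- arena_config(frame_rate_hz = 1)
  sch <- effective_onsets(epoch_schedule("LED", 0, 10), cfg1)

  # stationary flies: delta identically zero
  tab <- data.frame(movie_id = "m1",
                    fly_id = rep(c("a", "b"), each = 11),
                    frame = rep(0:10, 2), x_mm = rep(c(10, 20), each = 11),
                    y_mm = 0, heading_deg = 0)
  ud <- upwind_displacement(track_set(tab, cfg1, sch), epoch = 1, at_s = 10)
  expect_equal(ud$series$delta_index, rep(0, 11))

  # every fly from the center to the wall: delta endpoint +1
  tab2 <- data.frame(movie_id = "m1", fly_id = rep(c("a", "b"), each = 11),
                     frame = rep(0:10, 2),
                     x_mm = rep(c(rep(0, 10), 50), 2),
                     y_mm = 0, heading_deg = 0)
  ud2 <- upwind_displacement(track_set(tab2, cfg1, sch), epoch = 1, at_s = 10)
  expect_equal(ud2$endpoint$delta_index, 1)

  # per-fly mode gives one series per trajectory
  udf <- upwind_displacement(track_set(tab2, cfg1, sch), epoch = 1, at_s = 10,
                             by = "fly")
  expect_equal(sort(unique(udf$series$fly_id)), c("a", "b"))
  expect_equal(udf$endpoint$delta_index, c(1, 1))
})

test_that("mean cosine of the upwind angle hits its geometric extremes", {
  cfg1 <- arena_config(frame_rate_hz = 1)
  # flies at 4 bearings, all facing outward (upwind): mean cos = 1
  tab <- data.frame(movie_id = "m1", fly_id = letters[1:4], frame = 0,
                    x_mm = c(10, 0, -10, 0), y_mm = c(0, 10, 0, -10),
                    heading_deg = c(0, 90, 180, -90))
  expect_equal(mean_cos_upwind(track_set(tab, cfg1))$mean_cos, 1)
  # all facing the center: mean cos = -1
  tab$heading_deg <- wrap_angle(tab$heading_deg + 180)
  expect_equal(mean_cos_upwind(track_set(tab, cfg1))$mean_cos, -1)
  # undefined without wind
  cfg_off <- arena_config(frame_rate_hz = 1, wind_mode = "off",
                          arm_flow_ml_min = rep(0, 4), suction_flow_ml_min = 0)
  expect_error(mean_cos_upwind(track_set(tab, cfg_off)), "wind_mode")
})

test_that("cumulative turn folds the signed sum toward upwind", {
  cfg1 <- arena_config(frame_rate_hz = 1)
  # hand-stepped: fly at (10,0); alpha0 = -120 means heading 120;
  # rotating -10 deg/frame for 10 frames sums to -100 signed
  ts <- manual_ts(x = rep(10, 11), y = 0, heading = 120 - 10 * (0:10),
                  cfg = cfg1)
  ct <- cumulative_turn(ts, t0_s = 0, n_frames = 10)
  expect_equal(ct$alpha0_deg, -120)
  expect_equal(ct$signed_deg, -100)
  expect_equal(ct$toward_upwind_deg, 100)
  expect_true(ct$complete)

  # mirrored start: same rotation now turns away from upwind
  ts2 <- manual_ts(x = rep(10, 11), y = 0, heading = -120 - 10 * (0:10),
                   cfg = cfg1)
  ct2 <- cumulative_turn(ts2, t0_s = 0, n_frames = 10)
  expect_equal(ct2$alpha0_deg, 120)
  expect_equal(ct2$signed_deg, -100)
  expect_equal(ct2$toward_upwind_deg, -100)

  # constant heading: zero turn; facing upwind exactly scores 0 by convention
  ts3 <- manual_ts(x = rep(10, 11), y = 0, heading = 0, cfg = cfg1)
  ct3 <- cumulative_turn(ts3, t0_s = 0, n_frames = 10)
  expect_equal(ct3$signed_deg, 0)
  expect_equal(ct3$toward_upwind_deg, 0)

  # short window flagged incomplete
  ts4 <- manual_ts(x = rep(10, 5), y = 0, heading = 0, cfg = cfg1)
  expect_false(cumulative_turn(ts4, t0_s = 0, n_frames = 10)$complete)
})

test_that("onset curves smooth per-fly metrics over +/-30 degree windows", {
  cfg1 <- arena_config(frame_rate_hz = 1)
  sch <- effective_onsets(epoch_schedule("LED", 0, 10), cfg1)
  # many flies, constant metric: flat curve at that constant
  n <- 24
  alpha0 <- seq(-165, 180, by = 15)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(movie_id = "m1", fly_id = sprintf("f%02d", i), frame = 0:10,
               x_mm = 10, y_mm = 0, heading_deg = wrap_angle(-alpha0[i] + 2 * (0:10)))
  }))
  ts <- track_set(rows, cfg1, sch)
  curve <- binned_onset_response(ts, metric = "cumulative_turn")
  expect_true(all(abs(curve$metric_mean - 20) < 1e-9, na.rm = TRUE))
  expect_true(all(curve$n_per_bin > 0))

  # a single fly defines the curve only near its own initial angle
  one <- track_set(rows[rows$fly_id == "f01", ], cfg1, sch)
  c1 <- binned_onset_response(one, metric = "cumulative_turn")
  inwin <- abs(wrap_angle(c1$initial_angle_deg - (-165))) <= 30
  expect_true(all(!is.na(c1$metric_mean[inwin])))
  expect_true(all(is.na(c1$metric_mean[!inwin])))
})

test_that("sinusoidal turning is recovered from the binned onset curve", {
  cfg1 <- arena_config(frame_rate_hz = 1)
  sch <- effective_onsets(epoch_schedule("LED", 0, 10), cfg1)
  amp <- 40  # injected cumulative amplitude, degrees over the 10-frame window
  alpha0 <- seq(-177.5, 180, by = 2.5)
  rows <- do.call(rbind, lapply(seq_along(alpha0), function(i) {
    step <- amp * sin(alpha0[i] * pi / 180) / 10
    data.frame(movie_id = "m1", fly_id = sprintf("f%03d", i), frame = 0:10,
               x_mm = 10, y_mm = 0,
               heading_deg = wrap_angle(-alpha0[i] + step * (0:10)))
  }))
  curve <- binned_onset_response(track_set(rows, cfg1, sch),
                                 metric = "cumulative_turn")
  s <- sin(curve$initial_angle_deg * pi / 180)
  a_hat <- sum(curve$metric_mean * s) / sum(s^2)
  # +/-30 degree smoothing shrinks a sinusoid by sin(w)/w, w = pi/6
  shrink <- sin(pi / 6) / (pi / 6)
  expect_equal(a_hat, amp * shrink, tolerance = 0.02)
  expect_lt(abs(a_hat - amp) / amp, 0.10)
})

test_that("return probability implements away-then-back within the window", {
  cfg1 <- arena_config(frame_rate_hz = 1)
  path <- function(out_t, back_t, total = 20, out_r = 12, back_r = 2) {
    x <- numeric(total + 1)
    x[(0:total) >= out_t & (0:total) < back_t] <- out_r
    x[(0:total) >= back_t] <- back_r
    x
  }
  # out to 12 mm at +5 s, back to 2 mm at +10 s: return at time0 = 0
  ts <- manual_ts(path(5, 10), y = 0, heading = 0, cfg = cfg1)
  rp <- return_probability(ts, window_s = 15)
  expect_equal(rp$p_return[rp$time0_s == 0], 1)

  # back only at +16 s: outside the 15-s window
  ts2 <- manual_ts(path(5, 16, total = 30), y = 0, heading = 0, cfg = cfg1)
  rp2 <- return_probability(ts2, window_s = 15)
  expect_equal(rp2$p_return[rp2$time0_s == 0], 0)

  # never beyond 9 mm: no return regardless of coming back
  ts3 <- manual_ts(path(5, 10, out_r = 9), y = 0, heading = 0, cfg = cfg1)
  rp3 <- return_probability(ts3, window_s = 15)
  expect_equal(rp3$p_return[rp3$time0_s == 0], 0)

  # time0 domain: length - window
  expect_equal(max(rp$time0_s), 20 + 1 - 15)
  expect_error(return_probability(ts, window_s = 60), "longer than")
})

test_that("return probability is monotone in window length and away threshold", {
  cfg <- arena_config()
  ts <- simulate_flies(sim_params(n_flies = 10, duration_s = 20, seed = 31),
                       cfg, led_schedule(2, 5, cfg))
  p_short <- return_probability(ts, window_s = 5, time0_step_s = 0.5)
  p_long <- return_probability(ts, window_s = 10, time0_step_s = 0.5)
  common <- intersect(p_short$time0_s[p_short$time0_s <= 10],
                      p_long$time0_s)
  expect_true(all(p_long$p_return[match(common, p_long$time0_s)] >=
                    p_short$p_return[match(common, p_short$time0_s)]))

  p_near <- return_probability(ts, away_mm = 5, window_s = 10,
                               time0_step_s = 0.5)
  p_far <- return_probability(ts, away_mm = 15, window_s = 10,
                              time0_step_s = 0.5)
  expect_true(all(p_far$p_return <= p_near$p_return))
})

test_that("preference index counts diagonal quadrant occupancy", {
  cfg1 <- arena_config(frame_rate_hz = 1)
  # 15 flies in quadrant 1, 5 in quadrant 2, constant over 60 frames
  tab <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(movie_id = "m1", fly_id = sprintf("f%02d", i), frame = 0:59,
               x_mm = if (i <= 15) 10 else 0,
               y_mm = if (i <= 15) 0 else 10, heading_deg = 0)
  }))
  ts <- track_set(tab, cfg1)
  res <- preference_index(ts, odor_one_quadrants = c(1, 3),
                          window_s = c(30, 60))
  expect_equal(res$pi, 0.5)
  # antisymmetry under swapping the quadrant pair
  swapped <- preference_index(ts, odor_one_quadrants = c(2, 4),
                              window_s = c(30, 60))
  expect_equal(swapped$pi, -res$pi)

  # equal counts in the diagonal pairs: PI = 0
  tab$y_mm <- rep(c(0, 10, 0, 10), 5)[match(tab$fly_id, unique(tab$fly_id))]
  tab$x_mm <- ifelse(tab$y_mm == 0, 10, 0)
  expect_equal(preference_index(track_set(tab, cfg1))$pi, 0)

  # all flies in the odor-1 quadrants: PI = 1
  tab$x_mm <- rep(c(10, -10), 10)[match(tab$fly_id, unique(tab$fly_id))]
  tab$y_mm <- 0
  expect_equal(preference_index(track_set(tab, cfg1))$pi, 1)
})

test_that("reciprocal averaging expresses PI toward CS+ and cancels shared bias", {
  # A: CS+ in the measured pair, PI +0.4; B: roles swapped, PI toward the
  # same pair -0.2 (i.e. +0.2 toward CS+): average toward CS+ is 0.3
  expect_equal(reciprocal_average(0.4, -0.2)$reciprocal_mean, 0.3)
  expect_equal(reciprocal_average(0, 0)$reciprocal_mean, 0)
  # a pure position bias appears identically in both runs and cancels
  b <- 0.27
  expect_equal(reciprocal_average(b, b)$reciprocal_mean, 0)
})

test_that("learning rate is the single-training to peak ratio", {
  expect_equal(learning_rate(0.05, 0.20), 0.25)
  expect_equal(learning_rate(0.2, 0.2), 1)
  expect_equal(learning_rate(0, 0.2), 0)
  expect_warning(lr <- learning_rate(0.1, 0), "zero peak")
  expect_true(is.na(lr))
})
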