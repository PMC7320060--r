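# Gaze attribution, visit segmentation, travelled-distance matrices.

test_that("gaze attribution handles the dead-ahead, behind and tie cases", {
  lay <- fixed_layouts()$light
  # synthetic painting set: one at (2, 0) facing -x
  pts <- tibble::tibble(item_id = "p1", room_id = "r", ordinal_pos = 1L,
                        x = 2, y = 0, nx = -1, ny = 0)
  lay2 <- lay; lay2$paintings <- pts
  s <- list(x_m = 0, y_m = 0, heading_deg = 0)
  expect_equal(attribute_gaze(s, lay2, ang_thresh_deg = 30, max_dist_m = 5), "p1")
  s$heading_deg <- 180
  expect_true(is.na(attribute_gaze(s, lay2, 30, 5)))

  # two candidates at +10 and -5 degrees: nearest angle wins
  pts2 <- tibble::tibble(
    item_id = c("plus10", "minus5"), room_id = "r", ordinal_pos = 1:2,
    x = 3 * cos(c(10, -5) * pi / 180), y = 3 * sin(c(10, -5) * pi / 180),
    nx = -cos(c(10, -5) * pi / 180), ny = -sin(c(10, -5) * pi / 180)
  )
  lay2$paintings <- pts2
  s <- list(x_m = 0, y_m = 0, heading_deg = 0)
  expect_equal(attribute_gaze(s, lay2, 30, 5), "minus5")

  # canvas facing away is never attributed
  pts3 <- pts; pts3$nx <- 1
  lay2$paintings <- pts3
  expect_true(is.na(attribute_gaze(list(x_m = 0, y_m = 0, heading_deg = 0), lay2, 30, 5)))
})

test_that("viewing time is 0.1 s per attributed sample (noiseless oracle)", {
  params <- cohort_params(walk_speed_sd = 0, dwell_sd = 0, heading_noise_sd = 0,
                          dwell_mean = 20)
  for (shape in c("open_rect", "s_shape")) {
    lay <- make_room_layout("room", shape, seed = 2)
    w <- simulate_walk(lay, params, seed = 5)
    v <- segment_visits(w, lay)
    v <- v[order(v$ordinal_pos), ]
    expect_true(all(abs(v$viewing_time - 20) <= 0.2))
    expect_false(any(v$flagged))
    # central times increase along the route
    expect_true(all(diff(v$central_t) > 0))
  }
})

test_that("gaze runs split by a short look-away pool into one visit", {
  lay <- fixed_layouts()$light
  p1 <- lay$paintings[lay$paintings$ordinal_pos == 1, ]
  n <- 50
  h0 <- (atan2(p1$y - p1$view_y, p1$x - p1$view_x) * 180 / pi) %% 360
  heading <- rep(h0, n)
  heading[20:22] <- (heading[20:22] + 120) %% 360  # 0.3 s look-away
  log <- tracklog(round((0:(n - 1)) * 0.1, 3), rep(p1$view_x, n),
                  rep(p1$view_y, n), heading)
  v <- segment_visits(log, lay, gap_tol_s = 0.5)
  v1 <- v[v$ordinal_pos == 1, ]
  expect_equal(v1$n_runs, 1L)
  expect_equal(v1$viewing_time, (n - 3) * 0.1)
  v2 <- segment_visits(log, lay, gap_tol_s = 0.1)
  expect_equal(v2$n_runs[v2$ordinal_pos == 1], 2L)
})

test_that("travelled distances integrate the path between central times", {
  # straight L path: (0,0) -> (3,0) -> (3,4) at 0.5 m/s, samples every 0.1 s
  xs <- c(seq(0, 3, by = 0.05), rep(3, 80), rep(3, 160))
  ys <- c(rep(0, 61), seq(0.05, 4, by = 0.05), rep(4, 160))
  n <- length(xs)
  log <- tracklog(round((0:(n - 1)) * 0.1, 3), xs, ys, rep(0, n))
  visits <- tibble::tibble(
    item_id = c("a", "b"), ordinal_pos = 1:2,
    first_gaze_t = c(0, 14), last_gaze_t = c(0, 14),
    central_t = c(0, round(log$t_s[n], 3)), central_x = c(0, 3),
    central_y = c(0, 4), viewing_time = c(.1, .1), n_runs = c(1L, 1L),
    flagged = FALSE
  )
  d <- travelled_distances(log, visits)
  expect_equal(d$spatial["a", "b"], 7, tolerance = 1e-9)
  expect_equal(d$temporal["a", "b"], log$t_s[n])

  # explicit central times 10 s and 25 s -> temporal distance 15 s
  visits$central_t <- c(10, 25)
  d2 <- travelled_distances(log, visits)
  expect_equal(d2$temporal["a", "b"], 15)

  visits$central_t <- c(25, 10)
  expect_error(travelled_distances(log, visits), class = "walkmem_config_error")
})

test_that("cumulative path length is additive through any intermediate visit", {
  lay <- make_room_layout("light", "open_rect", seed = 4)
  w <- simulate_walk(lay, cohort_params(), seed = 21)
  v <- segment_visits(w, lay)
  v <- v[order(v$central_t), ]
  d <- travelled_distances(w, v)
  for (i in 1:7) for (k in (i + 1):8) for (j in (k + 1):9) {
    expect_equal(d$spatial[i, j], d$spatial[i, k] + d$spatial[k, j],
                 tolerance = 1e-9)
  }
  up <- upper.tri(d$spatial)
  expect_true(all(d$spatial[up] >= 0))
  expect_true(all(d$temporal[up] >= d$spatial[up] / d$v_max - 1e-9))
})

test_that("a never-gazed painting is flagged with a closest-approach central time", {
  lay <- fixed_layouts()$light
  w <- simulate_walk(lay, cohort_params(walk_speed_sd = 0, dwell_sd = 0,
                                        heading_noise_sd = 0), seed = 2)
  dw <- attr(w, "dwells")
  # truncate before the last painting's dwell: painting 9 never gazed
  keep <- w$t_s < dw$t_start[9]
  short <- tracklog(w$t_s[keep], w$x_m[keep], w$y_m[keep], w$heading_deg[keep],
                    participant_id = "P", room_id = "light")
  v <- segment_visits(short, lay)
  v9 <- v[v$ordinal_pos == 9, ]
  expect_true(v9$flagged)
  expect_equal(v9$viewing_time, 0)
  expect_true(is.na(v9$first_gaze_t))
  # closest approach over the whole log
  p9 <- lay$paintings[lay$paintings$ordinal_pos == 9, ]
  dists <- sqrt((short$x_m - p9$x)^2 + (short$y_m - p9$y)^2)
  expect_equal(v9$central_t, short$t_s[which.min(dists)])
})

test_that("room summaries report time in room and mean viewing time", {
  lay <- fixed_layouts()$light
  set.seed(1)
  log <- tracklog(round((0:599) * 0.1, 3), runif(600, 1, 3), runif(600, 1, 5),
                  runif(600, 0, 359), participant_id = "P01", room_id = "light")
  v <- segment_visits(log, lay)
  rs <- room_summaries(list(light = log), list(light = v))
  expect_equal(rs$time_in_room_s, 60)

  params <- cohort_params(walk_speed_sd = 0, dwell_sd = 0, heading_noise_sd = 0)
  w <- simulate_walk(lay, params, seed = 3)
  v <- segment_visits(w, lay)
  rs <- room_summaries(list(light = w), list(light = v))
  expect_equal(rs$mean_viewing_time_s, 20, tolerance = 0.01)

  empty <- room_summaries(list(light = log), list(light = v[0, ]))
  expect_true(empty$empty_visits)
  expect_equal(empty$mean_viewing_time_s, 0)
})

test_that("spatial and temporal distances are strongly correlated in cohorts", {
  an <- analyze_cohort(small_cohort(), seed = 2, scope = "dmpf")
  expect_gt(an$dist_correlation, 0.5)
})
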