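# Walking simulator: moves a virtual participant along the instructed route,
# dwelling in front of each painting, and emits a 10 Hz trajectory log.

#' Simulate one room walk
#'
#' The walker starts at the first route waypoint and follows the route
#' polyline. Each leg toward the next painting is walked at a speed drawn
#' from a truncated normal (truncation at +/- 3.5 SD keeps the per-sample
#' kinematic bound `(mean + 4 SD) * 0.1 m` valid despite duration rounding);
#' at each painting's viewing point the walker stops and faces the canvas for
#' a dwell drawn from a truncated normal. Leg and dwell durations are
#' quantised to the 0.1 s sampling grid so samples fall exactly on the
#' polyline. Heading is the direction of motion while walking and the
#' direction to the current painting while dwelling, plus Gaussian yaw noise.
#'
#' @param layout a [make_room_layout()] result.
#' @param params a [cohort_params()] list (uses `walk_speed_mean/sd`,
#'   `dwell_mean/sd`, `heading_noise_sd`).
#' @param seed integer seed.
#' @param participant_id label stored on the log.
#' @return a validated [tracklog()] sampled strictly every 0.1 s, with a
#'   `dwells` attribute (tibble: `ordinal, t_start, t_end`) recording the
#'   ground-truth dwell windows.
#' @export
simulate_walk <- function(layout, params, seed = 1,
                          participant_id = "P01") {
  stopifnot(inherits(layout, "walkmem_room_layout"))
  if (params$walk_speed_mean <= 0 || params$dwell_mean <= 0)
    abort("walk speed and dwell means must be positive.",
          class = "walkmem_config_error")
  if (params$walk_speed_sd < 0 || params$dwell_sd < 0)
    abort("walk speed and dwell SDs must be non-negative.",
          class = "walkmem_config_error")
  route <- layout$route
  pts <- layout$paintings
  with_seed(seed, {
    speeds <- rnorm_trunc(9, params$walk_speed_mean, params$walk_speed_sd,
                          lo = max(0.02, params$walk_speed_mean - 3.5 * params$walk_speed_sd),
                          hi = params$walk_speed_mean + 3.5 * params$walk_speed_sd)
    dwells <- rnorm_trunc(9, params$dwell_mean, params$dwell_sd,
                          lo = max(0.5, params$dwell_mean - 3.5 * params$dwell_sd),
                          hi = params$dwell_mean + 3.5 * params$dwell_sd)
    dwells <- pmax(0.1, round(dwells, 1))

    # Build the piecewise-linear (t, x, y) timeline. Knots are waypoint
    # arrivals plus dwell endpoints; all knot times are multiples of 0.1 s.
    kt <- 0; kx <- route$x[1]; ky <- route$y[1]
    dwell_tab <- matrix(NA_real_, nrow = 9, ncol = 2)
    leg <- 1L  # index of the next painting to be reached
    t_now <- 0
    for (i in seq_len(nrow(route))[-1]) {
      len <- sqrt((route$x[i] - route$x[i - 1])^2 + (route$y[i] - route$y[i - 1])^2)
      dur <- max(0.1, ceiling(len / speeds[min(leg, 9)] * 10) / 10)
      t_now <- round(t_now + dur, 1)
      kt <- c(kt, t_now); kx <- c(kx, route$x[i]); ky <- c(ky, route$y[i])
      ord <- route$ordinal[i]
      if (!is.na(ord)) {
        dwell_tab[ord, ] <- c(t_now, round(t_now + dwells[ord], 1))
        t_now <- round(t_now + dwells[ord], 1)
        kt <- c(kt, t_now); kx <- c(kx, route$x[i]); ky <- c(ky, route$y[i])
        leg <- leg + 1L
      }
    }

    n <- round(t_now / TRACKLOG_DT)
    t <- round((seq_len(n) - 1) * TRACKLOG_DT, 3)
    x <- approx(kt, kx, xout = t, rule = 2)$y
    y <- approx(kt, ky, xout = t, rule = 2)$y

    # Which samples fall in a dwell window [start, end)?
    dwell_of <- rep(NA_integer_, n)
    for (k in 1:9) {
      sel <- t >= dwell_tab[k, 1] - 1e-9 & t < dwell_tab[k, 2] - 1e-9
      dwell_of[sel] <- k
    }
    heading <- numeric(n)
    moving <- c(sqrt(diff(x)^2 + diff(y)^2) > 1e-9, FALSE)
    walk_idx <- which(is.na(dwell_of) & moving)
    heading[walk_idx] <- atan2(y[walk_idx + 1] - y[walk_idx],
                               x[walk_idx + 1] - x[walk_idx]) * 180 / pi
    dw_idx <- which(!is.na(dwell_of))
    k <- dwell_of[dw_idx]
    heading[dw_idx] <- atan2(pts$y[k] - y[dw_idx], pts$x[k] - x[dw_idx]) * 180 / pi
    still_idx <- which(is.na(dwell_of) & !moving)
    for (i in still_idx) heading[i] <- if (i > 1) heading[i - 1] else 0
    if (params$heading_noise_sd > 0)
      heading <- heading + rnorm(n, 0, params$heading_noise_sd)
    heading <- wrap_deg(heading)

    log <- tracklog(t, x, y, heading,
                    participant_id = participant_id, room_id = layout$room_id)
    attr(log, "dwells") <- tibble(ordinal = 1:9,
                                  t_start = dwell_tab[, 1], t_end = dwell_tab[, 2],
                                  dwell_s = dwell_tab[, 2] - dwell_tab[, 1])
    log
  })
}
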