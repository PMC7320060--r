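# Trajectory features: attribute helmet gaze to paintings, segment per-
# painting visits with central times and viewing times, and integrate the
# travelled spatial/temporal distance matrices that feed the d-MPF.

# Vectorised gaze attribution over all samples of a log. Returns an integer
# vector of painting ordinals (NA = no painting attended). A painting is a
# candidate when it lies within `max_dist_m`, within `ang_thresh_deg` of the
# heading, and its canvas faces the walker (dot(wall normal, walker->painting)
# < 0). Ties go to the smallest absolute gaze angle.
attribute_gaze_samples <- function(x, y, heading, paintings,
                                   ang_thresh_deg = 15, max_dist_m = 4) {
  if (ang_thresh_deg <= 0 || max_dist_m <= 0)
    abort("gaze thresholds must be positive.", class = "walkmem_config_error")
  n <- length(x)
  hx <- cos(heading * pi / 180)
  hy <- sin(heading * pi / 180)
  best <- rep(NA_integer_, n)
  best_ang <- rep(Inf, n)
  dists <- matrix(0, n, nrow(paintings))
  cos_thresh <- cos(ang_thresh_deg * pi / 180)
  for (k in seq_len(nrow(paintings))) {
    dx <- paintings$x[k] - x
    dy <- paintings$y[k] - y
    dist <- sqrt(dx^2 + dy^2)
    dists[, k] <- dist
    # gaze angle via the dot product with the heading unit vector
    cosang <- (dx * hx + dy * hy) / pmax(dist, 1e-12)
    ok <- dist <= max_dist_m & cosang >= cos_thresh &
      (dx * paintings$nx[k] + dy * paintings$ny[k]) < 0
    if (!any(ok)) next
    ang <- acos(pmin(1, pmax(-1, cosang[ok]))) * 180 / pi
    take_sub <- ang < best_ang[ok]
    take <- which(ok)[take_sub]
    best[take] <- k
    best_ang[take] <- ang[take_sub]
  }
  structure(as.integer(paintings$ordinal_pos[best]),
            dist_matrix = dists)
}

#' Attribute one gaze sample to a painting
#'
#' @param sample list or one-row data frame with `x_m`, `y_m`, `heading_deg`.
#' @param layout the room layout.
#' @param ang_thresh_deg gaze cone half-angle (degrees).
#' @param max_dist_m maximum gaze distance (m).
#' @return the attended painting's `item_id`, or `NA` if none.
#' @export
#' @examples
#' lay <- make_room_layout("light", "open_rect", seed = 1, jitter = 0)
#' p <- lay$paintings[1, ]
#' attribute_gaze(list(x_m = p$view_x, y_m = p$view_y,
#'                     heading_deg = atan2(p$y - p$view_y, p$x - p$view_x) * 180 / pi),
#'                lay)
attribute_gaze <- function(sample, layout, ang_thresh_deg = 15, max_dist_m = 4) {
  ord <- attribute_gaze_samples(sample$x_m, sample$y_m,
                                wrap_deg(sample$heading_deg),
                                layout$paintings, ang_thresh_deg, max_dist_m)
  if (is.na(ord)) NA_character_ else
    layout$paintings$item_id[match(ord, layout$paintings$ordinal_pos)]
}

#' Segment per-painting visits from a trajectory log
#'
#' Pools all gaze samples attributed to each painting into one visit record:
#' `viewing_time` is 0.1 s per attributed sample, the gaze span runs from the
#' first to the last attributed sample (runs separated by gaps up to
#' `gap_tol_s` count as one run in `n_runs`), and `central_t` is the sample
#' of closest approach to the painting within that span
#' (`central_time_mode = "closest_approach"`, the default) or the sample
#' nearest the middle of the span (`"gaze_midpoint"`). Paintings that were
#' never gazed at are retained with `viewing_time` 0 and `central_t` at the
#' closest-approach sample over the whole log, and are flagged.
#'
#' @param log a validated tracklog.
#' @param layout the matching room layout.
#' @param gap_tol_s look-away tolerance when merging gaze runs (s).
#' @param ang_thresh_deg,max_dist_m gaze attribution thresholds.
#' @param central_time_mode `"closest_approach"` or `"gaze_midpoint"`.
#' @return tibble with one row per painting: `item_id, ordinal_pos,
#'   first_gaze_t, last_gaze_t, central_t, central_x, central_y,
#'   viewing_time, n_runs, flagged`.
#' @export
segment_visits <- function(log, layout, gap_tol_s = 0.5,
                           ang_thresh_deg = 15, max_dist_m = 4,
                           central_time_mode = c("closest_approach", "gaze_midpoint")) {
  central_time_mode <- match.arg(central_time_mode)
  validate_tracklog(log)
  pts <- layout$paintings
  ord <- attribute_gaze_samples(log$x_m, log$y_m, log$heading_deg, pts,
                                ang_thresh_deg, max_dist_m)
  dist_mat <- attr(ord, "dist_matrix")
  gap_samples <- round(gap_tol_s / TRACKLOG_DT)
  n_p <- nrow(pts)
  first_t <- last_t <- central_t <- cx <- cy <- vt <- numeric(n_p)
  runs <- integer(n_p)
  flag <- logical(n_p)
  item <- character(n_p)
  for (k in seq_len(n_p)) {
    row <- which(pts$ordinal_pos == k)
    item[k] <- pts$item_id[row]
    dists <- dist_mat[, row]
    idx <- which(!is.na(ord) & ord == k)
    if (length(idx) == 0) {
      ci <- which.min(dists)
      first_t[k] <- NA_real_; last_t[k] <- NA_real_
      central_t[k] <- log$t_s[ci]; cx[k] <- log$x_m[ci]; cy[k] <- log$y_m[ci]
      vt[k] <- 0; runs[k] <- 0L; flag[k] <- TRUE
      next
    }
    span <- seq(min(idx), max(idx))
    ci <- if (central_time_mode == "closest_approach") {
      span[which.min(dists[span])]
    } else {
      span[which.min(abs(log$t_s[span] - (log$t_s[min(idx)] + log$t_s[max(idx)]) / 2))]
    }
    first_t[k] <- log$t_s[min(idx)]; last_t[k] <- log$t_s[max(idx)]
    central_t[k] <- log$t_s[ci]; cx[k] <- log$x_m[ci]; cy[k] <- log$y_m[ci]
    vt[k] <- length(idx) * TRACKLOG_DT
    runs[k] <- 1L + sum(diff(idx) - 1L > gap_samples)
  }
  visits <- tibble(
    item_id = item, ordinal_pos = seq_len(n_p),
    first_gaze_t = first_t, last_gaze_t = last_t,
    central_t = central_t, central_x = cx, central_y = cy,
    viewing_time = vt, n_runs = runs, flagged = flag
  )
  ok <- visits$flagged |
    (visits$first_gaze_t - 1e-9 <= visits$central_t &
       visits$central_t <= visits$last_gaze_t + 1e-9 &
       visits$viewing_time <= visits$last_gaze_t - visits$first_gaze_t + TRACKLOG_DT + 1e-9)
  assert_that(all(ok), "visit record invariants violated.")
  visits
}

#' Travelled spatial and temporal distance matrices
#'
#' For every pair of paintings, integrates the cumulative path length walked
#' between their central visit times (spatial distance, m) and the elapsed
#' time between them (temporal distance, s). Entries are indexed by the
#' order of the `visits` rows, which must be sorted by `central_t`.
#'
#' @param log a validated tracklog.
#' @param visits a [segment_visits()] result ordered by `central_t`.
#' @return a `walkmem_distances` list: `spatial` and `temporal` 9 x 9
#'   matrices (upper triangle filled, item ids as dimnames), `flagged`
#'   per-painting flags, and the `visits` table.
#' @export
travelled_distances <- function(log, visits) {
  validate_tracklog(log)
  if (is.unsorted(visits$central_t, strictly = FALSE))
    abort("visits must be ordered by central_t.", class = "walkmem_config_error")
  n <- nrow(visits)
  cumdist <- c(0, cumsum(sqrt(diff(log$x_m)^2 + diff(log$y_m)^2)))
  idx <- match(round(visits$central_t * 1000), round(log$t_s * 1000))
  assert_that(!anyNA(idx), "central times must coincide with log samples.")
  spatial <- matrix(0, n, n, dimnames = list(visits$item_id, visits$item_id))
  temporal <- spatial
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    spatial[i, j] <- cumdist[idx[j]] - cumdist[idx[i]]
    temporal[i, j] <- visits$central_t[j] - visits$central_t[i]
  }
  res <- structure(
    list(participant_id = attr(log, "participant_id"),
         room_id = attr(log, "room_id"),
         spatial = spatial, temporal = temporal,
         flagged = stats::setNames(visits$flagged, visits$item_id),
         visits = visits,
         v_max = max(sqrt(diff(log$x_m)^2 + diff(log$y_m)^2)) / TRACKLOG_DT),
    class = "walkmem_distances"
  )
  validate_distances(res)
  res
}

validate_distances <- function(d) {
  up <- upper.tri(d$spatial)
  assert_that(all(d$spatial[up] >= 0) && all(d$temporal[up] >= 0),
              "travelled distances must be non-negative.")
  if (d$v_max > 0)
    assert_that(all(d$temporal[up] >= d$spatial[up] / d$v_max - 1e-9),
                "temporal distance must be >= spatial distance / max speed.")
  # cumulative path length is nondecreasing in elapsed time
  n <- nrow(d$spatial)
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      assert_that(all(diff(d$spatial[i, seq(i + 1, n)]) >= -1e-9),
                  "cumulative travelled distance must be nondecreasing.")
    }
  }
  invisible(d)
}

# Distance between two paintings (unordered), by item id.
distance_between <- function(distances, item_a, item_b, metric = "spatial") {
  i <- match(item_a, rownames(distances[[metric]]))
  j <- match(item_b, colnames(distances[[metric]]))
  if (is.na(i) || is.na(j))
    abort("unknown item id in distance lookup.", class = "walkmem_config_error")
  distances[[metric]][min(i, j), max(i, j)]
}

#' Per-room walking summaries
#'
#' @param logs named list (by room id) of tracklogs for one participant.
#' @param visits named list (by room id) of matching [segment_visits()]
#'   tables.
#' @return tibble: `participant_id, room_id, time_in_room_s,
#'   mean_viewing_time_s, total_viewing_time_s, n_flagged`; zero rows with a
#'   flag when a visit table is empty.
#' @export
room_summaries <- function(logs, visits) {
  rows <- lapply(names(logs), function(rm) {
    log <- logs[[rm]]
    v <- visits[[rm]]
    tibble(
      participant_id = attr(log, "participant_id") %||% NA_character_,
      room_id = rm,
      time_in_room_s = nrow(log) * TRACKLOG_DT,
      mean_viewing_time_s = if (is.null(v) || nrow(v) == 0) 0 else mean(v$viewing_time),
      total_viewing_time_s = if (is.null(v) || nrow(v) == 0) 0 else sum(v$viewing_time),
      n_flagged = if (is.null(v)) NA_integer_ else sum(v$flagged),
      empty_visits = is.null(v) || nrow(v) == 0
    )
  })
  bind_rows(rows)
}
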