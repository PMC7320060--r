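# Museum room layouts: a 4 x 6 m floor with nine wall paintings and a fixed
# instructed route that passes a viewing point in front of each painting in
# ordinal order. Two shapes are provided: "open_rect" (open rectangle with a
# central bench/statue obstacle the route skirts) and "s_shape" (two interior
# wall segments forcing an S-shaped corridor). Coordinates are meters; wall
# normals are unit vectors pointing into the walkable space (the direction
# the canvas faces).

# Base geometry for a 4 (x) by 6 (y) floor. Columns: painting position (x, y),
# canvas normal (nx, ny), viewing point (vx, vy) 1.2 m in front of the canvas.
# Routes are axis-aligned so that, while walking, no painting lies both within
# gaze range and near the direction of travel; each viewing point is
# approached tangentially (parallel to its wall).
room_geometry <- function(shape) {
  if (shape == "open_rect") {
    paintings <- tibble(
      ordinal_pos = 1:9,
      x  = c(2.4, 3.4, 4.0, 4.0, 4.0, 1.7, 1.2, 0.0, 0.0),
      y  = c(0.0, 0.0, 2.6, 3.9, 5.2, 6.0, 6.0, 3.6, 2.2),
      nx = c(0, 0, -1, -1, -1, 0, 0, 1, 1),
      ny = c(1, 1, 0, 0, 0, -1, -1, 0, 0)
    )
    route <- tibble(
      x = c(0.6, 2.4, 3.4, 2.8, 2.8, 2.8, 2.8, 2.8, 1.7, 1.2, 1.2, 1.2),
      y = c(1.2, 1.2, 1.2, 1.2, 2.6, 3.9, 5.2, 4.8, 4.8, 4.8, 3.6, 2.2),
      ordinal = c(NA, 1, 2, NA, 3, 4, 5, NA, 6, 7, 8, 9)
    )
    obstacle <- list(x = 2.0, y = 3.0, radius = 0.6)
  } else if (shape == "s_shape") {
    # Interior wall A: y = 2, x in [0, 2.6]; wall B: y = 4, x in [1.4, 4].
    paintings <- tibble(
      ordinal_pos = 1:9,
      x  = c(1.4, 2.6, 4.0, 2.0, 0.9, 0.0, 1.7, 2.5, 3.3),
      y  = c(0.0, 0.0, 2.8, 4.0, 2.0, 5.2, 4.0, 4.0, 4.0),
      nx = c(0, 0, -1, 0, 0, 1, 0, 0, 0),
      ny = c(1, 1, 0, -1, 1, 0, 1, 1, 1)
    )
    route <- tibble(
      x = c(0.5, 1.4, 2.6, 3.3, 3.3, 2.8, 2.0, 1.5, 1.5, 0.9, 0.7, 0.7,
            1.2, 1.7, 2.5, 3.3),
      y = c(1.2, 1.2, 1.2, 1.2, 2.8, 2.8, 2.8, 2.8, 3.2, 3.2, 3.2, 5.2,
            5.2, 5.2, 5.2, 5.2),
      ordinal = c(NA, 1, 2, NA, NA, 3, 4, NA, NA, 5, NA, NA,
                  6, 7, 8, 9)
    )
    obstacle <- list(
      walls = list(a = list(y = 2, x_from = 0.0, x_to = 2.6),
                   b = list(y = 4, x_from = 1.4, x_to = 4.0))
    )
  } else {
    abort(paste0("unknown room shape: '", shape, "'"),
          class = "walkmem_config_error")
  }
  list(paintings = paintings, route = route, obstacle = obstacle,
       base_extent = c(4, 6))
}

#' Build a museum room layout
#'
#' Places nine paintings on the walls of a `width x depth` m floor (default
#' 4 x 6 m) and lays out the instructed walking route that passes a viewing
#' point ~1.2 m in front of each painting, in ordinal order. `"open_rect"`
#' rooms route around a central obstacle; `"s_shape"` rooms snake around two
#' interior wall segments. A small seeded tangential jitter individualises
#' painting positions between layout seeds.
#'
#' @param room_id room label, conventionally `"light"` or `"dark"`.
#' @param shape `"open_rect"` or `"s_shape"`.
#' @param seed integer seed for the position jitter.
#' @param extent `c(width, depth)` in meters.
#' @param jitter half-range (m) of the tangential position jitter.
#' @return a `walkmem_room_layout`: list with `room_id`, `shape`, `extent`,
#'   `paintings` (tibble: `item_id, room_id, ordinal_pos, x, y, nx, ny,
#'   view_x, view_y`) and `route` (tibble: `x, y, ordinal`).
#' @export
#' @examples
#' lay <- make_room_layout("light", "open_rect", seed = 1)
#' nrow(lay$paintings)  # 9
make_room_layout <- function(room_id, shape = c("open_rect", "s_shape"),
                             seed = 1, extent = c(4, 6), jitter = 0.05) {
  if (!is.character(shape) || !shape[1] %in% c("open_rect", "s_shape"))
    abort(paste0("unknown room shape: '", shape[1], "'"),
          class = "walkmem_config_error")
  shape <- shape[1]
  geo <- room_geometry(shape)
  sc <- extent / geo$base_extent
  p <- geo$paintings
  r <- geo$route
  p$x <- p$x * sc[1]; p$y <- p$y * sc[2]
  r$x <- r$x * sc[1]; r$y <- r$y * sc[2]
  # Tangential jitter along the wall individualises painting positions.
  # Viewpoints (route waypoints) stay fixed so route legs remain exactly
  # axis-aligned; the dwell heading simply tracks the jittered canvas.
  shift <- with_seed(seed, runif(nrow(p), -jitter, jitter))
  p$x <- p$x + shift * (-p$ny)
  p$y <- p$y + shift * p$nx
  vp_idx <- match(p$ordinal_pos, r$ordinal)
  offset <- sqrt((r$x[vp_idx] - p$x)^2 + (r$y[vp_idx] - p$y)^2)
  paintings <- tibble(
    item_id = sprintf("%s_%02d", room_id, p$ordinal_pos),
    room_id = room_id, ordinal_pos = p$ordinal_pos,
    x = p$x, y = p$y, nx = p$nx, ny = p$ny,
    view_x = r$x[vp_idx], view_y = r$y[vp_idx]
  )
  layout <- structure(
    list(room_id = room_id, shape = shape, extent = extent,
         paintings = paintings, route = r, obstacle = geo$obstacle,
         viewpoint_offset = offset, seed = seed),
    class = "walkmem_room_layout"
  )
  validate_room_layout(layout)
  layout
}

validate_room_layout <- function(layout) {
  p <- layout$paintings
  assert_that(nrow(p) == 9, "a room layout must contain exactly 9 paintings.")
  assert_that(setequal(p$ordinal_pos, 1:9),
              "painting ordinal positions must be a permutation of 1..9.")
  tol <- 1e-9
  assert_that(all(p$x >= -tol & p$x <= layout$extent[1] + tol &
                    p$y >= -tol & p$y <= layout$extent[2] + tol),
              "all painting positions must lie inside the room extent.")
  assert_that(all(abs(sqrt(p$nx^2 + p$ny^2) - 1) < 1e-9),
              "wall normals must have unit length.")
  d <- as.matrix(stats::dist(cbind(p$x, p$y)))
  assert_that(all(d[upper.tri(d)] > 1e-6),
              "painting positions must be pairwise distinct.")
  ord_on_route <- layout$route$ordinal[!is.na(layout$route$ordinal)]
  assert_that(identical(as.integer(ord_on_route), 1:9),
              "the route must visit the paintings in ordinal order.")
  invisible(layout)
}

#' @export
print.walkmem_room_layout <- function(x, ...) {
  cat(sprintf("<room layout '%s' (%s), %.0fx%.0f m, 9 paintings, route %.1f m>\n",
              x$room_id, x$shape, x$extent[1], x$extent[2],
              sum(sqrt(diff(x$route$x)^2 + diff(x$route$y)^2))))
  invisible(x)
}
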