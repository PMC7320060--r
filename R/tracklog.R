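# Trajectory log format: one CSV per participant x room with header
# t_s,x_m,y_m,heading_deg; positions at millimeter resolution, samples at a
# strict 10 Hz (0.100 s) grid; heading in degrees counter-clockwise from the
# +x axis, wrapped to [0, 360).

TRACKLOG_HZ <- 10
TRACKLOG_DT <- 0.1

#' Construct a trajectory log
#'
#' @param t,x,y,heading numeric vectors of equal length: sample times (s),
#'   XY position (m) and yaw heading (degrees CCW from +x, in `[0, 360)`).
#' @param participant_id,room_id identifying labels carried as attributes.
#' @param validate run [validate_tracklog()] on the result.
#' @return a `walkmem_tracklog` tibble with columns `t_s,x_m,y_m,heading_deg`.
#' @export
tracklog <- function(t, x, y, heading, participant_id = NA_character_,
                     room_id = NA_character_, validate = TRUE) {
  log <- tibble::new_tibble(
    list(t_s = as.numeric(t), x_m = as.numeric(x), y_m = as.numeric(y),
         heading_deg = as.numeric(heading)),
    nrow = length(t))
  attr(log, "participant_id") <- participant_id
  attr(log, "room_id") <- room_id
  class(log) <- c("walkmem_tracklog", "tbl_df", "tbl", "data.frame")
  if (validate) validate_tracklog(log)
  log
}

#' Validate a trajectory log
#'
#' Checks the format invariants: strictly increasing times on the 0.100 s
#' grid (tolerance 1e-6 s), finite positions, and heading in `[0, 360)`.
#'
#' @param log a tracklog tibble.
#' @return the log, invisibly; aborts with class `walkmem_corrupt_log` on
#'   violation.
#' @export
validate_tracklog <- function(log) {
  need <- c("t_s", "x_m", "y_m", "heading_deg")
  if (!all(need %in% names(log)))
    abort("tracklog is missing required columns t_s,x_m,y_m,heading_deg.",
          class = "walkmem_corrupt_log")
  if (nrow(log) < 2)
    abort("tracklog must contain at least 2 samples.", class = "walkmem_corrupt_log")
  dt <- diff(log$t_s)
  if (any(dt <= 0))
    abort("tracklog timestamps are not strictly increasing.",
          class = "walkmem_corrupt_log")
  if (any(abs(dt - TRACKLOG_DT) > 1e-6))
    abort("tracklog sampling deviates from the 0.100 s grid.",
          class = "walkmem_corrupt_log")
  if (any(!is.finite(log$x_m)) || any(!is.finite(log$y_m)))
    abort("tracklog contains non-finite positions.", class = "walkmem_corrupt_log")
  if (any(!is.finite(log$heading_deg)) ||
      any(log$heading_deg < 0 | log$heading_deg >= 360))
    abort("tracklog heading must lie in [0, 360).", class = "walkmem_corrupt_log")
  invisible(log)
}

#' Write a trajectory log to CSV
#'
#' Positions and times are written to 3 decimals (millimeter / millisecond
#' resolution); heading to 3 decimals. The canonical file name is
#' `<participant>_<room>.csv`.
#'
#' @param log a validated tracklog.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracklog <- function(log, path) {
  validate_tracklog(log)
  out <- data.frame(
    t_s = sprintf("%.3f", log$t_s),
    x_m = sprintf("%.3f", log$x_m),
    y_m = sprintf("%.3f", log$y_m),
    heading_deg = sprintf("%.3f", log$heading_deg)
  )
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) abort(paste0("cannot write tracklog: ", conditionMessage(e)),
                              class = "walkmem_io_error")
  )
  invisible(path)
}

#' Read a trajectory log from CSV
#'
#' In strict mode any deviation from the format invariants aborts with
#' `walkmem_corrupt_log`. In non-strict mode isolated single-sample gaps
#' (one missing 0.1 s sample) are filled by linear interpolation (heading
#' interpolated on the shortest arc) and counted in the `n_interpolated`
#' attribute; logs whose gap fraction exceeds `max_gap_frac` are still
#' rejected as corrupt.
#'
#' @param path CSV file path.
#' @param strict reject any irregular sampling instead of repairing it.
#' @param max_gap_frac maximum tolerated fraction of interpolated samples.
#' @param participant_id,room_id optional labels; defaults are parsed from a
#'   `<participant>_<room>.csv` file name.
#' @param heading_convention `"ccw_from_x"` (the canonical convention:
#'   degrees counter-clockwise from the +x axis) or `"cw_from_north"`
#'   (compass-style: clockwise from +y), converted on read.
#' @return a validated tracklog; missing files abort with class
#'   `walkmem_missing_log`.
#' @export
read_tracklog <- function(path, strict = FALSE, max_gap_frac = 0.05,
                          participant_id = NULL, room_id = NULL,
                          heading_convention = c("ccw_from_x", "cw_from_north")) {
  heading_convention <- match.arg(heading_convention)
  if (!file.exists(path))
    abort(paste0("trajectory log not found: ", path), class = "walkmem_missing_log")
  stem <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(stem, "_")[[1]]
  if (is.null(participant_id))
    participant_id <- if (length(parts) >= 2) paste(parts[-length(parts)], collapse = "_") else stem
  if (is.null(room_id))
    room_id <- if (length(parts) >= 2) parts[length(parts)] else NA_character_
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) abort(paste0("unparseable trajectory log: ", path),
                              class = "walkmem_corrupt_log")
  )
  if (!all(c("t_s", "x_m", "y_m", "heading_deg") %in% names(raw)) ||
      nrow(raw) < 2 || anyNA(raw))
    abort(paste0("unparseable or incomplete trajectory log: ", path),
          class = "walkmem_corrupt_log")
  if (heading_convention == "cw_from_north")
    raw$heading_deg <- wrap_deg(90 - raw$heading_deg)
  n_interp <- 0L
  if (!strict) {
    dt <- diff(raw$t_s)
    if (any(dt <= 0))
      abort("tracklog timestamps are not strictly increasing.",
            class = "walkmem_corrupt_log")
    gap1 <- which(abs(dt - 2 * TRACKLOG_DT) <= 1e-6)  # exactly one missing sample
    if (length(gap1) > 0) {
      if (length(gap1) / (nrow(raw) + length(gap1)) > max_gap_frac)
        abort(paste0("trajectory log has too many gaps: ", path),
              class = "walkmem_corrupt_log")
      fill <- tibble(
        t_s = raw$t_s[gap1] + TRACKLOG_DT,
        x_m = (raw$x_m[gap1] + raw$x_m[gap1 + 1]) / 2,
        y_m = (raw$y_m[gap1] + raw$y_m[gap1 + 1]) / 2,
        heading_deg = wrap_deg(raw$heading_deg[gap1] +
                                 ang_diff_deg(raw$heading_deg[gap1 + 1],
                                              raw$heading_deg[gap1]) / 2)
      )
      raw <- arrange(bind_rows(raw, fill), .data$t_s)
      n_interp <- nrow(fill)
      warn(sprintf("interpolated %d missing sample(s) in %s", n_interp, path))
    }
  }
  log <- tracklog(raw$t_s, raw$x_m, raw$y_m, raw$heading_deg,
                  participant_id = participant_id, room_id = room_id)
  attr(log, "n_interpolated") <- n_interp
  log
}
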