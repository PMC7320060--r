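# Pipeline orchestration: a resolved configuration object, an in-memory
# end-to-end analysis of a cohort, and the disk-artifact commands
# (simulate | features | analyze | dmpf | report) that mirror it for file
# based workflows. Every command is deterministic given config + seed and
# writes its resolved configuration next to its outputs.

#' Analysis configuration
#'
#' Collects every tunable analysis parameter with the pipeline defaults:
#' gaze attribution thresholds, visit gap tolerance and central-time
#' convention, conditional-rate eligibility, d-MPF binning, permutation
#' settings and the Bayes-factor prior scale.
#'
#' @param ang_thresh_deg gaze cone half-angle (degrees).
#' @param max_dist_m maximum gaze distance (m).
#' @param gap_tol_s look-away tolerance when pooling gaze runs (s).
#' @param central_time_mode `"closest_approach"` or `"gaze_midpoint"`.
#' @param min_pairs eligibility threshold for conditional rates.
#' @param n_bins d-MPF bins.
#' @param contrast_mode `"extreme_bins"` or `"linear_trend"`.
#' @param n_perm permutations for the d-MPF test.
#' @param r_scale Cauchy prior scale for BF01.
#' @param confidence_direction `"sure_low"` (1 = Sure) or `"sure_high"`.
#' @param strict_logs reject rather than repair single-sample log gaps.
#' @return a named list of class `walkmem_config`.
#' @export
analysis_config <- function(ang_thresh_deg = 15, max_dist_m = 4,
                            gap_tol_s = 0.5,
                            central_time_mode = "closest_approach",
                            min_pairs = 1, n_bins = 5,
                            contrast_mode = "extreme_bins", n_perm = 2000,
                            r_scale = sqrt(2) / 2,
                            confidence_direction = "sure_low",
                            strict_logs = FALSE) {
  structure(list(ang_thresh_deg = ang_thresh_deg, max_dist_m = max_dist_m,
                 gap_tol_s = gap_tol_s, central_time_mode = central_time_mode,
                 min_pairs = min_pairs, n_bins = n_bins,
                 contrast_mode = contrast_mode, n_perm = n_perm,
                 r_scale = r_scale,
                 confidence_direction = confidence_direction,
                 strict_logs = strict_logs),
            class = "walkmem_config")
}

#' Trajectory features for every participant of a cohort
#'
#' Computes visits and distance matrices for every participant whose two
#' logs are present and valid; participants with a missing or corrupt log
#' are excluded with a reason.
#'
#' @param cohort a `walkmem_cohort`.
#' @param config an [analysis_config()].
#' @return list: `usable` (ids), `excluded` (named reasons), `visits`,
#'   `distances` (nested by participant then room).
#' @export
cohort_features <- function(cohort, config = analysis_config()) {
  pids <- cohort$participants$participant_id
  visits <- list(); distances <- list()
  excluded <- list()
  for (pid in pids) {
    ok <- TRUE; reason <- NULL
    vr <- list(); dr <- list()
    for (rm in c("light", "dark")) {
      log <- cohort$logs[[pid]][[rm]]
      if (is.null(log)) { ok <- FALSE; reason <- "missing log"; break }
      val <- tryCatch({ validate_tracklog(log); TRUE },
                      walkmem_corrupt_log = function(e) FALSE)
      if (!val) { ok <- FALSE; reason <- "corrupt log"; break }
      v <- segment_visits(log, cohort$layouts[[rm]],
                          gap_tol_s = config$gap_tol_s,
                          ang_thresh_deg = config$ang_thresh_deg,
                          max_dist_m = config$max_dist_m,
                          central_time_mode = config$central_time_mode)
      vr[[rm]] <- v
      dr[[rm]] <- travelled_distances(log, v[order(v$central_t), ])
    }
    if (ok) {
      visits[[pid]] <- vr; distances[[pid]] <- dr
    } else {
      excluded[[pid]] <- reason
    }
  }
  list(usable = names(visits), excluded = excluded,
       visits = visits, distances = distances)
}

#' Analyse a cohort end to end (in memory)
#'
#' Runs the full pipeline on a [generate_cohort()] bundle (or any object
#' with the same structure): trajectory features and exclusions, sequential
#' pair labelling and outcomes, participant statistics and group contrasts,
#' and the spatial and temporal d-MPFs with their permutation tests.
#' Participants with missing or corrupt logs are excluded from the
#' trajectory-based analyses only; recognition statistics use everyone.
#'
#' @param cohort a `walkmem_cohort`.
#' @param config an [analysis_config()].
#' @param seed seed for the permutation tests.
#' @param scope `"full"`, or `"dmpf"` to compute only the trajectory
#'   features, pair outcomes and d-MPF permutation tests (used by
#'   simulation studies that do not need the recognition battery).
#' @return a list: `features`, `pairs`, `stats`, `contrasts`,
#'   `dmpf_spatial`, `dmpf_temporal`, `perm_spatial`, `perm_temporal`,
#'   `room_summaries`, `dist_correlation`, `excluded`.
#' @export
analyze_cohort <- function(cohort, config = analysis_config(), seed = 1,
                           scope = c("full", "dmpf")) {
  scope <- match.arg(scope)
  feats <- cohort_features(cohort, config)
  pairs <- label_pairs_by_participant(cohort$trials)
  pairs <- pair_outcomes(pairs, cohort$responses, feats$distances)
  stats <- contrasts <- NULL
  if (scope == "full") {
    stats <- participant_stats(cohort$responses, pairs,
                               min_pairs = config$min_pairs)
    contrasts <- group_contrasts(stats, r_scale = config$r_scale)
  }
  elig <- eligible_pairs(pairs)
  dmpf_sp <- dmpf_tm <- perm_sp <- perm_tm <- NULL
  if (nrow(elig) > 0) {
    dmpf_sp <- compute_dmpf(elig, "spatial", n_bins = config$n_bins)
    dmpf_tm <- compute_dmpf(elig, "temporal", n_bins = config$n_bins)
    perm_sp <- tryCatch(
      perm_ttest(dmpf_sp, config$contrast_mode, n_perm = config$n_perm,
                 seed = derive_seed(seed, "perm_spatial")),
      walkmem_config_error = function(e) NULL)
    perm_tm <- tryCatch(
      perm_ttest(dmpf_tm, config$contrast_mode, n_perm = config$n_perm,
                 seed = derive_seed(seed, "perm_temporal")),
      walkmem_config_error = function(e) NULL)
  }
  summaries <- if (scope == "full")
    bind_rows(lapply(feats$usable, function(pid)
      room_summaries(cohort$logs[[pid]], feats$visits[[pid]]))) else NULL
  dist_cor <- if (nrow(elig) > 1 && stats::sd(elig$spatial_m) > 0)
    cor(elig$spatial_m, elig$temporal_s) else NA_real_
  list(features = feats, pairs = pairs, stats = stats, contrasts = contrasts,
       dmpf_spatial = dmpf_sp, dmpf_temporal = dmpf_tm,
       perm_spatial = perm_sp, perm_temporal = perm_tm,
       room_summaries = summaries, dist_correlation = dist_cor,
       excluded = feats$excluded)
}

# label_pairs() per participant over a combined trials table.
label_pairs_by_participant <- function(trials) {
  bind_rows(lapply(split(trials, trials$participant_id), function(tr) {
    mutate(label_pairs(tr[order(tr$probe_index), ]),
           participant_id = tr$participant_id[1], .before = 1)
  }))
}

distances_to_long <- function(distances) {
  rows <- list()
  for (pid in names(distances)) for (rm in names(distances[[pid]])) {
    d <- distances[[pid]][[rm]]
    n <- nrow(d$spatial)
    idx <- which(upper.tri(d$spatial), arr.ind = TRUE)
    rows[[paste(pid, rm)]] <- tibble(
      participant_id = pid, room_id = rm,
      item_i = rownames(d$spatial)[idx[, 1]],
      item_j = colnames(d$spatial)[idx[, 2]],
      spatial_m = d$spatial[idx], temporal_s = d$temporal[idx],
      flagged = d$flagged[idx[, 1]] | d$flagged[idx[, 2]]
    )
  }
  bind_rows(rows)
}

pipeline_paths <- function(outdir) {
  list(logs = file.path(outdir, "logs"),
       trials = file.path(outdir, "trials.csv"),
       responses = file.path(outdir, "responses.csv"),
       truth = file.path(outdir, "truth.json"),
       config = file.path(outdir, "config.json"),
       visits = file.path(outdir, "visits.csv"),
       distances = file.path(outdir, "distances.csv"),
       summaries = file.path(outdir, "room_summaries.csv"),
       exclusions = file.path(outdir, "exclusions.json"),
       stats = file.path(outdir, "participant_stats.csv"),
       contrasts = file.path(outdir, "group_contrasts.csv"),
       dmpf = file.path(outdir, "dmpf.csv"),
       perm = file.path(outdir, "dmpf_permutation.json"),
       plot = file.path(outdir, "dmpf_spatial.png"),
       report = file.path(outdir, "report.txt"))
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    abort(sprintf("missing pipeline artifact '%s'; run %s first.",
                  path, produced_by),
          class = "walkmem_pipeline_error")
  path
}

write_config_json <- function(cohort_params, config, seed, outdir) {
  jsonlite::write_json(
    list(params = unclass(cohort_params), analysis = unclass(config),
         seed = seed),
    file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

#' Pipeline command: simulate a cohort to disk
#'
#' Writes trajectory logs (`logs/<participant>_<room>.csv`; dropped logs are
#' not written, corrupted ones are written as-is), `trials.csv`,
#' `responses.csv`, a `truth.json` sidecar with the injected effects, and
#' the resolved `config.json`.
#'
#' @param params a [cohort_params()].
#' @param config an [analysis_config()] (recorded alongside).
#' @param outdir output directory (created if needed).
#' @return the cohort, invisibly.
#' @export
pipeline_simulate <- function(params = cohort_params(),
                              config = analysis_config(), outdir) {
  dir.create(file.path(outdir, "logs"), recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(outdir)
  cohort <- generate_cohort(params)
  for (pid in names(cohort$logs)) for (rm in names(cohort$logs[[pid]])) {
    log <- cohort$logs[[pid]][[rm]]
    if (is.null(log)) next
    out <- data.frame(t_s = sprintf("%.3f", log$t_s),
                      x_m = sprintf("%.3f", log$x_m),
                      y_m = sprintf("%.3f", log$y_m),
                      heading_deg = sprintf("%.3f", log$heading_deg))
    utils::write.csv(out, file.path(paths$logs, paste0(pid, "_", rm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  readr::write_csv(cohort$trials, paths$trials)
  readr::write_csv(cohort$responses, paths$responses)
  jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config_json(params, config, params$seed, outdir)
  invisible(cohort)
}

read_cohort_from_disk <- function(outdir, params, config) {
  paths <- pipeline_paths(outdir)
  require_artifact(paths$trials, "pipeline_simulate()")
  layouts <- list(
    light = make_room_layout("light", "open_rect",
                             seed = derive_seed(params$seed, "layout_light"),
                             extent = params$extent),
    dark = make_room_layout("dark", "s_shape",
                            seed = derive_seed(params$seed, "layout_dark"),
                            extent = params$extent)
  )
  trials <- readr::read_csv(paths$trials, show_col_types = FALSE)
  responses <- readr::read_csv(paths$responses, show_col_types = FALSE)
  pids <- unique(trials$participant_id)
  logs <- stats::setNames(lapply(pids, function(pid) {
    out <- list()
    for (rm in c("light", "dark")) {
      f <- file.path(paths$logs, paste0(pid, "_", rm, ".csv"))
      out[[rm]] <- if (!file.exists(f)) NULL else
        tryCatch(read_tracklog(f, strict = config$strict_logs),
                 walkmem_corrupt_log = function(e) {
                   bad <- tracklog(c(0, 1), c(0, 0), c(0, 0), c(0, 0),
                                   validate = FALSE)
                   attr(bad, "unreadable") <- TRUE
                   bad
                 })
    }
    out
  }), pids)
  list(params = params, layouts = layouts,
       participants = tibble(participant_id = pids),
       logs = logs, trials = trials, responses = responses)
}

#' Pipeline command: trajectory features to disk
#'
#' Reads the simulated logs back from `outdir`, segments visits, computes
#' distance matrices and room summaries, and records exclusions (missing or
#' corrupt logs) with reasons.
#'
#' @inheritParams pipeline_simulate
#' @export
pipeline_features <- function(params = cohort_params(),
                              config = analysis_config(), outdir) {
  paths <- pipeline_paths(outdir)
  cohort <- read_cohort_from_disk(outdir, params, config)
  feats <- cohort_features(cohort, config)
  write_config_json(params, config, params$seed, outdir)
  all_visits <- bind_rows(lapply(names(feats$visits), function(pid)
    bind_rows(lapply(names(feats$visits[[pid]]), function(rm)
      mutate(feats$visits[[pid]][[rm]], participant_id = pid, room_id = rm,
             .before = 1)))))
  readr::write_csv(all_visits, paths$visits)
  readr::write_csv(distances_to_long(feats$distances), paths$distances)
  summaries <- bind_rows(lapply(feats$usable, function(pid)
    room_summaries(cohort$logs[[pid]], feats$visits[[pid]])))
  readr::write_csv(summaries, paths$summaries)
  jsonlite::write_json(list(usable = feats$usable, excluded = feats$excluded),
                       paths$exclusions, auto_unbox = TRUE, pretty = TRUE)
  invisible(feats)
}

#' Pipeline command: recognition statistics to disk
#'
#' @inheritParams pipeline_simulate
#' @export
pipeline_analyze <- function(params = cohort_params(),
                             config = analysis_config(), outdir) {
  paths <- pipeline_paths(outdir)
  require_artifact(paths$responses, "pipeline_simulate()")
  write_config_json(params, config, params$seed, outdir)
  trials <- readr::read_csv(paths$trials, show_col_types = FALSE)
  responses <- readr::read_csv(paths$responses, show_col_types = FALSE)
  pairs <- label_pairs_by_participant(trials)
  pairs <- pair_outcomes(pairs, responses)
  stats <- participant_stats(responses, pairs, min_pairs = config$min_pairs)
  contrasts <- group_contrasts(stats, r_scale = config$r_scale)
  readr::write_csv(stats, paths$stats)
  readr::write_csv(contrasts, paths$contrasts)
  invisible(list(stats = stats, contrasts = contrasts))
}

#' Pipeline command: d-MPFs and permutation tests to disk
#'
#' Requires the feature artifacts; writes the participant x bin d-MPF
#' table, the permutation results as JSON, and a spatial d-MPF bar plot
#' (plot written best-effort; skipped if no graphics device is available).
#'
#' @inheritParams pipeline_simulate
#' @param seed permutation seed.
#' @export
pipeline_dmpf <- function(params = cohort_params(),
                          config = analysis_config(), outdir, seed = 1) {
  paths <- pipeline_paths(outdir)
  require_artifact(paths$distances, "pipeline_features()")
  write_config_json(params, config, params$seed, outdir)
  trials <- readr::read_csv(paths$trials, show_col_types = FALSE)
  responses <- readr::read_csv(paths$responses, show_col_types = FALSE)
  dist_long <- readr::read_csv(paths$distances, show_col_types = FALSE)
  pairs <- label_pairs_by_participant(trials)
  pairs <- pair_outcomes(pairs, responses)
  key <- paste(dist_long$participant_id, dist_long$room_id,
               pmin(dist_long$item_i, dist_long$item_j),
               pmax(dist_long$item_i, dist_long$item_j))
  pk <- paste(pairs$participant_id, pairs$first_room,
              pmin(pairs$first_item, pairs$second_item),
              pmax(pairs$first_item, pairs$second_item))
  m <- match(pk, key)
  pairs$spatial_m <- dist_long$spatial_m[m]
  pairs$temporal_s <- dist_long$temporal_s[m]
  pairs$dist_flagged <- dist_long$flagged[m]
  elig <- eligible_pairs(pairs)
  res <- list()
  dmpf_tabs <- list()
  for (metric in c("spatial", "temporal")) {
    dm <- compute_dmpf(elig, metric, n_bins = config$n_bins)
    pt <- perm_ttest(dm, config$contrast_mode, n_perm = config$n_perm,
                     seed = derive_seed(seed, paste0("perm_", metric)))
    dmpf_tabs[[metric]] <- mutate(as_tibble(dm), metric = metric, .before = 1)
    res[[metric]] <- list(T_obs = pt$T_obs, df = pt$df, p_perm = pt$p_perm,
                          cohen_d = pt$cohen_d, n_perm = pt$n_perm,
                          n_complete = pt$n_complete,
                          contrast_mode = pt$contrast_mode,
                          bin_edges = attr(dm, "bin_edges"))
    if (metric == "spatial") {
      ok <- tryCatch({
        grDevices::png(paths$plot, width = 800, height = 600)
        print(plot_dmpf(dm))
        grDevices::dev.off()
        TRUE
      }, error = function(e) FALSE)
      if (!ok) warn("could not render the d-MPF plot (no graphics device?)")
    }
  }
  readr::write_csv(bind_rows(dmpf_tabs), paths$dmpf)
  jsonlite::write_json(res, paths$perm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(res)
}

#' Pipeline command: human-readable report
#'
#' Collates the group contrasts, d-MPF permutation results, room summaries
#' and exclusions into a single plain-text report.
#'
#' @inheritParams pipeline_simulate
#' @export
pipeline_report <- function(params = cohort_params(),
                            config = analysis_config(), outdir) {
  paths <- pipeline_paths(outdir)
  require_artifact(paths$contrasts, "pipeline_analyze()")
  require_artifact(paths$perm, "pipeline_dmpf()")
  contrasts <- readr::read_csv(paths$contrasts, show_col_types = FALSE)
  perm <- jsonlite::read_json(paths$perm, simplifyVector = TRUE)
  excl <- jsonlite::read_json(paths$exclusions, simplifyVector = TRUE)
  lines <- c(
    "walkmem pipeline report",
    strrep("=", 60),
    "",
    sprintf("Trajectory exclusions: %d (%s)", length(excl$excluded),
            if (length(excl$excluded) == 0) "none" else
              paste(names(excl$excluded), unlist(excl$excluded),
                    sep = ": ", collapse = "; ")),
    "",
    "Group contrasts (paired/one-sample t):",
    sprintf("  %-30s n=%2d t=%7.3f df=%2d p=%7.4g d=%6.2f BF01=%s",
            contrasts$statistic, contrasts$n, contrasts$t, contrasts$df,
            contrasts$p, contrasts$cohen_d,
            ifelse(is.na(contrasts$bf01), "-", sprintf("%.2f", contrasts$bf01))),
    "",
    "d-MPF permutation tests (sign-flip, within participant):",
    vapply(names(perm), function(m) sprintf(
      "  %-8s T[%d] = %.2f, p_perm = %.4g, d = %.2f (n = %d, %s, %d permutations)",
      m, perm[[m]]$df, perm[[m]]$T_obs, perm[[m]]$p_perm, perm[[m]]$cohen_d,
      perm[[m]]$n_complete, perm[[m]]$contrast_mode, perm[[m]]$n_perm),
      character(1)),
    ""
  )
  writeLines(lines, paths$report)
  invisible(paths$report)
}
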