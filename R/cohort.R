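# Synthetic cohort generator: a generative twin of the analyses. Recognition
# responses are drawn trial by trial from a base-rate model with injectable
# spatial-boundary (beta_room), ordinal-proximity (beta_lag) and travelled-
# distance (beta_dist) effects, so the downstream pipeline can be validated
# against known ground truth.

#' Generative parameters for a synthetic cohort
#'
#' Defaults emulate the study conditions this pipeline targets: 30
#' participants, hit rate ~.62, lure false-alarm rate .20, new-item false
#' alarms .05, a +.07 conditional-hit-rate boost when the preceding probe
#' was a correctly recognised same-room item, a further +.13 when that item
#' was also encoded within ordinal lag 3, a -0.03 per meter travelled-
#' distance slope (applied to the distance centred on the room's mean pair
#' distance, so the slope and the boundary boost stay separately
#' recoverable), source accuracy .78, ~20 s dwells and a 0.11 m/s walking
#' pace on a 4 x 6 m floor (room time ~ 290 s). Per-trial hit probabilities
#' are clipped to `[0.01, 0.99]`.
#'
#' @param n_participants cohort size.
#' @param base_hit baseline P("old" | old probe).
#' @param base_far_lure,base_far_new P("old") for lure / new probes.
#' @param beta_room,beta_lag additive hit-probability boosts (see above).
#' @param beta_dist hit-probability slope per meter of travelled spatial
#'   distance between the pair's paintings (negative = memory fades with
#'   distance).
#' @param source_acc P(correct room attribution | hit).
#' @param walk_speed_mean,walk_speed_sd walking speed (m/s).
#' @param dwell_mean,dwell_sd per-painting dwell (s).
#' @param heading_noise_sd yaw noise (degrees).
#' @param n_drop participants whose trajectory logs go missing.
#' @param n_corrupt participants with one timestamp-scrambled log file.
#' @param extent room floor `c(width, depth)` in meters.
#' @param seed master seed; every stream below it is derived
#'   deterministically.
#' @return a validated parameter list of class `walkmem_params`.
#' @export
cohort_params <- function(n_participants = 30,
                          base_hit = 0.62, base_far_lure = 0.20,
                          base_far_new = 0.05,
                          beta_room = 0.07, beta_lag = 0.13,
                          beta_dist = -0.03, source_acc = 0.78,
                          walk_speed_mean = 0.11, walk_speed_sd = 0.02,
                          dwell_mean = 20, dwell_sd = 3,
                          heading_noise_sd = 5,
                          n_drop = 0, n_corrupt = 0,
                          extent = c(4, 6), seed = 1) {
  p <- list(n_participants = as.integer(n_participants),
            base_hit = base_hit, base_far_lure = base_far_lure,
            base_far_new = base_far_new, beta_room = beta_room,
            beta_lag = beta_lag, beta_dist = beta_dist,
            source_acc = source_acc,
            walk_speed_mean = walk_speed_mean, walk_speed_sd = walk_speed_sd,
            dwell_mean = dwell_mean, dwell_sd = dwell_sd,
            heading_noise_sd = heading_noise_sd,
            n_drop = as.integer(n_drop), n_corrupt = as.integer(n_corrupt),
            extent = extent, seed = as.integer(seed))
  for (nm in c("base_hit", "base_far_lure", "base_far_new", "source_acc"))
    if (!is_scalar_prob(p[[nm]]))
      abort(paste0(nm, " must be a probability in [0, 1]."),
            class = "walkmem_config_error")
  if (p$n_participants < 1)
    abort("n_participants must be >= 1.", class = "walkmem_config_error")
  if (p$walk_speed_mean <= 0 || p$dwell_mean <= 0)
    abort("walk speed and dwell means must be positive.",
          class = "walkmem_config_error")
  if (p$n_drop + p$n_corrupt > p$n_participants)
    abort("cannot drop/corrupt more participants than exist.",
          class = "walkmem_config_error")
  structure(p, class = "walkmem_params")
}

#' Generate recognition responses from the generative memory model
#'
#' Walks the trial sequence in probe order. Old probes are answered "old"
#' with probability `base_hit`, plus `beta_room` when the directly preceding
#' probe was a distinct same-room old item that was itself answered "old",
#' plus `beta_lag` when that preceding item was additionally within ordinal
#' lag 3, plus `beta_dist` times the travelled spatial distance between the
#' two paintings centred on the room's mean pairwise distance (centring
#' keeps the average same-room boost equal to `beta_room`, so the slope and
#' the boundary effect stay separately recoverable). Lure and new probes
#' use their base false-alarm rates.
#' Probabilities are clipped to `[0.01, 0.99]`. Every "old" answer receives
#' a source-room attribution (correct with probability `source_acc`; a fair
#' coin for new items) and a 4-level confidence rating drawn as
#' `1 + Binomial(3, 1 - p_trial)`, so confidence shifts toward 1 = "Sure" as
#' the trial's hit probability rises.
#'
#' @param trials a trial sequence for one participant.
#' @param distances named list (by room id) of [travelled_distances()]
#'   results for that participant; a missing same-room pair distance is an
#'   error.
#' @param params a [cohort_params()] list.
#' @param seed integer seed.
#' @return the trials tibble plus `old_response` ("yes"/"no"),
#'   `source_response`, `confidence` and the generative `p_true`.
#' @export
generate_responses <- function(trials, distances, params, seed = 1) {
  n <- nrow(trials)
  status <- trials$status; item <- trials$item_id; room <- trials$source_room
  pos <- trials$encoding_pos
  old_resp <- character(n); src <- rep(NA_character_, n)
  conf <- rep(NA_integer_, n); p_true <- numeric(n)
  rooms <- unique(room[status == "old"])
  dbar <- vapply(rooms, function(rm) {
    d <- distances[[rm]]
    if (is.null(d))
      abort(paste0("no distance matrix for room ", rm),
            class = "walkmem_config_error")
    mean(d$spatial[upper.tri(d$spatial)])
  }, numeric(1))
  with_seed(seed, {
    for (i in seq_len(n)) {
      base <- switch(status[i], old = params$base_hit,
                     lure = params$base_far_lure, new = params$base_far_new)
      p <- base
      if (status[i] == "old" && i > 1 && status[i - 1] == "old" &&
          item[i - 1] != item[i] && old_resp[i - 1] == "yes" &&
          identical(room[i - 1], room[i])) {
        p <- p + params$beta_room
        lag <- pos[i] - pos[i - 1]
        if (abs(lag) <= 3) p <- p + params$beta_lag
        d <- distances[[room[i]]]
        p <- p + params$beta_dist *
          (distance_between(d, item[i - 1], item[i], "spatial") - dbar[[room[i]]])
      }
      # clip boost-adjusted probabilities to keep the model proper under
      # large betas, without overriding intentionally degenerate base rates
      p <- clip_prob(p, lo = min(0.01, base), hi = max(0.99, base))
      p_true[i] <- p
      yes <- runif(1) < p
      old_resp[i] <- if (yes) "yes" else "no"
      if (yes) {
        true_room <- room[i]
        src[i] <- if (is.na(true_room)) {
          sample(rooms, 1)
        } else if (runif(1) < params$source_acc) {
          true_room
        } else {
          setdiff(rooms, true_room)[1]
        }
        conf[i] <- 1L + rbinom(1, 3, 1 - p)
      }
    }
  })
  out <- trials
  out$old_response <- old_resp
  out$source_response <- src
  out$confidence <- conf
  out$p_true <- p_true
  out
}

#' Generate a complete synthetic cohort
#'
#' Builds the two room layouts (an open rectangular "light" room and an
#' S-shaped "dark" room), and for each participant: a randomized room order,
#' one simulated 10 Hz walk per room, the 77-trial recognition sequence with
#' sequential-pair reordering, and model-generated responses whose
#' distance effects use the participant's own travelled-distance matrices.
#' Optionally `n_drop` participants lose their trajectory logs and
#' `n_corrupt` further participants get one timestamp-scrambled log,
#' mirroring real data loss; recognition responses are unaffected.
#'
#' @param params a [cohort_params()] list (its `seed` drives every stream).
#' @return a `walkmem_cohort` list: `params`, `layouts`, `participants`
#'   (tibble with room order and log-fate flags), `logs` (nested list,
#'   participant -> room -> tracklog or NULL), `trials`, `responses`
#'   (tibbles over all participants) and `truth` (the injected parameters).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "walkmem_params"))
  seed <- params$seed
  layouts <- list(
    light = make_room_layout("light", "open_rect",
                             seed = derive_seed(seed, "layout_light"),
                             extent = params$extent),
    dark = make_room_layout("dark", "s_shape",
                            seed = derive_seed(seed, "layout_dark"),
                            extent = params$extent)
  )
  n <- params$n_participants
  pids <- sprintf("P%03d", seq_len(n))
  first_room <- with_seed(derive_seed(seed, "room_order"),
                          ifelse(runif(n) < 0.5, "light", "dark"))
  fate <- with_seed(derive_seed(seed, "log_fate"), {
    aff <- sample(pids, params$n_drop + params$n_corrupt)
    list(drop = aff[seq_len(params$n_drop)],
         corrupt = setdiff(aff, aff[seq_len(params$n_drop)]))
  })
  logs <- stats::setNames(vector("list", n), pids)
  trials_all <- vector("list", n)
  responses_all <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- pids[i]
    logs[[pid]] <- list()
    dists <- list()
    for (rm in c("light", "dark")) {
      walk <- simulate_walk(layouts[[rm]], params,
                            seed = derive_seed(seed, paste0("walk_", pid, "_", rm)),
                            participant_id = pid)
      visits <- segment_visits(walk, layouts[[rm]])
      dists[[rm]] <- travelled_distances(walk, visits[order(visits$central_t), ])
      logs[[pid]][[rm]] <- walk
    }
    items <- trial_items(layouts, first_room[i])
    trials <- build_trials(items, seed = derive_seed(seed, paste0("trials_", pid)))
    trials <- reorder_for_pairs(trials,
                                seed = derive_seed(seed, paste0("reorder_", pid)))
    resp <- generate_responses(trials, dists, params,
                               seed = derive_seed(seed, paste0("resp_", pid)))
    trials$participant_id <- pid
    resp$participant_id <- pid
    trials_all[[i]] <- trials[c("participant_id", setdiff(names(trials), "participant_id"))]
    responses_all[[i]] <- resp[c("participant_id", setdiff(names(resp), "participant_id"))]
    if (pid %in% fate$drop) logs[[pid]] <- list(light = NULL, dark = NULL)
    if (pid %in% fate$corrupt) {
      rm_bad <- with_seed(derive_seed(seed, paste0("corrupt_", pid)),
                          sample(c("light", "dark"), 1))
      bad <- logs[[pid]][[rm_bad]]
      perm <- with_seed(derive_seed(seed, paste0("corruptperm_", pid)),
                        sample.int(nrow(bad)))
      bad$t_s <- bad$t_s[perm]
      logs[[pid]][[rm_bad]] <- structure(bad, corrupted = TRUE)
    }
  }
  structure(
    list(params = params, layouts = layouts,
         participants = tibble(participant_id = pids, first_room = first_room,
                               logs_dropped = pids %in% fate$drop,
                               log_corrupted = pids %in% fate$corrupt),
         logs = logs,
         trials = bind_rows(trials_all),
         responses = bind_rows(responses_all),
         truth = list(beta_room = params$beta_room, beta_lag = params$beta_lag,
                      beta_dist = params$beta_dist, params = unclass(params))),
    class = "walkmem_cohort"
  )
}

#' @export
print.walkmem_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic cohort: %d participants, %d trials each, %d dropped / %d corrupted logs, seed %d>\n",
    x$params$n_participants, 77, x$params$n_drop, x$params$n_corrupt,
    x$params$seed))
  invisible(x)
}
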