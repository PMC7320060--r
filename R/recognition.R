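# Conventional recognition-memory statistics: conditional hit rates by room
# relation and ordinal lag, source attribution, per-room signal detection
# (HR, FAR, d'), confidence summaries, and the group-level paired contrasts.

PAIR_CONDITIONS <- c("same", "across", "close", "remote",
                     "close_fwd", "remote_fwd", "close_bwd", "remote_bwd")

pair_condition_mask <- function(pairs, condition) {
  switch(condition,
    same   = pairs$room_relation == "same",
    across = pairs$room_relation == "across",
    close  = pairs$room_relation == "same" & pairs$proximity == "close",
    remote = pairs$room_relation == "same" & pairs$proximity == "remote",
    close_fwd  = pairs$room_relation == "same" & pairs$proximity == "close" &
      pairs$direction == "forward",
    remote_fwd = pairs$room_relation == "same" & pairs$proximity == "remote" &
      pairs$direction == "forward",
    close_bwd  = pairs$room_relation == "same" & pairs$proximity == "close" &
      pairs$direction == "backward",
    remote_bwd = pairs$room_relation == "same" & pairs$proximity == "remote" &
      pairs$direction == "backward",
    abort(paste0("unknown pair condition: ", condition),
          class = "walkmem_config_error")
  )
}

#' Join sequential pairs with recognition outcomes (and distances)
#'
#' Adds to each labelled pair whether its first probe was a hit
#' (`first_is_hit`), whether the second probe was answered "old"
#' (`second_hit`), the second probe's confidence, and — for same-room pairs
#' of participants with usable trajectory data — the travelled spatial and
#' temporal distances between the two paintings with their flag.
#'
#' @param pairs a [label_pairs()] table with a `participant_id` column.
#' @param responses the response table (participant_id, probe_index,
#'   old_response, confidence, ...).
#' @param distances optional nested list `distances[[participant]][[room]]`
#'   of [travelled_distances()] objects.
#' @return the pairs tibble with outcome (and distance) columns.
#' @export
pair_outcomes <- function(pairs, responses, distances = NULL) {
  key <- paste(responses$participant_id, responses$probe_index)
  i1 <- match(paste(pairs$participant_id, pairs$first_probe), key)
  i2 <- match(paste(pairs$participant_id, pairs$second_probe), key)
  assert_that(!anyNA(i1) && !anyNA(i2),
              "every pair probe must have a response row.")
  out <- mutate(pairs,
                first_is_hit = responses$old_response[i1] == "yes",
                second_hit = responses$old_response[i2] == "yes",
                second_confidence = responses$confidence[i2])
  out$spatial_m <- NA_real_
  out$temporal_s <- NA_real_
  out$dist_flagged <- NA
  if (!is.null(distances)) {
    same <- which(out$room_relation == "same")
    for (r in same) {
      d <- distances[[out$participant_id[r]]][[out$first_room[r]]]
      if (is.null(d)) next
      out$spatial_m[r] <- distance_between(d, out$first_item[r], out$second_item[r], "spatial")
      out$temporal_s[r] <- distance_between(d, out$first_item[r], out$second_item[r], "temporal")
      out$dist_flagged[r] <- d$flagged[[out$first_item[r]]] || d$flagged[[out$second_item[r]]]
    }
  }
  out
}

#' Conditional hit rate of the second pair member
#'
#' Among pairs in `condition` whose first probe was correctly recognised,
#' the proportion whose second probe was also answered "old" — computed per
#' participant. Participants with fewer than `min_pairs` qualifying pairs
#' are returned with `hr = NA` (ineligible).
#'
#' @param pairs a [pair_outcomes()] table.
#' @param condition one of `same, across, close, remote, close_fwd,
#'   remote_fwd, close_bwd, remote_bwd`.
#' @param min_pairs eligibility threshold on the denominator.
#' @return tibble: `participant_id, condition, n_pairs, hr`.
#' @export
conditional_hr <- function(pairs, condition, min_pairs = 1) {
  mask <- pair_condition_mask(pairs, condition) & pairs$first_is_hit
  mask[is.na(mask)] <- FALSE
  pids <- unique(pairs$participant_id)
  hits <- lapply(pids, function(p) pairs$second_hit[mask & pairs$participant_id == p])
  tibble(
    participant_id = pids, condition = condition,
    n_pairs = vapply(hits, length, integer(1)),
    hr = vapply(hits, function(h) if (length(h) >= min_pairs) mean(h) else NA_real_,
                numeric(1))
  )
}

#' Per-room hit rate, false-alarm rate and d'
#'
#' HR is computed over a room's old probes (trial level, repeats included);
#' FAR over that room's lure probes only (new items belong to neither room).
#' Extreme rates are adjusted by the 1/(2N) rule before the z transform so
#' d' stays finite.
#'
#' @param responses response table for one or more participants.
#' @return tibble per participant x room: `n_old, hr, hr_adj, n_lure, far,
#'   far_adj, dprime`.
#' @export
sdt_per_room <- function(responses) {
  adj <- function(rate, n) ifelse(rate >= 1, 1 - 1 / (2 * n),
                                  ifelse(rate <= 0, 1 / (2 * n), rate))
  dat <- filter(responses, .data$status %in% c("old", "lure"))
  res <- summarise(
    group_by(dat, .data$participant_id, room_id = .data$source_room),
    n_old = sum(.data$status == "old"),
    hr = mean(.data$old_response[.data$status == "old"] == "yes"),
    n_lure = sum(.data$status == "lure"),
    far = mean(.data$old_response[.data$status == "lure"] == "yes"),
    .groups = "drop"
  )
  mutate(res,
         hr_adj = adj(.data$hr, .data$n_old),
         far_adj = adj(.data$far, .data$n_lure),
         dprime = qnorm(.data$hr_adj) - qnorm(.data$far_adj))
}

#' Source attribution accuracy
#'
#' Proportion of hits whose source-room response matches the encoding room,
#' per participant and room, with group one-sample t-tests against the
#' 2-room chance level of .5.
#'
#' @param responses response table.
#' @param chance chance proportion (default .5).
#' @return list: `per_participant` (tibble with `n_hits, source_hr`; NA and
#'   flagged when a participant has no hit in a room) and `tests` (one
#'   [one_sample_t()] row per room).
#' @export
source_attribution <- function(responses, chance = 0.5) {
  hits <- filter(responses, .data$status == "old", .data$old_response == "yes")
  grid <- tidyr::expand_grid(
    participant_id = unique(responses$participant_id),
    room_id = sort(unique(responses$source_room[responses$status == "old"]))
  )
  per <- summarise(group_by(hits, .data$participant_id, room_id = .data$source_room),
                   n_hits = dplyr::n(),
                   source_hr = mean(.data$source_response == .data$room_id),
                   .groups = "drop")
  per <- left_join(grid, per, by = c("participant_id", "room_id"))
  per$n_hits[is.na(per$n_hits)] <- 0L
  per$flagged <- per$n_hits == 0
  tests <- bind_rows(lapply(split(per, per$room_id), function(d) {
    x <- d$source_hr[!is.na(d$source_hr)]
    if (length(x) < 2) return(NULL)
    one_sample_t(x, mu = chance, name = paste0("source_", d$room_id[1], "_vs_chance"))
  }))
  list(per_participant = per, tests = tests)
}

#' Mean confidence per condition
#'
#' Confidence is coded 1 = "Sure" ... 4 = "Completely unsure" (so lower
#' means more confident; set `direction = "sure_high"` to flip). Close and
#' remote means are taken over second-probe hits of the respective pair
#' conditions; room means over all hits of that room's old probes.
#' Participants with fewer than `min_hits` contributing hits in a condition
#' get `NA` there.
#'
#' @param responses response table.
#' @param pairs a [pair_outcomes()] table.
#' @param min_hits eligibility threshold.
#' @param direction confidence coding direction.
#' @return tibble per participant: `conf_close, conf_remote, conf_light,
#'   conf_dark`.
#' @export
confidence_summary <- function(responses, pairs, min_hits = 1,
                               direction = c("sure_low", "sure_high")) {
  direction <- match.arg(direction)
  conv <- function(v) if (direction == "sure_low") v else 5 - v
  cond_mean <- function(v) if (length(v) >= min_hits) mean(conv(v)) else NA_real_
  pair_conf <- function(pp, cond) {
    mask <- pair_condition_mask(pp, cond) & pp$first_is_hit & pp$second_hit
    mask[is.na(mask)] <- FALSE
    cond_mean(pp$second_confidence[mask])
  }
  hits <- filter(responses, .data$status == "old", .data$old_response == "yes")
  rows <- lapply(unique(responses$participant_id), function(pid) {
    pp <- pairs[pairs$participant_id == pid, ]
    hh <- hits[hits$participant_id == pid, ]
    tibble(
      participant_id = pid,
      conf_close = pair_conf(pp, "close"),
      conf_remote = pair_conf(pp, "remote"),
      conf_light = cond_mean(hh$confidence[hh$source_room == "light"]),
      conf_dark = cond_mean(hh$confidence[hh$source_room == "dark"])
    )
  })
  bind_rows(rows)
}

#' Per-participant summary statistics
#'
#' One row per participant with all conditional hit rates, source hit
#' rates, per-room HR/FAR/d' and confidence means — the input to
#' [group_contrasts()].
#'
#' @param responses response table.
#' @param pairs a [pair_outcomes()] table.
#' @param min_pairs eligibility threshold for conditional rates.
#' @return a wide tibble, one row per participant.
#' @export
participant_stats <- function(responses, pairs, min_pairs = 1) {
  out <- tibble(participant_id = sort(unique(responses$participant_id)))
  for (cond in PAIR_CONDITIONS) {
    chr <- conditional_hr(pairs, cond, min_pairs)
    out[[paste0("hr_", cond)]] <- chr$hr[match(out$participant_id, chr$participant_id)]
  }
  src <- source_attribution(responses)$per_participant
  for (rm in unique(src$room_id)) {
    sub <- src[src$room_id == rm, ]
    out[[paste0("source_hr_", rm)]] <-
      sub$source_hr[match(out$participant_id, sub$participant_id)]
  }
  sdt <- sdt_per_room(responses)
  for (rm in unique(sdt$room_id)) {
    sub <- sdt[sdt$room_id == rm, ]
    m <- match(out$participant_id, sub$participant_id)
    out[[paste0("hr_", rm)]] <- sub$hr[m]
    out[[paste0("far_", rm)]] <- sub$far[m]
    out[[paste0("dprime_", rm)]] <- sub$dprime[m]
  }
  conf <- confidence_summary(responses, pairs, min_hits = min_pairs)
  m <- match(out$participant_id, conf$participant_id)
  out$conf_close <- conf$conf_close[m]
  out$conf_remote <- conf$conf_remote[m]
  out$conf_light <- conf$conf_light[m]
  out$conf_dark <- conf$conf_dark[m]
  out
}

GROUP_CONTRASTS <- list(
  list(name = "hr_same_vs_across", a = "hr_same", b = "hr_across", tail = "two.sided"),
  list(name = "hr_close_vs_remote", a = "hr_close", b = "hr_remote", tail = "two.sided"),
  list(name = "hr_close_vs_remote_forward", a = "hr_close_fwd", b = "hr_remote_fwd", tail = "greater"),
  list(name = "hr_close_vs_remote_backward", a = "hr_close_bwd", b = "hr_remote_bwd", tail = "greater"),
  list(name = "source_light_vs_chance", a = "source_hr_light", mu = 0.5, tail = "two.sided"),
  list(name = "source_dark_vs_chance", a = "source_hr_dark", mu = 0.5, tail = "two.sided"),
  list(name = "source_light_vs_dark", a = "source_hr_light", b = "source_hr_dark", tail = "two.sided"),
  list(name = "dprime_light_vs_dark", a = "dprime_light", b = "dprime_dark", tail = "two.sided"),
  list(name = "hr_light_vs_dark", a = "hr_light", b = "hr_dark", tail = "two.sided"),
  list(name = "far_light_vs_dark", a = "far_light", b = "far_dark", tail = "two.sided"),
  list(name = "conf_close_vs_remote", a = "conf_close", b = "conf_remote", tail = "two.sided"),
  list(name = "conf_light_vs_dark", a = "conf_light", b = "conf_dark", tail = "two.sided")
)

#' Group-level contrasts over participant statistics
#'
#' Runs the standard battery of paired (and chance-level one-sample)
#' t-tests over a [participant_stats()] table, with listwise deletion per
#' contrast, Cohen's d (`mean(diff)/sd(diff)`) and the JZS BF01 alongside
#' each test. Contrasts with fewer than 2 complete participants are skipped
#' with a warning.
#'
#' @param stats a [participant_stats()] tibble.
#' @param r_scale Cauchy prior scale for the Bayes factors.
#' @return a tibble of [new_stat_result()] rows.
#' @export
group_contrasts <- function(stats, r_scale = sqrt(2) / 2) {
  rows <- lapply(GROUP_CONTRASTS, function(ct) {
    if (!ct$a %in% names(stats) || (!is.null(ct$b) && !ct$b %in% names(stats)))
      return(NULL)
    x <- stats[[ct$a]]
    if (is.null(ct$b)) {
      keep <- !is.na(x)
      if (sum(keep) < 2) {
        warn(paste0("contrast ", ct$name, " skipped: fewer than 2 eligible participants"))
        return(NULL)
      }
      res <- one_sample_t(x[keep], mu = ct$mu, tail = ct$tail, name = ct$name)
    } else {
      y <- stats[[ct$b]]
      keep <- !is.na(x) & !is.na(y)
      if (sum(keep) < 2) {
        warn(paste0("contrast ", ct$name, " skipped: fewer than 2 eligible participants"))
        return(NULL)
      }
      res <- paired_t(x[keep], y[keep], tail = ct$tail, name = ct$name)
    }
    if (is.finite(res$t)) res$bf01 <- jzs_bf01(res$t, res$n, r_scale = r_scale)
    res
  })
  bind_rows(rows)
}
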