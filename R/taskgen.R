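# Recognition task construction: the 77-trial old/new sequence with its
# probe multiplicities, the sequential-pair reordering that enriches the
# shuffled sequence in classifiable consecutive old-old pairs, and the pure
# labelling of those pairs by room relation, ordinal lag and direction.

#' Item table for the recognition task
#'
#' Builds the probe item inventory from two encoded room layouts: 18 old
#' paintings with global encoding positions 1..18 (the first-explored room
#' occupies 1..9), one lure per old painting, and 9 unrelated new items.
#'
#' @param layouts named list of the two room layouts.
#' @param first_room id of the room explored first.
#' @return tibble: `item_id, status, source_room, encoding_pos, lure_of`.
#' @export
trial_items <- function(layouts, first_room) {
  rooms <- names(layouts)
  if (!first_room %in% rooms)
    abort("first_room must name one of the layouts.", class = "walkmem_config_error")
  second <- setdiff(rooms, first_room)
  old <- bind_rows(
    mutate(layouts[[first_room]]$paintings[, c("item_id", "room_id", "ordinal_pos")],
           encoding_pos = .data$ordinal_pos),
    mutate(layouts[[second]]$paintings[, c("item_id", "room_id", "ordinal_pos")],
           encoding_pos = .data$ordinal_pos + 9L)
  )
  bind_rows(
    tibble(item_id = old$item_id, status = "old", source_room = old$room_id,
           encoding_pos = as.integer(old$encoding_pos), lure_of = NA_character_),
    tibble(item_id = paste0("lure_", old$item_id), status = "lure",
           source_room = old$room_id, encoding_pos = NA_integer_,
           lure_of = old$item_id),
    tibble(item_id = sprintf("new_%02d", 1:9), status = "new",
           source_room = NA_character_, encoding_pos = NA_integer_,
           lure_of = NA_character_)
  )
}

#' Build the 77-trial recognition sequence
#'
#' Expands the item inventory to the probe multiset — the four boundary
#' paintings (encoding positions 1, 9, 10 and 18, i.e. the first and last of
#' each room) probed twice each, the other 14 old paintings three times
#' each, every lure and new item once — and shuffles it uniformly. The
#' result has 77 trials: 50 old and 27 lure/new probes.
#'
#' @param items a [trial_items()] table (18 old, 9 per room; 18 lures; 9 new).
#' @param seed shuffle seed.
#' @return tibble with `probe_index` 1..77 plus the item columns.
#' @export
build_trials <- function(items, seed = 1) {
  old <- items[items$status == "old", ]
  lure <- items[items$status == "lure", ]
  new <- items[items$status == "new", ]
  if (nrow(old) != 18 || nrow(lure) != 18 || nrow(new) != 9 ||
      !setequal(old$encoding_pos, 1:18) ||
      any(table(old$source_room) != 9))
    abort("trial_items must contain 18 old items (9 per room, positions 1..18), 18 lures and 9 new items.",
          class = "walkmem_config_error")
  boundary <- old$encoding_pos %in% c(1L, 9L, 10L, 18L)
  reps <- ifelse(boundary, 2L, 3L)
  pool <- bind_rows(old[rep(seq_len(18), reps), ], lure, new)
  shuffled <- with_seed(seed, pool[sample.int(nrow(pool)), ])
  mutate(shuffled, probe_index = row_number(), .before = 1)
}

# Counts of classifiable consecutive pairs in a trial sequence:
#   room pairs  = consecutive old-old probes of distinct items (classifiable
#                 as same- or across-room);
#   prox pairs  = the same-room subset (classifiable as close or remote).
count_sequential_pairs <- function(status, item_id, source_room) {
  n <- length(status)
  a <- seq_len(n - 1)
  oldold <- status[a] == "old" & status[a + 1] == "old" &
    item_id[a] != item_id[a + 1]
  same <- oldold & source_room[a] == source_room[a + 1]
  c(room = sum(oldold), prox = sum(same))
}

#' Reorder trials to enrich sequential pairs
#'
#' Greedy constrained reordering: random transpositions of two trials are
#' accepted whenever they reduce the remaining deficit to the targets —
#' at least `target_prox_pairs` consecutive old-old pairs classifiable by
#' ordinal proximity (same room) and at least `target_room_pairs`
#' classifiable by room relation. The trial multiset is conserved. If the
#' targets are not reached within `max_attempts` proposals, the best
#' sequence found is returned with a warning.
#'
#' @param trials a [build_trials()] sequence.
#' @param target_prox_pairs,target_room_pairs pair-count targets (defaults
#'   14 and 28, the design's average yields).
#' @param seed proposal seed.
#' @param max_attempts proposal budget.
#' @return the reordered trial tibble (attribute `pair_counts` holds the
#'   achieved counts and number of accepted swaps).
#' @export
reorder_for_pairs <- function(trials, target_prox_pairs = 14,
                              target_room_pairs = 28, seed = 1,
                              max_attempts = 10000) {
  if (target_prox_pairs < 0 || target_room_pairs < 0)
    abort("pair targets must be non-negative.", class = "walkmem_config_error")
  status <- trials$status; item <- trials$item_id; room <- trials$source_room
  ord <- seq_len(nrow(trials))
  deficit <- function(cnt) {
    max(0, target_prox_pairs - cnt[["prox"]]) + max(0, target_room_pairs - cnt[["room"]])
  }
  cnt <- count_sequential_pairs(status[ord], item[ord], room[ord])
  n_swaps <- 0L
  if (deficit(cnt) > 0 && max_attempts > 0) {
    with_seed(seed, {
      for (att in seq_len(max_attempts)) {
        ij <- sample.int(length(ord), 2)
        cand <- ord
        cand[ij] <- cand[rev(ij)]
        cnt2 <- count_sequential_pairs(status[cand], item[cand], room[cand])
        if (deficit(cnt2) < deficit(cnt)) {
          ord <- cand; cnt <- cnt2; n_swaps <- n_swaps + 1L
          if (deficit(cnt) == 0) break
        }
      }
    })
    if (deficit(cnt) > 0)
      warn(sprintf(
        "pair targets not reached after %d attempts (prox %d/%d, room %d/%d); returning best effort",
        max_attempts, cnt[["prox"]], target_prox_pairs, cnt[["room"]], target_room_pairs))
  }
  out <- trials[ord, ]
  out$probe_index <- seq_len(nrow(out))
  attr(out, "pair_counts") <- c(cnt, swaps = n_swaps)
  out
}

#' Label consecutive old-old probe pairs
#'
#' Every pair of consecutive trials in which both probes are (distinct) old
#' items yields one sequential pair labelled with its room relation
#' (same/across), signed ordinal lag (same-room pairs; second minus first
#' encoding position), proximity class (close: |lag| <= 3; remote:
#' |lag| >= 4) and direction (forward: lag > 0). Consecutive repeats of the
#' same item are not pairs. A pure function of the trial sequence.
#'
#' @param trials a trial sequence tibble.
#' @return tibble: `first_probe, second_probe, first_item, second_item,
#'   first_pos, second_pos, room_relation, lag, proximity, direction`.
#' @export
label_pairs <- function(trials) {
  n <- nrow(trials)
  a <- seq_len(n - 1)
  keep <- trials$status[a] == "old" & trials$status[a + 1] == "old" &
    trials$item_id[a] != trials$item_id[a + 1]
  a <- a[keep]
  same <- trials$source_room[a] == trials$source_room[a + 1]
  lag <- ifelse(same, trials$encoding_pos[a + 1] - trials$encoding_pos[a], NA_integer_)
  tibble(
    first_probe = trials$probe_index[a],
    second_probe = trials$probe_index[a + 1],
    first_item = trials$item_id[a],
    second_item = trials$item_id[a + 1],
    first_room = trials$source_room[a],
    second_room = trials$source_room[a + 1],
    first_pos = trials$encoding_pos[a],
    second_pos = trials$encoding_pos[a + 1],
    room_relation = ifelse(same, "same", "across"),
    lag = as.integer(lag),
    proximity = ifelse(same, ifelse(abs(lag) <= 3, "close", "remote"), NA_character_),
    direction = ifelse(same, ifelse(lag > 0, "forward", "backward"), NA_character_)
  )
}
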