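# Shared fixtures, built in code.

# A small cached cohort used by several test files (defaults except size).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_params(n_participants = 6, seed = 11))
    cache
  }
})

# A pair of layouts without jitter, for geometric reasoning.
fixed_layouts <- function() {
  list(light = make_room_layout("light", "open_rect", seed = 1, jitter = 0),
       dark = make_room_layout("dark", "s_shape", seed = 1, jitter = 0))
}

# Response-only simulation: draws trials + responses against a fixed set of
# distance matrices, skipping the walking simulation. Used by Monte-Carlo
# tests of the generative response model.
responses_only <- function(n_participants, params, dists, layouts, seed) {
  out <- vector("list", n_participants)
  first <- with_seed_local(seed, ifelse(runif(n_participants) < 0.5, "light", "dark"))
  for (i in seq_len(n_participants)) {
    items <- trial_items(layouts, first[i])
    tr <- build_trials(items, seed = seed + 37 * i)
    r <- generate_responses(tr, dists, params, seed = seed + 91 * i)
    r$participant_id <- sprintf("S%03d", i)
    out[[i]] <- r
  }
  dplyr::bind_rows(out)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Build a pair-outcomes-shaped tibble directly (for d-MPF unit tests).
make_pairs <- function(participant_id, spatial_m, second_hit,
                       temporal_s = spatial_m * 10) {
  tibble::tibble(
    participant_id = participant_id,
    room_relation = "same", first_is_hit = TRUE,
    spatial_m = spatial_m, temporal_s = temporal_s,
    dist_flagged = FALSE, second_hit = second_hit
  )
}
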