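# Conditional hit rates, signal detection, source attribution, confidence,
# and the group contrast battery.

toy_pairs <- function() {
  tibble::tibble(
    participant_id = "P1",
    room_relation = c(rep("same", 5), rep("across", 3)),
    proximity = c("close", "close", "remote", "remote", "close", NA, NA, NA),
    direction = c("forward", "backward", "forward", "backward", "forward", NA, NA, NA),
    lag = c(1L, -2L, 5L, -6L, 3L, NA, NA, NA),
    first_is_hit = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    second_hit = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    second_confidence = c(1L, 2L, 1L, NA, 3L, 1L, NA, 4L)
  )
}

test_that("conditional hit rates are simple filtered proportions", {
  pr <- toy_pairs()
  # 4 eligible same-room pairs (first hit), 3 second-hits -> 0.75
  expect_equal(conditional_hr(pr, "same")$hr, 0.75)
  expect_equal(conditional_hr(pr, "same")$n_pairs, 4L)
  expect_equal(conditional_hr(pr, "across")$hr, 0.5)
  expect_equal(conditional_hr(pr, "close")$hr, 1)
  expect_equal(conditional_hr(pr, "remote")$hr, 0.5)
  expect_equal(conditional_hr(pr, "remote_bwd")$hr, 0)
  expect_error(conditional_hr(pr, "nearby"), class = "walkmem_config_error")
})

test_that("participants below the pair floor are flagged ineligible", {
  pr <- toy_pairs()
  pr$first_is_hit <- FALSE
  expect_true(is.na(conditional_hr(pr, "same")$hr))
  expect_true(is.na(conditional_hr(toy_pairs(), "same", min_pairs = 5)$hr))
})

test_that("d-prime follows the adjusted normal quantiles", {
  resp <- tibble::tibble(
    participant_id = "P1",
    status = c(rep("old", 10), rep("lure", 9)),
    source_room = "light",
    old_response = c(rep("yes", 10), rep("no", 9))
  )
  s <- sdt_per_room(resp)
  expect_equal(s$hr_adj, 0.95)              # 1 - 1/(2*10)
  expect_equal(s$far_adj, 1 / 18)
  expect_equal(s$dprime, qnorm(0.95) - qnorm(1 / 18), tolerance = 1e-12)

  resp2 <- resp
  resp2$old_response <- c(rep("yes", 5), rep("no", 5), rep("yes", 4), rep("no", 5))
  s2 <- sdt_per_room(resp2)
  expect_equal(s2$hr, 0.5)
  expect_equal(s2$dprime, qnorm(0.5) - qnorm(s2$far_adj))

  # HR = FAR -> d' = 0
  resp4 <- tibble::tibble(participant_id = "P", status = rep(c("old", "lure"), each = 4),
                          source_room = "dark",
                          old_response = rep(c("yes", "no", "yes", "no"), 2))
  s4 <- sdt_per_room(resp4)
  expect_equal(s4$dprime, 0)
})

test_that("cohort-level HR and FAR recover the base generative rates", {
  co <- small_cohort()
  s <- sdt_per_room(co$responses)
  far <- mean(s$far)
  # lure false alarms: binomial around base_far_lure = .20 (9 lures/room)
  se_far <- sqrt(0.2 * 0.8 / (nrow(s) * 9))
  expect_lt(abs(far - 0.20), 4 * se_far)
  expect_true(all(s$hr >= 0 & s$hr <= 1))
})

test_that("source attribution scores hits against the encoding room", {
  resp <- tibble::tibble(
    participant_id = rep(c("P1", "P2"), each = 4),
    status = "old",
    source_room = rep(c("light", "dark"), 4),
    old_response = c(rep("yes", 7), "no"),
    source_response = c("light", "dark", "light", "dark",
                        "dark", "dark", "dark", NA)
  )
  sa <- source_attribution(resp)
  p1 <- sa$per_participant[sa$per_participant$participant_id == "P1", ]
  expect_equal(p1$source_hr, c(1, 1))
  p2d <- sa$per_participant[sa$per_participant$participant_id == "P2" &
                              sa$per_participant$room_id == "dark", ]
  expect_equal(p2d$source_hr, 1)
  p2l <- sa$per_participant[sa$per_participant$participant_id == "P2" &
                              sa$per_participant$room_id == "light", ]
  expect_equal(p2l$source_hr, 0)
  # zero hits in a room -> flagged
  resp2 <- resp[resp$source_room == "light" | resp$participant_id == "P1", ]
  resp2$old_response[resp2$participant_id == "P2"] <- "no"
  sa2 <- source_attribution(resp2)
  flagged <- sa2$per_participant[sa2$per_participant$participant_id == "P2", ]
  expect_true(all(flagged$flagged))
})

test_that("confidence means follow the 1=Sure coding and exclusion rule", {
  pr <- toy_pairs()
  resp <- tibble::tibble(
    participant_id = "P1", status = "old", source_room = "light",
    old_response = "yes", confidence = c(1L, 1L, 1L)
  )
  cs <- confidence_summary(resp, pr)
  expect_equal(cs$conf_light, 1)
  resp$confidence <- c(1L, 2L, 3L)
  expect_equal(confidence_summary(resp, pr)$conf_light, 2)
  # equal mix of the four levels -> 2.5
  resp4 <- tibble::tibble(participant_id = "P1", status = "old",
                          source_room = "dark", old_response = "yes",
                          confidence = 1:4)
  expect_equal(confidence_summary(resp4, pr[0, ])$conf_dark, 2.5)
  # no dark-room hits -> excluded as NA
  expect_true(is.na(confidence_summary(resp, pr)$conf_dark))
  # sure_high flips the scale
  expect_equal(confidence_summary(resp4, pr[0, ], direction = "sure_high")$conf_dark, 2.5)
  expect_equal(confidence_summary(resp, pr, direction = "sure_high")$conf_light, 3)
})

test_that("group contrasts expose t, d and BF01 with listwise deletion", {
  stats <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6),
    hr_same = c(.7, .8, .6, .9, .75, .65),
    hr_across = c(.6, .7, .55, .8, .7, .6)
  )
  ct <- suppressWarnings(group_contrasts(stats))
  row <- ct[ct$statistic == "hr_same_vs_across", ]
  ref <- t.test(stats$hr_same, stats$hr_across, paired = TRUE)
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(row$p, ref$p.value, tolerance = 1e-10)
  expect_gt(row$bf01, 0)

  # diffs {0, 1, 2} -> d = 1
  stats2 <- tibble::tibble(participant_id = c("a", "b", "c"),
                           hr_same = c(1, 2, 3), hr_across = c(1, 1, 1))
  ct2 <- suppressWarnings(group_contrasts(stats2))
  expect_equal(ct2$cohen_d[ct2$statistic == "hr_same_vs_across"], 1)

  # identical vectors -> t = 0, p = 1, d = 0
  stats3 <- tibble::tibble(participant_id = c("a", "b", "c"),
                           hr_same = c(.5, .6, .7), hr_across = c(.5, .6, .7))
  ct3 <- suppressWarnings(group_contrasts(stats3))
  row3 <- ct3[ct3$statistic == "hr_same_vs_across", ]
  expect_equal(row3$t, 0); expect_equal(row3$p, 1); expect_equal(row3$cohen_d, 0)

  # a contrast with < 2 complete participants is skipped with a warning
  stats4 <- tibble::tibble(participant_id = c("a", "b", "c"),
                           hr_same = c(.5, NA, NA), hr_across = c(.5, .6, NA))
  expect_warning(group_contrasts(stats4), "skipped")
})

test_that("close/remote rates aggregate back to the classifiable same-room rate", {
  co <- small_cohort()
  pairs <- pair_outcomes(walkmem:::label_pairs_by_participant(co$trials),
                         co$responses)
  for (pid in unique(pairs$participant_id)) {
    pp <- pairs[pairs$participant_id == pid, ]
    cl <- conditional_hr(pp, "close"); rm <- conditional_hr(pp, "remote")
    n_cl <- cl$n_pairs; n_rm <- rm$n_pairs
    if (n_cl == 0 || n_rm == 0) next
    pooled <- (cl$hr * n_cl + rm$hr * n_rm) / (n_cl + n_rm)
    expect_equal(pooled, conditional_hr(pp, "same")$hr, tolerance = 1e-12)
  }
})

test_that("directional one-tailed p halves the two-tailed p on cohort data", {
  co <- small_cohort()
  pairs <- pair_outcomes(walkmem:::label_pairs_by_participant(co$trials),
                         co$responses)
  stats <- participant_stats(co$responses, pairs)
  keep <- !is.na(stats$hr_close_fwd) & !is.na(stats$hr_remote_fwd)
  x <- stats$hr_close_fwd[keep]; y <- stats$hr_remote_fwd[keep]
  if (sum(keep) >= 3 && mean(x - y) > 0 && sd(x - y) > 0) {
    one <- paired_t(x, y, tail = "greater")
    two <- paired_t(x, y, tail = "two.sided")
    expect_equal(one$p, two$p / 2, tolerance = 1e-12)
  } else {
    succeed("no directional effect in this fixture; identity vacuous")
  }
})

test_that("the boundary contrast stays null-calibrated under the null model", {
  lay <- fixed_layouts()
  w <- simulate_walk(lay$light, cohort_params(), seed = 1, participant_id = "P")
  v <- segment_visits(w, lay$light)
  w2 <- simulate_walk(lay$dark, cohort_params(), seed = 2, participant_id = "P")
  v2 <- segment_visits(w2, lay$dark)
  dists <- list(light = travelled_distances(w, v[order(v$central_t), ]),
                dark = travelled_distances(w2, v2[order(v2$central_t), ]))
  params <- cohort_params(beta_room = 0, beta_lag = 0, beta_dist = 0)
  reject <- logical(80)
  for (k in seq_len(80)) {
    resp <- responses_only(10, params, dists, lay, seed = 3000 + k)
    pairs <- pair_outcomes(walkmem:::label_pairs_by_participant(resp), resp)
    same <- conditional_hr(pairs, "same")$hr
    acr <- conditional_hr(pairs, "across")$hr
    keep <- !is.na(same) & !is.na(acr)
    reject[k] <- sum(keep) >= 3 && sd(same[keep] - acr[keep]) > 0 &&
      paired_t(same[keep], acr[keep])$p < 0.05
  }
  # expected rate .05: allow 3 binomial SE around it
  expect_lt(mean(reject), 0.05 + 3 * sqrt(0.05 * 0.95 / 80))
})
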