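# Distance-based mnemonic probability functions and the sign-flip
# permutation t-test.

test_that("eligibility keeps same-room first-hit pairs with clean distances", {
  pr <- tibble::tibble(
    participant_id = "P1",
    room_relation = c("same", "same", "across", "same"),
    first_is_hit = c(TRUE, FALSE, TRUE, TRUE),
    spatial_m = c(2, 3, 4, 5), temporal_s = c(20, 30, 40, 50),
    dist_flagged = c(FALSE, FALSE, FALSE, TRUE),
    second_hit = TRUE
  )
  kept <- eligible_pairs(pr)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$spatial_m, 2)
})

test_that("bin edges span the pooled range in equal widths", {
  pr <- make_pairs(rep(c("a", "b"), each = 6),
                   spatial_m = c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 11),
                   second_hit = rep(TRUE, 12))
  dm <- compute_dmpf(pr, "spatial")
  expect_equal(attr(dm, "bin_edges"), c(1, 3, 5, 7, 9, 11))
  # max edge inclusive: the 11 m pairs land in bin 5
  expect_equal(dm$pair_count[dm$participant_id == "a" & dm$bin == 5], 2L)
  # all-hit participants have HR 1 in every non-empty bin
  expect_true(all(dm$hit_rate[dm$pair_count > 0] == 1))
  expect_true(all(is.na(dm$hit_rate[dm$pair_count == 0])))
  # per-participant bin counts sum to the eligible pair count
  expect_equal(sum(dm$pair_count), 12L)
  expect_error(compute_dmpf(pr[0, ], "spatial"), class = "walkmem_config_error")
})

test_that("flat identical d-MPFs give T = 0 and p = 1", {
  pr <- make_pairs(rep(c("a", "b", "c", "d"), each = 10),
                   spatial_m = rep(seq(1, 10, length.out = 10), 4),
                   second_hit = rep(c(TRUE, FALSE), 20))
  dm <- compute_dmpf(pr, "spatial")
  res <- perm_ttest(dm, "extreme_bins", n_perm = 500, seed = 1)
  expect_equal(res$T_obs, 0)
  expect_equal(res$p_perm, 1)
})

test_that("Monte-Carlo p agrees with exhaustive sign-flip enumeration", {
  set.seed(42)
  n <- 8
  pids <- sprintf("P%d", 1:n)
  # 2 pairs in each of bins 1 and 5 per participant, random outcomes
  pr <- make_pairs(rep(pids, each = 4),
                   spatial_m = rep(c(0.5, 0.6, 9.5, 10), n),
                   second_hit = runif(4 * n) < rep(runif(n, .3, .9), each = 4))
  dm <- compute_dmpf(pr, "spatial")
  mc <- perm_ttest(dm, "extreme_bins", n_perm = 2000, seed = 7)
  ex <- perm_ttest(dm, "extreme_bins", exhaustive = TRUE)
  expect_equal(ex$n_perm, 2^8)
  expect_lt(abs(mc$p_perm - ex$p_perm), 0.02)
  expect_equal(mc$df, ex$df)
  expect_equal(mc$T_obs, ex$T_obs)
})

test_that("permutation p-values are stable across permutation seeds", {
  set.seed(9)
  n <- 12
  pr <- make_pairs(rep(sprintf("P%d", 1:n), each = 6),
                   spatial_m = rep(c(1, 2, 4, 6, 8, 10), n),
                   second_hit = runif(6 * n) < 0.6)
  dm <- compute_dmpf(pr, "spatial")
  p1 <- perm_ttest(dm, "extreme_bins", seed = 1)$p_perm
  p2 <- perm_ttest(dm, "extreme_bins", seed = 2)$p_perm
  expect_lt(abs(p1 - p2), 2 * sqrt(p1 * (1 - p1) / 2000) + 1e-3)
})

test_that("permutation p-values are super-uniform under a sign-symmetric null", {
  set.seed(123)
  nsim <- 200
  pvals <- numeric(nsim)
  for (k in seq_len(nsim)) {
    n <- 12
    # balanced Bernoulli hit rates in extreme bins: null contrasts
    pr <- make_pairs(rep(sprintf("P%d", 1:n), each = 6),
                     spatial_m = rep(c(0.5, 0.7, 1.0, 9.0, 9.6, 10), n),
                     second_hit = runif(6 * n) < 0.55)
    dm <- compute_dmpf(pr, "spatial")
    pvals[k] <- perm_ttest(dm, "extreme_bins", n_perm = 500, seed = k)$p_perm
  }
  for (alpha in c(0.01, 0.05, 0.10)) {
    rate <- mean(pvals <= alpha)
    expect_lte(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / nsim))
  }
})

test_that("linear-trend contrasts recover slope signs", {
  n <- 10
  pids <- sprintf("P%d", 1:n)
  # strictly declining d-MPF: all hits in bin 1, none in bin 5
  pr <- make_pairs(rep(pids, each = 4),
                   spatial_m = rep(c(0.5, 0.7, 9.5, 10), n),
                   second_hit = rep(c(TRUE, TRUE, FALSE, FALSE), n))
  dm <- compute_dmpf(pr, "spatial")
  res <- perm_ttest(dm, "linear_trend", n_perm = 200, seed = 3)
  expect_lt(res$T_obs, 0)
  expect_lt(res$p_perm, 0.05)
  # extreme-bins agrees on the sign convention: far minus near is negative
  res2 <- perm_ttest(dm, "extreme_bins", n_perm = 200, seed = 3)
  expect_lt(res2$T_obs, 0)
  expect_true(all(res2$contrasts == -1))
})

test_that("participants missing an extreme bin are dropped listwise", {
  pr <- dplyr::bind_rows(
    make_pairs(rep("full1", 4), c(0.5, 1, 9, 10), c(TRUE, TRUE, FALSE, TRUE)),
    make_pairs(rep("full2", 4), c(0.6, 1, 9, 10), c(TRUE, FALSE, FALSE, TRUE)),
    make_pairs(rep("full3", 4), c(0.6, 1, 8.9, 10), c(TRUE, FALSE, TRUE, TRUE)),
    make_pairs(rep("mid_only", 3), c(4, 5, 6), c(TRUE, TRUE, FALSE))
  )
  dm <- compute_dmpf(pr, "spatial")
  res <- perm_ttest(dm, "extreme_bins", n_perm = 100, seed = 1)
  expect_equal(res$n_complete, 3L)
  expect_equal(res$df, 2L)
  pr2 <- pr[pr$participant_id %in% c("full1", "full2", "mid_only"), ]
  expect_error(perm_ttest(compute_dmpf(pr2, "spatial"), n_perm = 50),
               class = "walkmem_config_error")
})

test_that("an injected negative distance slope yields a declining group d-MPF", {
  co <- generate_cohort(cohort_params(n_participants = 60, seed = 314))
  an <- analyze_cohort(co, seed = 3, scope = "dmpf")
  means <- vapply(1:5, function(b) {
    h <- an$dmpf_spatial$hit_rate[an$dmpf_spatial$bin == b]
    mean(h, na.rm = TRUE)
  }, numeric(1))
  expect_equal(cor(means, 1:5, method = "spearman"), -1)
  expect_lt(an$perm_spatial$T_obs, 0)
  expect_lt(an$perm_spatial$p_perm, 0.05)
})

test_that("the d-MPF plot is a ggplot object", {
  pr <- make_pairs(rep("a", 10), seq(1, 10), runif(10) < .6)
  dm <- compute_dmpf(pr, "spatial")
  expect_s3_class(plot_dmpf(dm), "ggplot")
})
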