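# Distance-based mnemonic probability functions (d-MPFs): per-participant
# hit rates of the second member of eligible sequential pairs, binned by the
# spatial or temporal distance physically travelled between the two
# paintings during encoding, and the sign-flip permutation t-test of the
# resulting distance contrast.

#' Filter pairs eligible for the d-MPF
#'
#' Keeps sequential pairs that were encoded in the same room, whose first
#' probe was correctly recognised, and whose travelled distances are
#' available and unflagged.
#'
#' @param pairs a [pair_outcomes()] table with distance columns.
#' @return the filtered pairs tibble.
#' @export
eligible_pairs <- function(pairs) {
  keep <- pairs$room_relation == "same" & pairs$first_is_hit &
    !is.na(pairs$spatial_m) & !is.na(pairs$dist_flagged) & !pairs$dist_flagged
  keep[is.na(keep)] <- FALSE
  pairs[keep, ]
}

#' Compute distance-based mnemonic probability functions
#'
#' Pools the eligible pairs of all participants (both rooms collapsed) to
#' fix `n_bins` equal-width distance bins spanning the pooled range
#' (max edge inclusive), then computes, per participant and bin, the hit
#' rate of the pairs' second probes. Empty bins have `hit_rate = NA` and
#' `pair_count = 0`.
#'
#' @param pairs an [eligible_pairs()] table.
#' @param metric `"spatial"` (meters) or `"temporal"` (seconds).
#' @param n_bins number of equal-width bins (default 5).
#' @return a `walkmem_dmpf` tibble (`participant_id, bin, hit_rate,
#'   pair_count`) with attributes `metric`, `bin_edges` and `bin_mid`.
#' @export
compute_dmpf <- function(pairs, metric = c("spatial", "temporal"), n_bins = 5) {
  metric <- match.arg(metric)
  if (nrow(pairs) == 0)
    abort("no eligible pairs: cannot compute a d-MPF.",
          class = "walkmem_config_error")
  v <- if (metric == "spatial") pairs$spatial_m else pairs$temporal_s
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  if (edges[1] == edges[n_bins + 1])
    edges <- edges[1] + (seq_len(n_bins + 1) - 1 - n_bins / 2) * 1e-6
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  pids <- unique(pairs$participant_id)
  grid <- tidyr::expand_grid(participant_id = pids, bin = seq_len(n_bins))
  agg <- summarise(group_by(tibble(participant_id = pairs$participant_id,
                                   bin = bin, hit = pairs$second_hit),
                            .data$participant_id, .data$bin),
                   hit_rate = mean(.data$hit), pair_count = dplyr::n(),
                   .groups = "drop")
  out <- left_join(grid, agg, by = c("participant_id", "bin"))
  out$pair_count[is.na(out$pair_count)] <- 0L
  total <- vapply(split(out$pair_count, out$participant_id), sum, numeric(1))
  assert_that(sum(total) == nrow(pairs),
              "d-MPF bin counts must sum to the eligible pair count.")
  structure(out, metric = metric, bin_edges = edges,
            bin_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
            class = c("walkmem_dmpf", class(out)))
}

# Per-participant distance contrast extracted from a d-MPF.
#   extreme_bins: HR(last bin) - HR(first bin)  -> negative when memory
#                 fades with distance (the convention in which the observed
#                 group T and Cohen's d are reported).
#   linear_trend: least-squares slope of HR on bin midpoint over non-empty
#                 bins (>= 2 bins required).
dmpf_contrasts <- function(dmpf, contrast_mode) {
  mids <- attr(dmpf, "bin_mid")
  n_bins <- length(mids)
  per <- split(as.data.frame(dmpf), dmpf$participant_id)
  vals <- vapply(per, function(d) {
    d <- d[order(d$bin), ]
    if (contrast_mode == "extreme_bins") {
      lo <- d$hit_rate[d$bin == 1]
      hi <- d$hit_rate[d$bin == n_bins]
      if (is.na(lo) || is.na(hi)) NA_real_ else hi - lo
    } else {
      keep <- !is.na(d$hit_rate)
      if (sum(keep) < 2) return(NA_real_)
      x <- mids[d$bin[keep]]
      y <- d$hit_rate[keep]
      sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    }
  }, numeric(1))
  vals
}

#' Sign-flip permutation t-test of the d-MPF distance contrast
#'
#' Reduces each participant's d-MPF to one contrast value (see
#' `contrast_mode`), excludes participants for whom it is undefined
#' (listwise: both extreme bins non-empty, or >= 2 non-empty bins for the
#' trend), and tests the group mean against zero with a paired t statistic
#' whose null distribution is built by randomly negating each participant's
#' contrast (the within-participant sign-flip scheme; contrasts are
#' exchangeable in sign under the null of no distance effect). The
#' two-tailed permutation p-value is the proportion of surrogate |T| values
#' at or above |T_obs|, add-one smoothed to `(1 + k) / (n_perm + 1)` by
#' default (`p_smoothing = FALSE` gives the raw proportion). With
#' `exhaustive = TRUE` (n <= 20) all 2^n sign assignments are enumerated
#' instead of sampled.
#'
#' @param dmpf a [compute_dmpf()] result.
#' @param contrast_mode `"extreme_bins"` or `"linear_trend"`.
#' @param n_perm number of random sign assignments (default 2000).
#' @param seed permutation seed.
#' @param p_smoothing use the add-one estimator.
#' @param exhaustive enumerate all sign assignments instead of sampling.
#' @return a `walkmem_perm_ttest` list: `T_obs, df, p_perm, cohen_d,
#'   n_perm, n_complete, contrast_mode, metric, contrasts`.
#' @export
perm_ttest <- function(dmpf, contrast_mode = c("extreme_bins", "linear_trend"),
                       n_perm = 2000, seed = 1, p_smoothing = TRUE,
                       exhaustive = FALSE) {
  contrast_mode <- match.arg(contrast_mode)
  d <- dmpf_contrasts(dmpf, contrast_mode)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 3)
    abort(sprintf("only %d participant(s) with a defined contrast; >= 3 required.", n),
          class = "walkmem_config_error")
  t_of <- function(m) {
    s2 <- (sum(d^2) - n * m^2) / (n - 1)
    ifelse(s2 <= 0, ifelse(m == 0, 0, sign(m) * Inf), m / sqrt(s2 / n))
  }
  T_obs <- t_of(mean(d))
  if (exhaustive) {
    if (n > 20)
      abort("exhaustive enumeration limited to n <= 20.",
            class = "walkmem_config_error")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_eff <- nrow(signs)
  } else {
    signs <- with_seed(seed,
                       matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), ncol = n))
    n_eff <- n_perm
  }
  m_star <- as.vector(signs %*% d) / n
  T_star <- t_of(m_star)
  k <- sum(abs(T_star) >= abs(T_obs) - 1e-12)
  p <- if (p_smoothing) (1 + k) / (n_eff + 1) else k / n_eff
  structure(
    list(T_obs = T_obs, df = n - 1L, p_perm = p,
         cohen_d = if (sd(d) == 0) NA_real_ else mean(d) / sd(d),
         n_perm = n_eff, n_complete = n, contrast_mode = contrast_mode,
         metric = attr(dmpf, "metric"), contrasts = d,
         exhaustive = exhaustive, p_smoothing = p_smoothing),
    class = "walkmem_perm_ttest"
  )
}

#' @export
print.walkmem_perm_ttest <- function(x, ...) {
  cat(sprintf(
    "<d-MPF permutation t-test (%s, %s): T[%d] = %.2f, p_perm = %.4g, Cohen's d = %.2f, %d participants, %d permutations>\n",
    x$metric, x$contrast_mode, x$df, x$T_obs, x$p_perm, x$cohen_d,
    x$n_complete, x$n_perm))
  invisible(x)
}

#' Bar plot of a d-MPF
#'
#' Group-mean hit rate per distance bin with SEM error bars, mirroring the
#' standard d-MPF figure layout.
#'
#' @param dmpf a [compute_dmpf()] result.
#' @return a ggplot object.
#' @export
plot_dmpf <- function(dmpf) {
  metric <- attr(dmpf, "metric")
  mids <- attr(dmpf, "bin_mid")
  edges <- attr(dmpf, "bin_edges")
  summ <- summarise(group_by(as_tibble(dmpf), .data$bin),
                    mean_hr = mean(.data$hit_rate, na.rm = TRUE),
                    sem = sd(.data$hit_rate, na.rm = TRUE) /
                      sqrt(sum(!is.na(.data$hit_rate))),
                    .groups = "drop")
  summ$mid <- mids[summ$bin]
  unit <- if (metric == "spatial") "m" else "s"
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(round(.data$mid, 1)),
                                     y = .data$mean_hr)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_hr - .data$sem,
                                        ymax = .data$mean_hr + .data$sem),
                           width = 0.2) +
    ggplot2::labs(
      x = sprintf("travelled %s distance, bin midpoint (%s)", metric, unit),
      y = "hit rate (second item)",
      title = sprintf("d-MPF: %s distance (bin width %.1f %s)", metric,
                      diff(edges)[1], unit)
    ) +
    ggplot2::theme_minimal()
}
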