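test_that("signed-rank z follows the declared sign convention and degenerates loudly", {
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "fewer than 5 nonzero")
  expect_error(wilcoxon_signed_rank(1:3, 2:4), "fewer than 5 nonzero")
  wt <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))
  expect_lt(wt$z, 0)          # uniform improvement => negative z
  expect_equal(wt$n_effective, 6)
  # antisymmetry: swapping pre and post flips z, keeps p
  set.seed(51)
  pre <- sample(0:80, 30, replace = TRUE)
  post <- pmin(80, pre + sample(-5:15, 30, replace = TRUE))
  a <- wilcoxon_signed_rank(pre, post)
  b <- wilcoxon_signed_rank(post, pre)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
})

test_that("signed-rank p matches stats::wilcox.test on tied, gridded scores", {
  set.seed(52)
  for (rep in 1:20) {
    pre <- sample(seq(0, 100, by = 5), 40, replace = TRUE)
    post <- pmin(100, pre + sample(seq(-10, 20, by = 5), 40, replace = TRUE))
    if (sum(post != pre) < 5) next
    ours <- wilcoxon_signed_rank(pre, post)
    ref <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE,
                         correct = FALSE))
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("with distinct differences the tie term vanishes and z matches the closed form", {
  d <- c(3, -1, 7, 2, -4, 9, 5, -8)
  pre <- rep(0, 8); post <- d
  wt <- wilcoxon_signed_rank(pre, post)
  n <- 8
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  z_closed <- (w - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(wt$z, -z_closed, tolerance = 1e-12)
})

test_that("normal-approximation p tracks the exhaustive 2^n permutation oracle", {
  set.seed(53)
  for (rep in 1:10) {
    d <- sample(c(-1, 1), 8, replace = TRUE) * sample(seq(1, 40), 8)
    wt <- wilcoxon_signed_rank(rep(0, 8), d)
    p_exact <- exact_signed_rank_p(d)
    expect_lt(abs(wt$p - p_exact), 0.05)
  }
})

test_that("Rosenthal r and labels behave across the threshold bands", {
  expect_equal(rosenthal_r(0, 307)$r, 0)
  expect_equal(rosenthal_r(0, 307)$label, "weak")
  expect_equal(rosenthal_r(-5.2, 307)$label, "weak")     # |r| = 0.297
  expect_equal(rosenthal_r(-5.3, 307)$label, "moderate") # |r| = 0.302
  expect_equal(rosenthal_r(10.6, 307)$label, "strong")   # |r| = 0.605
  expect_error(rosenthal_r(1, 0), "n_pairs")
})

test_that("McNemar statistic, degenerate case and stats::mcnemar.test agreement", {
  # b = c = 5: symmetric, no change
  sym <- mcnemar_test(rep(c(TRUE, FALSE), 5), rep(c(FALSE, TRUE), 5))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)
  # b = 10, c = 2 by construction
  pre <- rep(c(TRUE, FALSE, TRUE), c(10, 2, 8))
  post <- rep(c(FALSE, TRUE, TRUE), c(10, 2, 8))
  m <- mcnemar_test(pre, post)
  expect_equal(m$discordant, list(b = 10, c = 2))
  expect_equal(m$statistic, 64 / 12, tolerance = 1e-12)
  # no discordant pairs at all
  none <- mcnemar_test(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(none$statistic, 0)
  expect_equal(none$p, 1)
  # agreement with the standard implementation (no continuity correction)
  set.seed(54)
  for (rep in 1:20) {
    a <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    if (sum(a != b) == 0) next
    ours <- mcnemar_test(a, b)
    ref <- stats::mcnemar.test(table(factor(a, c(FALSE, TRUE)),
                                     factor(b, c(FALSE, TRUE))),
                               correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("pre/post summary matches order-statistics oracle and flags degeneracy", {
  set.seed(55)
  sim <- simulate_cohort(sim_config(n_participants = 60, seed = 60))
  cohort <- build_paired_cohort(select_first_posttest(sim$responses), sim$bank)
  scores <- score_cohort(cohort, sim$bank)
  profiles <- profile_cohort(cohort, sim$bank)
  s <- prepost_summary(scores, profiles)
  expect_equal(s$score, c("ctf_sum", "binary_pct", "ac", "bs", "ccp", "cip", "dis"))

  # medians/IQR against independent sort-based quantile arithmetic
  pre_ctf <- scores$ctf_sum[scores$phase == "pre"]
  expect_equal(s$median_pre[1], sort_quantile(pre_ctf, 0.5))
  expect_equal(s$q1_pre[1], sort_quantile(pre_ctf, 0.25))
  expect_equal(s$q3_pre[1], sort_quantile(pre_ctf, 0.75))
  expect_equal(s$min_pre[1], min(pre_ctf))
  post_ac <- profiles$ac[profiles$phase == "post"]
  expect_equal(s$median_post[3], sort_quantile(post_ac, 0.5))

  # improvement cohort: negative z for the knowledge scores
  expect_lt(s$z[s$score == "ctf_sum"], 0)
  expect_lt(s$z[s$score == "binary_pct"], 0)

  # pairwise exclusion bookkeeping: n + n_excluded is the cohort size
  expect_true(all(s$n + s$n_excluded == cohort$n))

  # null cohort (post identical to pre): every row flagged, no statistics
  null_scores <- scores
  null_profiles <- profiles
  for (col in c("ctf_sum", "ctf_pct", "binary_pct"))
    null_scores[[col]][null_scores$phase == "post"] <-
      null_scores[[col]][null_scores$phase == "pre"]
  for (col in c("ac", "bs", "ccp", "cip", "dis", "cc", "uc", "ci", "ui"))
    null_profiles[[col]][null_profiles$phase == "post"] <-
      null_profiles[[col]][null_profiles$phase == "pre"]
  s0 <- prepost_summary(null_scores, null_profiles)
  expect_true(all(is.na(s0$z)))
  expect_true(all(!is.na(s0$note)))
})
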