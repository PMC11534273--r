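test_that("simulation config validates probabilities and sizes", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(dropout_post = 1.2), "probability")
  expect_error(sim_config(conf_given_correct_pre = -0.1), "probability")
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(knowledge_pre = c(1, -2)), "Beta")
})

test_that("a fixed seed reproduces the cohort bit-identically, on disk too", {
  cfg <- sim_config(n_participants = 25, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$truth$theta, b$truth$theta)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_responses(a$responses, pa)
  write_responses(b$responses, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
  c_ <- simulate_cohort(sim_config(n_participants = 25, seed = 124))
  expect_false(identical(a$responses$choice, c_$responses$choice))
})

test_that("generated data always passes pipeline validation end-to-end", {
  sim <- simulate_cohort(sim_config(n_participants = 30, seed = 2,
                                    dropout_post = 0.2,
                                    extra_attempts_max = 2))
  # records validate, keys count as configured
  expect_s3_class(sim$responses, "ctf_responses")
  expect_equal(sum(!sim$bank$answer_key), 13)
  cohort <- build_paired_cohort(select_first_posttest(sim$responses), sim$bank)
  expect_lte(cohort$n, 30)
  # without dropout the paired n equals the simulated n
  sim0 <- simulate_cohort(sim_config(n_participants = 30, seed = 2))
  cohort0 <- build_paired_cohort(select_first_posttest(sim0$responses), sim0$bank)
  expect_equal(cohort0$n, 30)
})

test_that("posttest dropout thins the paired cohort at the configured rate", {
  sim <- simulate_cohort(sim_config(n_participants = 100, seed = 9,
                                    dropout_post = 0.3))
  cohort <- build_paired_cohort(select_first_posttest(sim$responses), sim$bank)
  # 70 expected; allow ~3.5 binomial SDs
  expect_gt(cohort$n, 54)
  expect_lt(cohort$n, 86)
  expect_equal(cohort$n, sum(sim$truth$has_post))
})

test_that("retakes are biased upward, so the first-attempt rule matters", {
  sim <- simulate_cohort(sim_config(n_participants = 120, seed = 14,
                                    extra_attempts_max = 3,
                                    attempt_bonus = 1.5))
  # extra attempts have strictly later timestamps
  post <- sim$responses[sim$responses$phase == "post", ]
  expect_gt(max(post$attempt_time), 1)
  first <- build_paired_cohort(select_first_posttest(sim$responses), sim$bank)
  # keep the LAST attempt instead and compare mean posttest scores
  tmax <- stats::ave(post$attempt_time, post$participant_id, FUN = max)
  last_post <- post[post$attempt_time == tmax, ]
  last_post$attempt_time <- 1
  last_records <- rbind(sim$responses[sim$responses$phase == "pre", ], last_post)
  last <- build_paired_cohort(last_records, sim$bank)
  s_first <- score_cohort(first, sim$bank)
  s_last <- score_cohort(last, sim$bank)
  m_first <- mean(s_first$ctf_sum[s_first$phase == "post"])
  m_last <- mean(s_last$ctf_sum[s_last$phase == "post"])
  expect_gt(m_last, m_first)
})

test_that("marginal pretest correctness converges to the model integral", {
  cfg <- sim_config(n_participants = 10000, seed = 17)
  sim <- simulate_cohort(cfg)
  pre <- sim$responses[sim$responses$phase == "pre", ]
  key <- sim$bank$answer_key[match(pre$item_id, sim$bank$item_id)]
  rate <- mean(binary_correct(pre$choice, key))
  # conditional on the realized item offsets delta_j (only n_items of them
  # are drawn), the marginal correctness is the ability integral
  # mean_j E_p[plogis(qlogis(p) + delta_j)], p ~ Beta(a, b) — computed by
  # numerical integration, independent of the simulator's response draws
  per_item <- vapply(sim$truth$delta, function(dj) {
    stats::integrate(function(p)
      stats::plogis(stats::qlogis(p) + dj) *
        stats::dbeta(p, cfg$knowledge_pre[1], cfg$knowledge_pre[2]),
      1e-8, 1 - 1e-8)$value
  }, numeric(1))
  expected <- mean(per_item)
  expect_equal(rate, expected, tolerance = 0.02)
})

test_that("all-confident limit collapses AC onto binary accuracy", {
  sim <- simulate_cohort(sim_config(n_participants = 40, seed = 19,
                                    conf_given_correct_pre = 1,
                                    conf_given_incorrect_pre = 1,
                                    conf_given_correct_post = 1,
                                    conf_given_incorrect_post = 1))
  cohort <- build_paired_cohort(select_first_posttest(sim$responses), sim$bank)
  prof <- profile_cohort(cohort, sim$bank)
  sc <- score_cohort(cohort, sim$bank)
  expect_true(all(prof$ui == 0 & prof$uc == 0))
  m <- merge(prof, sc, by = c("participant_id", "phase"))
  expect_equal(m$ac, m$cc / m$n_items)
  expect_equal(100 * m$ac, m$binary_pct)
})

test_that("parameter recovery finds the configured confidence calibration", {
  sim <- simulate_cohort(sim_config(n_participants = 1000, seed = 23,
                                    conf_given_correct_pre = 0.8,
                                    conf_given_incorrect_pre = 0.3,
                                    conf_given_correct_post = 0.8,
                                    conf_given_incorrect_post = 0.3))
  rec <- recover_parameters(sim)
  expect_equal(nrow(rec), 4)
  expect_true(all(abs(rec$bias) < 0.03))
  expect_true(all(rec$n_defined > 900))
})

test_that("a null knowledge effect leaves mean binary scores unchanged", {
  sim <- simulate_cohort(sim_config(n_participants = 2000, seed = 29,
                                    knowledge_effect = 0))
  cohort <- build_paired_cohort(select_first_posttest(sim$responses), sim$bank)
  sc <- score_cohort(cohort, sim$bank)
  gap <- abs(mean(sc$binary_pct[sc$phase == "post"]) -
               mean(sc$binary_pct[sc$phase == "pre"]))
  expect_lt(gap, 2)
})
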