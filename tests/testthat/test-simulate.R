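test_that("detection probability follows the salience model", {
  cfg <- cohort_config()
  # mid ramp-up: fully salient in either protocol
  expect_equal(detection_probability(15, active_protocol(), cfg), cfg$p_on)
  expect_equal(detection_probability(15, sham_protocol(), cfg), cfg$p_on)
  # long after sham current-off plus the persistence window: floor
  expect_equal(
    detection_probability(80 + cfg$persistence_s + 1, sham_protocol(), cfg),
    cfg$p_off
  )
  # no desensitisation limit: plateau stays at p_on
  cfg_inf <- cohort_config(desensitization_halflife_s = Inf)
  expect_equal(detection_probability(60, active_protocol(), cfg_inf),
               cfg_inf$p_on)
  expect_error(detection_probability(-1, active_protocol(), cfg),
               "non-negative")
})

test_that("detection probability is bounded and decays after active ramp-down onset", {
  cfg <- cohort_config()
  t <- seq(0, 1200, by = 5)
  p <- detection_probability(t, active_protocol(), cfg)
  expect_true(all(p >= cfg$p_off - 1e-12 & p <= cfg$p_on + 1e-12))
  after <- t >= 630  # active ramp-down onset
  expect_true(all(diff(p[after]) <= 1e-12))
})

test_that("cohorts are bit-reproducible under a fixed seed and differ across seeds", {
  a <- simulate_cohort(quick_cfg(6), seed = 11)
  b <- simulate_cohort(quick_cfg(6), seed = 11)
  c <- simulate_cohort(quick_cfg(6), seed = 12)
  expect_identical(a$probes, b$probes)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$guesses, b$guesses)
  expect_false(identical(a$probes, c$probes))
})

test_that("cohort structure matches the crossover design", {
  n <- 8
  cohort <- simulate_cohort(quick_cfg(n), seed = 5)
  counts <- dplyr::count(cohort$probes, participant_id, condition)
  expect_true(all(counts$n == 32))
  expect_equal(nrow(counts), n * 2)

  trials <- cohort$trials
  per_session <- dplyr::count(trials, participant_id, condition)
  expect_true(all(per_session$n == 420))
  in_stim <- dplyr::filter(trials, block %in% c(2, 3))
  expect_true(all(dplyr::count(in_stim, participant_id, condition)$n == 220))
  post <- dplyr::filter(trials, block == 4)
  expect_true(all(dplyr::count(post, participant_id, condition)$n == 100))
  expect_equal(sort(unique(trials$subblock)), 1:32)
  expect_true(all(is.na(trials$subblock[trials$block == 1])))

  expect_equal(nrow(cohort$ratings), n * 2)
  expect_equal(nrow(cohort$guesses), n)
})

test_that("degenerate generator settings produce deterministic records", {
  cfg <- cohort_config(n_participants = 4, p_on = 1, p_off = 0,
                       confidence_sd = 0, confidence_participant_sd = 0,
                       p_probe_missing = 0,
                       desensitization_halflife_s = Inf)
  cohort <- simulate_cohort(cfg, seed = 2)
  scored <- weighted_scores(cohort$probes)
  on <- scored$time_s <= 80 & scored$condition == "sham"
  expect_true(all(scored$score[on] == cfg$confidence_on_mean))
  off <- scored$time_s > 80 + cfg$persistence_s & scored$condition == "sham"
  expect_true(all(scored$score[off] == -cfg$confidence_off_mean))
  # active plateau with no desensitisation: always confidently "on"
  act <- scored$condition == "active" & scored$time_s <= 660
  expect_true(all(scored$score[act] == cfg$confidence_on_mean))

  all_correct <- simulate_cohort(cohort_config(n_participants = 3,
                                               accuracy_p = 1,
                                               p_no_response = 0), seed = 2)
  expect_true(all(all_correct$trials$correct))
  expect_true(all(!is.na(all_correct$trials$rt_ms)))
})

test_that("group scores at 120 s separate the conditions in sign", {
  # many participants stand in for many cohorts: the group mean weighted
  # score shortly after sham current-off is negative for sham, positive
  # for active
  cohort <- simulate_cohort(quick_cfg(1000), seed = 9)
  scored <- dplyr::filter(weighted_scores(cohort$probes), time_s == 120)
  means <- dplyr::summarise(dplyr::group_by(scored, condition),
                            m = mean(score, na.rm = TRUE))
  expect_lt(means$m[means$condition == "sham"], 0)
  expect_gt(means$m[means$condition == "active"], 0)
})

test_that("the anodal facilitation calibration scales with the requested dz", {
  cfg0 <- cohort_config(anodal_dz = 0)
  expect_equal(anodal_shift_ms(cfg0)$shift_ms, 0)
  cfg <- cohort_config(anodal_dz = 0.45)
  shift <- anodal_shift_ms(cfg)
  expect_equal(shift$shift_ms, 0.45 * shift$sd_contrast_ms)
  expect_gt(shift$sd_contrast_ms, cfg$anodal_sd_ms)  # median noise adds in
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(p_on = 0.4), "p_on")
  expect_error(cohort_config(p_off = 0.6), "p_off")
  expect_error(cohort_config(p_on = 0.51, p_off = 0.49, confidence_on_mean = 12),
               "confidence")
  expect_error(cohort_config(accuracy_p = 0), "accuracy_p")
  expect_error(cohort_config(practice_slope_ms_per_block = 1), "practice")
  expect_error(cohort_config(guess_informed_p = 0.3), "guess_informed_p")
})
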