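test_that("weighted scores combine answer sign and confidence", {
  expect_equal(weighted_score("yes", 10), 10)
  expect_equal(weighted_score("no", 10), -10)
  expect_equal(weighted_score("yes", 0), 0)
  expect_equal(weighted_score("no", 0), 0)
  expect_equal(weighted_score(c("yes", NA), c(3.5, NA)), c(3.5, NA))
  expect_error(weighted_score("maybe", 5), "yes")
  expect_error(weighted_score("yes", 12), "\\[0, 10\\]")
  scored <- weighted_scores(simulate_cohort(quick_cfg(4), seed = 1)$probes)
  expect_true(all(abs(scored$score) <= 10, na.rm = TRUE))
  expect_identical(is.na(scored$score), is.na(scored$answer))
})

test_that("bootstrap band of constant data collapses to the constant", {
  b <- bootstrap_median_ci(rep(7, 20), n_boot = 500)
  expect_equal(b$median, 7)
  expect_equal(b$ci_lo, 7)
  expect_equal(b$ci_hi, 7)
})

test_that("bootstrap CI endpoints match exhaustive enumeration for n = 3", {
  # oracle: all 27 equally likely resamples of 3 values, their medians,
  # and the same percentile rule applied to the exact distribution
  enum_ci <- function(x, level = 0.95) {
    idx <- expand.grid(1:3, 1:3, 1:3)
    meds <- apply(idx, 1, function(i) sort(x[as.numeric(i)])[2])
    a <- (1 - level) / 2
    quantile(meds, c(a, 1 - a), names = FALSE, type = 7)
  }
  for (x in list(c(-10, 0, 10), c(0, 0, 10), c(1, 2, 3), c(-5, -5, -5))) {
    oracle <- enum_ci(x)
    set.seed(1)
    got <- bootstrap_median_ci(x, n_boot = 4000)
    expect_equal(c(got$ci_lo, got$ci_hi), oracle,
                 info = paste(x, collapse = ","))
  }
})

test_that("probe bands are reproducible under a fixed seed and flag thin probes", {
  probes <- simulate_cohort(quick_cfg(8), seed = 4)$probes
  b1 <- probe_bands(probes, n_boot = 300, seed = 99)
  b2 <- probe_bands(probes, n_boot = 300, seed = 99)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$ci_lo <= b1$group_median & b1$group_median <= b1$ci_hi,
                  na.rm = TRUE))

  solo <- dplyr::filter(probes, participant_id == "P01")
  expect_true(all(probe_bands(solo, n_boot = 50)$flagged))
  expect_error(bootstrap_median_ci(c(1)), "at least 2")
})

test_that("window merging reproduces the first-to-last-probe convention", {
  distinct_at <- c(seq(120, 360, 30), 480, 510, 660, 690)
  win <- distinct_windows(bands_with_distinct_at(distinct_at))
  expect_equal(win$windows$start_s, c(120, 480, 660))
  expect_equal(win$windows$end_s, c(360, 510, 690))
  expect_equal(win$total_distinct_s, 300)
  expect_equal(glance(win)$n_distinct_probes, length(distinct_at))

  # identical bands: nothing distinct
  same <- bands_with_distinct_at(numeric(0))
  expect_equal(distinct_windows(same)$total_distinct_s, 0)

  # an isolated distinct probe contributes a zero-length window
  iso <- distinct_windows(bands_with_distinct_at(240))
  expect_equal(iso$windows$duration_s, 0)

  # mismatched grids error
  a <- bands_with_distinct_at(120)
  b <- a[a$time_s != 960 | a$condition == "active", ]
  expect_error(distinct_windows(b), "time grid")
})

test_that("window detection is symmetric and matches a run-length scanner", {
  times <- probe_schedule()
  set.seed(21)
  for (i in 1:200) {
    flags <- runif(32) < runif(1, 0.05, 0.6)
    bands <- bands_with_distinct_at(times[flags])
    win <- distinct_windows(bands)
    # oracle: explicit scanner over the flag vector
    oracle <- scan_windows(times, flags)
    expect_equal(win$windows$start_s, oracle$start_s)
    expect_equal(win$windows$end_s, oracle$end_s)
    # symmetry in the two conditions
    swapped <- dplyr::mutate(bands, condition = ifelse(condition == "active",
                                                       "sham", "active"))
    expect_equal(distinct_windows(swapped)$windows, win$windows)
    expect_lte(win$total_distinct_s, max(times) - min(times))
  }
})

test_that("widening any CI never increases the total distinct time", {
  times <- probe_schedule()
  set.seed(22)
  for (i in 1:50) {
    flags <- runif(32) < 0.3
    bands <- bands_with_distinct_at(times[flags])
    base_total <- distinct_windows(bands)$total_distinct_s
    widened <- bands
    j <- sample(nrow(bands), 5)
    widened$ci_lo[j] <- widened$ci_lo[j] - runif(5, 0, 8)
    widened$ci_hi[j] <- widened$ci_hi[j] + runif(5, 0, 8)
    expect_lte(distinct_windows(widened)$total_distinct_s, base_total)
  }
})

test_that("distinct time converts to percent of the stimulation-time difference", {
  expect_equal(round(percent_of_stim_difference(300), 1), 51.7)
  expect_equal(percent_of_stim_difference(0), 0)
  expect_equal(percent_of_stim_difference(580), 100)
  equal_protocols <- stim_protocol("sham", 30, 600, 30)
  expect_error(percent_of_stim_difference(300, active_protocol(), equal_protocols),
               "undefined")
})

test_that("logistic crossover fits classify response patterns", {
  t <- probe_schedule()
  probe_tbl <- function(answers) {
    tibble::tibble(participant_id = "P01", condition = "active",
                   probe_index = seq_along(t), time_s = t,
                   answer = answers,
                   confidence = ifelse(is.na(answers), NA_real_, 5))
  }
  # clean step: yes until 300 s, then no -> crossover in the flanking gap
  step <- fit_crossover(probe_tbl(ifelse(t <= 300, "yes", "no")))
  expect_equal(step$failure_reason, "ok")
  expect_gt(step$crossover_s, 300)
  expect_lt(step$crossover_s, 330)

  expect_equal(fit_crossover(probe_tbl(rep("yes", 32)))$failure_reason,
               "degenerate_responses")

  alt <- fit_crossover(probe_tbl(rep(c("yes", "no"), 16)))
  expect_equal(alt$failure_reason, "non_monotone")
  expect_lt(abs(alt$slope), 0.01)

  # noisy but monotone drift with the midpoint far outside the task window
  late <- fit_crossover(probe_tbl(
    c(rep("yes", 30), "no", "yes")))
  expect_true(late$failure_reason %in% c("crossover_out_of_range",
                                         "non_monotone"))

  mixed <- fit_crossover(probe_tbl(c(rep("yes", 10), rep(NA, 22))))
  expect_equal(mixed$failure_reason, "degenerate_responses")
})
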