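trial_row <- function(participant, condition, block, rt, correct = TRUE,
                      subblock = NA_integer_) {
  tibble::tibble(participant_id = participant, condition = condition,
                 block = as.integer(block), subblock = subblock,
                 stimulus = "diamond",
                 response = dplyr::case_when(is.na(rt) ~ "none",
                                             correct ~ "left",
                                             TRUE ~ "right"),
                 correct = correct & !is.na(rt), rt_ms = rt)
}

test_that("block medians use correct trials only and subtract baseline", {
  trials <- dplyr::bind_rows(
    trial_row("P01", "active", 1, c(400, 420, 500)),
    trial_row("P01", "active", 3, c(400, 420, 500)),
    # incorrect trials carry extreme RTs that must not leak in
    trial_row("P01", "active", 3, c(5, 4000), correct = FALSE)
  )
  bm <- block_medians(trials)
  b1 <- bm$median_rt_ms[bm$block == 1]
  b3 <- bm$median_rt_ms[bm$block == 3]
  expect_equal(b1, 420)
  expect_equal(b3, 420)
  expect_equal(bm$delta_rt_ms[bm$block == 3], 0)
  # oracle: recompute with an explicit filter
  oracle <- median(trials$rt_ms[trials$correct & trials$block == 3])
  expect_equal(b3, oracle)
})

test_that("participants with an empty block are flagged", {
  trials <- dplyr::bind_rows(
    trial_row("P01", "active", 1, c(400, 410)),
    trial_row("P01", "active", 2, c(NA_real_), correct = FALSE)
  )
  expect_warning(bm <- block_medians(trials), "P01")
  expect_true("P01" %in% attr(bm, "flagged"))
  expect_true(is.na(bm$median_rt_ms[bm$block == 2]))
})

test_that("paired t matches the dz closed form and an independent oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 500, 50)
    y <- rnorm(n, 495, 50)
    res <- paired_t_one_tailed(x, y, "greater")
    d <- x - y
    expect_equal(res$t, (mean(d) / sd(d)) * sqrt(n), tolerance = 1e-9)
    oracle <- t.test(x, y, paired = TRUE, alternative = "greater")
    expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(res$p, oracle$p.value, tolerance = 1e-9)
    expect_equal(res$df, unname(oracle$parameter))
  }
})

test_that("paired t agrees with a hand-computed textbook example", {
  x <- c(25, 29, 30, 27, 26)
  y <- c(23, 26, 28, 27, 24)
  # by hand: d = (2, 3, 2, 0, 2), mean 1.8, sd = sqrt(1.2), t = 1.8/sqrt(1.2/5)
  res <- paired_t_one_tailed(x, y, "greater")
  expect_equal(res$t, 1.8 / sqrt(1.2 / 5), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$dz, 1.8 / sqrt(1.2), tolerance = 1e-12)
})

test_that("mean-zero differences give t = 0 and one-tailed p = 0.5, zero variance errors", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)  # differences (-1, 1, -1, 1)
  res <- paired_t_one_tailed(x, y, "greater")
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)
  expect_error(paired_t_one_tailed(x, x), "zero variance")
})

test_that("TOST reproduces the standardised-bound closed forms", {
  res <- tost_from_dz(-0.02, 32, 0.4)
  expect_equal(round(res$t, 2), 2.15)
  expect_equal(round(res$p, 2), 0.02)
  expect_true(res$equivalent)
  expect_equal(res$t_lower, (-0.02 + 0.4) * sqrt(32), tolerance = 1e-12)
  expect_equal(res$t_upper, (-0.02 - 0.4) * sqrt(32), tolerance = 1e-12)

  # dz exactly at the upper bound: the binding one-sided test is at its null
  at_bound <- tost_from_dz(0.4, 32, 0.4)
  expect_equal(at_bound$t_upper, 0)
  expect_equal(at_bound$p, 0.5)
  expect_false(at_bound$equivalent)

  # p is monotone non-increasing in the bound
  set.seed(32)
  x <- rnorm(20, 500, 40)
  y <- x + rnorm(20, 1, 20)
  ps <- vapply(seq(0.1, 1.2, by = 0.1),
               function(b) tost_paired(x, y, b)$p, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))

  # tost_paired and tost_from_dz agree on the same data
  d <- x - y
  expect_equal(tost_paired(x, y, 0.4)$p,
               tost_from_dz(mean(d) / sd(d), 20, 0.4)$p, tolerance = 1e-12)
  expect_error(tost_paired(x, x, 0.4), "zero variance")
  expect_error(tost_from_dz(0.1, 32, 0), "positive")
})

test_that("accuracy summary counts non-responses as errors and is reproducible", {
  trials <- dplyr::bind_rows(
    trial_row("P01", "active", 1, c(400, 420)),
    trial_row("P02", "active", 1, c(400, 420))
  )
  acc <- accuracy_summary(trials, n_boot = 200, seed = 1)
  expect_equal(acc$mean_pct, 100)
  expect_equal(acc$ci_lo, 100)
  expect_equal(acc$ci_hi, 100)

  cohort <- simulate_cohort(quick_cfg(8), seed = 6)
  a1 <- accuracy_summary(cohort$trials, n_boot = 300, seed = 2)
  a2 <- accuracy_summary(cohort$trials, n_boot = 300, seed = 2)
  expect_identical(a1[c("mean_pct", "ci_lo", "ci_hi")],
                   a2[c("mean_pct", "ci_lo", "ci_hi")])
  # no-response trials lower accuracy
  cohort_miss <- simulate_cohort(cohort_config(n_participants = 8,
                                               accuracy_p = 0.9,
                                               p_no_response = 0.1), seed = 6)
  expect_lt(accuracy_summary(cohort_miss$trials, n_boot = 100,
                             seed = 1)$mean_pct, 95)
})

test_that("sub-block time course has 32 sub-blocks and collapses for constant RTs", {
  cohort <- simulate_cohort(quick_cfg(6), seed = 8)
  sub <- subblock_timecourse(cohort$trials, n_boot = 200, seed = 1)
  expect_equal(sort(unique(sub$bands$subblock)), 1:32)
  expect_equal(nrow(sub$bands), 64)  # 32 sub-blocks x 2 conditions

  const <- cohort$trials
  const$rt_ms[!is.na(const$rt_ms)] <- 430
  csub <- subblock_timecourse(const, n_boot = 100, seed = 1)
  expect_true(all(csub$bands$ci_lo == 430 & csub$bands$ci_hi == 430))
  expect_equal(csub$windows$total_distinct_s, 0)
})

test_that("null cohorts rarely show distinct RT sub-blocks", {
  distinct_any <- vapply(1:15, function(s) {
    cohort <- simulate_cohort(quick_cfg(32), seed = 100 + s)
    sub <- subblock_timecourse(cohort$trials, n_boot = 500, seed = s)
    sum(sub$windows$flags$distinct)
  }, numeric(1))
  expect_gte(mean(distinct_any == 0), 0.95)
})
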