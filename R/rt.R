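# Reaction-time pipeline: per-block medians of correct trials,
# baseline-corrected deltas, one-tailed paired tests with Cohen's dz, TOST
# equivalence, accuracy with a bootstrap CI, and the sub-block bootstrap
# time course.

#' Per-block median reaction times and baseline-corrected deltas
#'
#' Medians are taken over correct, responded trials only.  The Block-1
#' (pre-stimulation baseline) median is subtracted from each of Blocks 2-4
#' to give `delta_rt_ms`.  Participants with a block containing no usable
#' trial are flagged (their affected medians are `NA`).
#'
#' @param trials A trial tibble (see [read_trials()]).
#' @return A `block_summary` tibble: `participant_id`, `condition`,
#'   `block`, `n_correct`, `median_rt_ms`, `delta_rt_ms` (NA for Block 1).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 4), seed = 1)
#' block_medians(cohort$trials)
#' @export
block_medians <- function(trials) {
  usable <- trials[trials$correct & !is.na(trials$rt_ms), , drop = FALSE]
  grid <- tidyr::expand_grid(
    participant_id = unique(trials$participant_id),
    condition = unique(trials$condition),
    block = sort(unique(trials$block))
  )
  med <- dplyr::summarise(
    dplyr::group_by(usable, .data$participant_id, .data$condition, .data$block),
    n_correct = dplyr::n(),
    median_rt_ms = median(.data$rt_ms),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid, med,
                          by = c("participant_id", "condition", "block"))
  out$n_correct[is.na(out$n_correct)] <- 0L
  flagged <- unique(out$participant_id[out$n_correct == 0L])
  if (length(flagged) > 0) {
    warn(sprintf("participant(s) with an empty block flagged: %s",
                 paste(flagged, collapse = ", ")))
  }
  base <- out[out$block == 1L, c("participant_id", "condition", "median_rt_ms")]
  names(base)[3] <- "baseline_rt_ms"
  out <- dplyr::left_join(out, base, by = c("participant_id", "condition"))
  out$delta_rt_ms <- ifelse(out$block == 1L, NA_real_,
                            out$median_rt_ms - out$baseline_rt_ms)
  out$baseline_rt_ms <- NULL
  structure(out, class = c("block_summary", class(out)), flagged = flagged)
}

#' One-tailed paired t-test with Cohen's dz
#'
#' Classical paired t-test on `x - y` with the direction fixed a priori.
#' Cohen's dz is `mean(x - y) / sd(x - y)`, so the t statistic equals
#' `dz * sqrt(n)` exactly.
#'
#' @param x,y Paired numeric vectors of equal length (pairs with any NA are
#'   dropped); n >= 2 after dropping.
#' @param alternative Direction of the alternative for `mean(x - y)`:
#'   `"greater"`, `"less"`, or `"two.sided"`.
#' @return A `paired_t_result` list: `t`, `df`, `p`, `dz`, `n`, `tail`.
#' @examples
#' paired_t_one_tailed(c(5, 7, 6, 9), c(4, 6, 7, 8), "greater")
#' @export
paired_t_one_tailed <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  keep <- complete.cases(x, y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L) abort("at least 2 complete pairs are required")
  s <- sd(d)
  if (s == 0) abort("the paired differences have zero variance; t is undefined")
  dz <- mean(d) / s
  t <- dz * sqrt(n)
  df <- n - 1L
  p <- switch(alternative,
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df),
              two.sided = 2 * pt(-abs(t), df))
  structure(list(t = t, df = df, p = p, dz = dz, n = n,
                 tail = if (alternative == "two.sided") "two_tailed" else "one_tailed",
                 alternative = alternative),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t-test (%s, %s): t(%d) = %.3f, p = %.4g, dz = %.3f\n",
              x$tail, x$alternative, x$df, x$t, x$p, x$dz))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.paired_t_result <- function(x, ...) {
  tibble(t = x$t, df = x$df, p.value = x$p, dz = x$dz, n = x$n,
         tail = x$tail, alternative = x$alternative)
}

#' Block-wise one-tailed paired tests of baseline-corrected RT
#'
#' For each of Blocks 2-4, tests whether active stimulation speeded
#' responses relative to sham: the paired differences are
#' `delta_sham - delta_active` and the alternative is that their mean is
#' positive (anodal facilitation makes active deltas more negative).
#'
#' @param summaries A [block_medians()] result.
#' @return A tibble with one row per block: `block`, `t`, `df`, `p.value`,
#'   `dz`, `n`.
#' @export
rt_block_tests <- function(summaries) {
  wide <- tidyr::pivot_wider(
    summaries[summaries$block != 1L,
              c("participant_id", "condition", "block", "delta_rt_ms")],
    names_from = "condition", values_from = "delta_rt_ms"
  )
  purrr::map_dfr(sort(unique(wide$block)), function(b) {
    sub <- wide[wide$block == b, , drop = FALSE]
    res <- paired_t_one_tailed(sub$sham, sub$active, "greater")
    tibble(block = b, t = res$t, df = res$df, p.value = res$p,
           dz = res$dz, n = res$n)
  })
}

#' TOST paired equivalence test from an observed dz
#'
#' Two one-sided tests against equivalence bounds expressed as a
#' standardised effect: `t_lower = (dz + bound) * sqrt(n)` tests that the
#' effect exceeds `-bound`, `t_upper = (dz - bound) * sqrt(n)` tests that
#' it falls below `+bound`, each on `n - 1` degrees of freedom.  The TOST
#' p-value is the larger of the two one-sided p-values and equivalence is
#' declared when it is below `alpha`.
#'
#' @param dz Observed Cohen's dz of the paired differences.
#' @param n Number of pairs.
#' @param bound_dz Positive equivalence bound on the dz scale.
#' @param alpha Significance level (default 0.05).
#' @return A `tost_result` list: `dz_observed`, `bound_dz`, `t_lower`,
#'   `t_upper`, `df`, `p_lower`, `p_upper`, `p`, `t` (the statistic of the
#'   binding side), `equivalent`, `alpha`, `n`.
#' @examples
#' tost_from_dz(-0.02, 32, 0.4)  # t = 2.15, p = 0.02
#' @export
tost_from_dz <- function(dz, n, bound_dz, alpha = 0.05) {
  if (bound_dz <= 0) abort("`bound_dz` must be positive")
  if (n < 2) abort("`n` must be at least 2")
  df <- n - 1
  t_lower <- (dz + bound_dz) * sqrt(n)
  t_upper <- (dz - bound_dz) * sqrt(n)
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df)
  p <- max(p_lower, p_upper)
  structure(list(dz_observed = dz, bound_dz = bound_dz,
                 t_lower = t_lower, t_upper = t_upper, df = df,
                 p_lower = p_lower, p_upper = p_upper, p = p,
                 t = if (p_lower >= p_upper) t_lower else t_upper,
                 equivalent = p < alpha, alpha = alpha, n = n),
            class = "tost_result")
}

#' TOST paired equivalence test on raw data
#'
#' Computes the observed dz from the paired differences `x - y` and applies
#' [tost_from_dz()].
#'
#' @inheritParams paired_t_one_tailed
#' @inheritParams tost_from_dz
#' @return A `tost_result`; see [tost_from_dz()].
#' @export
tost_paired <- function(x, y, bound_dz, alpha = 0.05) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  keep <- complete.cases(x, y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L) abort("at least 2 complete pairs are required")
  s <- sd(d)
  if (s == 0) abort("the paired differences have zero variance; TOST is undefined")
  tost_from_dz(mean(d) / s, n, bound_dz, alpha)
}

#' @export
print.tost_result <- function(x, ...) {
  verdict <- if (x$equivalent) "equivalent" else "not equivalent"
  cat(sprintf("TOST (bounds dz = +/-%g): dz = %.3f, t(%d) = %.3f, p = %.4g -> %s at alpha = %g\n",
              x$bound_dz, x$dz_observed, x$df, x$t, x$p, verdict, x$alpha))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tost_result <- function(x, ...) {
  tibble(dz = x$dz_observed, bound_dz = x$bound_dz,
         t_lower = x$t_lower, t_upper = x$t_upper, t = x$t, df = x$df,
         p.value = x$p, equivalent = x$equivalent, n = x$n)
}

#' @exportS3Method generics::glance
glance.tost_result <- function(x, ...) {
  tibble(t = x$t, df = x$df, p.value = x$p, equivalent = x$equivalent)
}

# Bootstrap percentile CI of a mean over participants via multinomial
# resample counts.
boot_mean_ci <- function(x, n_boot, level) {
  n <- length(x)
  W <- rmultinom(n_boot, n, rep.int(1 / n, n))
  means <- as.vector(crossprod(W, x)) / n
  a <- (1 - level) / 2
  q <- quantile(means, c(a, 1 - a), names = FALSE, type = 7)
  list(mean = mean(x), ci_lo = q[1], ci_hi = q[2])
}

#' Group accuracy with a bootstrap confidence interval
#'
#' Per-participant accuracy (percentage of trials answered correctly;
#' trials with no response count as errors), the group mean, and a
#' percentile-bootstrap CI over participants.
#'
#' @param trials A trial tibble (see [read_trials()]).
#' @param n_boot Bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A list with `mean_pct`, `ci_lo`, `ci_hi`, `n_participants`, and
#'   the per-participant tibble `by_participant`.
#' @export
accuracy_summary <- function(trials, n_boot = 5000, level = 0.95, seed = NULL) {
  if (nrow(trials) == 0) abort("`trials` is empty")
  if (!is.null(seed)) set.seed(seed)
  by_p <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id),
    accuracy_pct = 100 * mean(.data$correct),
    .groups = "drop"
  )
  b <- boot_mean_ci(by_p$accuracy_pct, n_boot, level)
  list(mean_pct = b$mean, ci_lo = b$ci_lo, ci_hi = b$ci_hi,
       n_participants = nrow(by_p), by_participant = by_p)
}

#' Sub-block bootstrap time course of median RT
#'
#' The exploratory fine-grained analogue of the block analysis: for each
#' 10-trial sub-block of the in-task blocks, the per-participant median RT
#' of correct trials is bootstrapped across participants into a band per
#' condition, and non-overlapping sub-blocks are merged into windows with
#' the same machinery as the blinding analysis.
#'
#' @inheritParams accuracy_summary
#' @return A list with `bands` (a `subblock_bands` tibble: `condition`,
#'   `subblock`, `time_s`, `n`, `group_median`, `ci_lo`, `ci_hi`,
#'   `flagged`) and `windows` (a [distinct_windows()] object on the
#'   sub-block time grid).
#' @export
subblock_timecourse <- function(trials, n_boot = 5000, level = 0.95, seed = NULL) {
  task <- trials[!is.na(trials$subblock) & trials$correct & !is.na(trials$rt_ms), ,
                 drop = FALSE]
  if (nrow(task) == 0) abort("no usable in-task trials with sub-block labels")
  med <- dplyr::summarise(
    dplyr::group_by(task, .data$participant_id, .data$condition, .data$subblock),
    median_rt_ms = median(.data$rt_ms),
    .groups = "drop"
  )
  bands <- band_by_time(med, "median_rt_ms", "subblock", n_boot, level, seed)
  bands$time_s <- bands$subblock * 30
  bands <- structure(bands, class = c("subblock_bands", class(bands)),
                     n_boot = n_boot, level = level, seed = seed)
  windows <- distinct_windows(bands, time_col = "time_s")
  list(bands = bands, windows = windows)
}
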