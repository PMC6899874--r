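# Core blinding time-course analysis: confidence-weighted detection scores,
# percentile-bootstrap bands of the per-probe group medians, non-overlap
# window detection, and per-participant logistic crossover fits.

#' Confidence-weighted detection score
#'
#' Combines the binary "Is the stimulation on?" answer with the 0-10
#' confidence report into a single signed score: "yes" maps to +1, "no" to
#' -1, multiplied by the confidence.  +10 therefore means high confidence
#' that the stimulation is on, -10 high confidence that it is off, and 0
#' complete uncertainty in either direction.  Missing answers propagate to
#' missing scores (they are never coded as 0, which would mean "answered,
#' maximally unsure").
#'
#' @param answer Character vector of `"yes"`/`"no"` (NA allowed).
#' @param confidence Numeric vector in \[0, 10\] (NA iff `answer` is NA).
#' @return Numeric scores in \[-10, 10\], NA where the answer is missing.
#' @examples
#' weighted_score(c("yes", "no", "no", NA), c(10, 10, 0, NA))
#' @export
weighted_score <- function(answer, confidence) {
  if (length(answer) != length(confidence)) {
    abort("`answer` and `confidence` must have the same length")
  }
  known <- !is.na(answer)
  if (any(!answer[known] %in% c("yes", "no"))) {
    abort("`answer` must be 'yes', 'no' or NA")
  }
  if (any(confidence[known] < 0 | confidence[known] > 10, na.rm = TRUE)) {
    abort("`confidence` must lie in [0, 10]")
  }
  ifelse(is.na(answer), NA_real_,
         ifelse(answer == "yes", 1, -1) * confidence)
}

#' Add weighted scores to a probe table
#'
#' @param probes A probe tibble (see [read_probes()]).
#' @return The same tibble with a `score` column in \[-10, 10\].
#' @export
weighted_scores <- function(probes) {
  probes$score <- weighted_score(probes$answer, probes$confidence)
  probes
}

# All B bootstrap medians of x, drawn with replacement, using multinomial
# resample counts: the median of a resample is read off the sorted sample
# at the positions where the cumulative count reaches the central order
# statistics.  Equivalent in law to resampling x directly, but O(n * B)
# with vectorised arithmetic.
boot_medians <- function(x, n_boot) {
  x <- sort(x)
  n <- length(x)
  W <- rmultinom(n_boot, n, rep.int(1 / n, n))      # n x B counts
  L <- matrix(0, n, n)
  L[lower.tri(L, diag = TRUE)] <- 1
  cum <- L %*% W                                     # cumulative counts
  if (n %% 2L == 0L) {
    klo <- n %/% 2L
    khi <- klo + 1L
  } else {
    klo <- khi <- (n + 1L) %/% 2L
  }
  jlo <- colSums(cum < klo) + 1L
  jhi <- colSums(cum < khi) + 1L
  (x[jlo] + x[jhi]) / 2
}

#' Percentile bootstrap confidence interval for a median
#'
#' Resamples the observations with replacement `n_boot` times, takes the
#' median of each resample, and returns the percentile interval of the
#' bootstrap distribution at the requested level.  The point estimate is
#' the plain sample median.
#'
#' @param x Numeric observations (NAs dropped); at least 2 non-missing
#'   values are required.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @return A list with `median`, `ci_lo`, `ci_hi`, and `n` (non-missing
#'   observations used).
#' @examples
#' set.seed(1)
#' bootstrap_median_ci(rnorm(32), n_boot = 1000)
#' @export
bootstrap_median_ci <- function(x, n_boot = 5000, level = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    abort("at least 2 non-missing observations are required for a bootstrap band")
  }
  if (n_boot < 1) abort("`n_boot` must be a positive integer")
  meds <- boot_medians(x, n_boot)
  a <- (1 - level) / 2
  q <- quantile(meds, c(a, 1 - a), names = FALSE, type = 7)
  list(median = median(x), ci_lo = q[1], ci_hi = q[2], n = length(x))
}

# Shared band machinery: one bootstrap band per (condition, time) cell of a
# long table with columns condition, <time_col>, <value_col>.  One RNG
# stream per condition (seed, seed + 1, ... in condition order), cells
# processed in time order, so results are reproducible bit for bit.
band_by_time <- function(df, value_col, time_col, n_boot, level, seed) {
  conditions <- sort(unique(df$condition))
  out <- purrr::map_dfr(seq_along(conditions), function(ci) {
    cond <- conditions[ci]
    if (!is.null(seed)) set.seed(seed + ci - 1L)
    sub <- df[df$condition == cond, , drop = FALSE]
    times <- sort(unique(sub[[time_col]]))
    purrr::map_dfr(times, function(tm) {
      x <- sub[[value_col]][sub[[time_col]] == tm]
      x <- x[!is.na(x)]
      if (length(x) < 2L) {
        tibble(condition = cond, !!time_col := tm, n = length(x),
               group_median = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               flagged = TRUE)
      } else {
        b <- bootstrap_median_ci(x, n_boot = n_boot, level = level)
        tibble(condition = cond, !!time_col := tm, n = b$n,
               group_median = b$median, ci_lo = b$ci_lo, ci_hi = b$ci_hi,
               flagged = FALSE)
      }
    })
  })
  out
}

#' Bootstrap confidence bands of median weighted scores per probe
#'
#' For each condition and probe time, computes the group median of the
#' confidence-weighted detection scores across participants together with a
#' percentile-bootstrap confidence interval (participants resampled with
#' replacement).  Missing scores shrink that probe's resampling pool; a
#' probe with fewer than 2 non-missing scores is flagged and gets no band.
#'
#' One seeded RNG stream is used per condition (in alphabetical condition
#' order, streams `seed`, `seed + 1`, ...), with probes processed in time
#' order, so a fixed `seed` reproduces the bands bit for bit.
#'
#' @param probes A probe tibble (see [read_probes()]).
#' @param n_boot Bootstrap resamples per probe (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A `blinding_bands` tibble: `condition`, `time_s`, `n`,
#'   `group_median`, `ci_lo`, `ci_hi`, `flagged`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 8), seed = 1)
#' bands <- probe_bands(cohort$probes, n_boot = 200, seed = 1)
#' @export
probe_bands <- function(probes, n_boot = 5000, level = 0.95, seed = NULL) {
  scored <- weighted_scores(probes)
  out <- band_by_time(scored, "score", "time_s", n_boot, level, seed)
  structure(out,
            class = c("blinding_bands", class(out)),
            n_boot = n_boot, level = level, seed = seed)
}

#' Find distinct (non-overlapping) windows between two bands
#'
#' A probe time is *distinct* when the active and sham confidence intervals
#' do not intersect.  Runs of consecutive distinct probes on the grid merge
#' into windows spanning the first to the last probe time of the run, so an
#' isolated distinct probe contributes a zero-length window.  Probes where
#' either band is missing (flagged) are treated as overlapping.
#'
#' @param bands A `blinding_bands` (or similarly shaped) tibble holding
#'   exactly two conditions on a common time grid, or a list/pair of two
#'   single-condition band tibbles.
#' @param time_col Name of the time column (default `"time_s"`).
#' @return A `distinct_windows` object: list with `flags` (per-time
#'   distinctness), `windows` (tibble of `start_s`, `end_s`,
#'   `duration_s`), and `total_distinct_s`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 8), seed = 1)
#' bands <- probe_bands(cohort$probes, n_boot = 200, seed = 1)
#' distinct_windows(bands)
#' @export
distinct_windows <- function(bands, time_col = "time_s") {
  if (is.list(bands) && !is.data.frame(bands) && length(bands) == 2L) {
    bands <- dplyr::bind_rows(bands)
  }
  conditions <- sort(unique(bands$condition))
  if (length(conditions) != 2L) {
    abort("`bands` must contain exactly two conditions")
  }
  a <- bands[bands$condition == conditions[1], , drop = FALSE]
  b <- bands[bands$condition == conditions[2], , drop = FALSE]
  a <- a[order(a[[time_col]]), ]
  b <- b[order(b[[time_col]]), ]
  if (!isTRUE(all.equal(a[[time_col]], b[[time_col]]))) {
    abort("the two conditions must share the same time grid")
  }
  t <- a[[time_col]]
  distinct <- (a$ci_lo > b$ci_hi) | (b$ci_lo > a$ci_hi)
  distinct[is.na(distinct)] <- FALSE
  flags <- tibble(!!time_col := t, distinct = distinct)
  windows <- merge_flag_runs(t, distinct)
  structure(
    list(flags = flags, windows = windows,
         total_distinct_s = sum(windows$duration_s)),
    class = "distinct_windows"
  )
}

# Merge runs of TRUE flags on a regular grid into first-to-last-probe
# windows.  Consecutive means adjacent on the grid (spacing equal to the
# smallest grid step).
merge_flag_runs <- function(t, flag) {
  stopifnot(length(t) == length(flag), !is.unsorted(t))
  if (!any(flag)) {
    return(tibble(start_s = numeric(), end_s = numeric(),
                  duration_s = numeric()))
  }
  step <- if (length(t) > 1L) min(diff(t)) else Inf
  idx <- which(flag)
  new_run <- c(TRUE, diff(t[idx]) > step + 1e-9)
  run_id <- cumsum(new_run)
  starts <- tapply(t[idx], run_id, min)
  ends <- tapply(t[idx], run_id, max)
  tibble(start_s = as.numeric(starts), end_s = as.numeric(ends),
         duration_s = as.numeric(ends) - as.numeric(starts))
}

#' @export
print.distinct_windows <- function(x, ...) {
  cat(sprintf("<distinct_windows> %d window(s), total %g s\n",
              nrow(x$windows), x$total_distinct_s))
  if (nrow(x$windows) > 0) print(x$windows)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.distinct_windows <- function(x, ...) x$windows

#' @exportS3Method generics::glance
glance.distinct_windows <- function(x, ...) {
  tibble(n_windows = nrow(x$windows),
         n_distinct_probes = sum(x$flags$distinct),
         total_distinct_s = x$total_distinct_s)
}

#' Distinct time as a percentage of the stimulation-time difference
#'
#' Expresses the total duration of non-overlapping windows as a percentage
#' of the difference in total current-on time (ramps included) between the
#' active and sham protocols.  With the default protocols the denominator
#' is 660 - 80 = 580 s.
#'
#' @param total_distinct_s Total distinct duration in seconds (>= 0).
#' @param active,sham The two [stim_protocol()]s.
#' @return Percentage in \[0, 100\] (not rounded).
#' @examples
#' percent_of_stim_difference(300)  # 51.72...
#' @export
percent_of_stim_difference <- function(total_distinct_s,
                                       active = active_protocol(),
                                       sham = sham_protocol()) {
  if (total_distinct_s < 0) abort("`total_distinct_s` must be non-negative")
  denom <- total_on_s(active) - total_on_s(sham)
  if (denom <= 0) {
    abort(paste0("the active protocol must deliver more current-on time than sham ",
                 "(difference is ", denom, " s); the percentage is undefined"))
  }
  100 * total_distinct_s / denom
}

#' Per-participant logistic crossover fits
#'
#' For each participant and session, fits a maximum-likelihood binomial
#' logistic regression of the yes/no probe answers on probe time and
#' derives the crossover time at which the fitted "yes" probability is
#' 50%: `-intercept / slope`.  Because individual response sequences are
#' often unsuitable for this model, every fit carries a failure reason:
#'
#' * `degenerate_responses` - all answers identical (perfect separation at
#'   the boundary; no crossover exists),
#' * `nonconvergent` - the IRLS fit did not converge,
#' * `non_monotone` - the slope is indistinguishable from 0 (likelihood
#'   ratio test at `alpha`), as for rapidly alternating answers,
#' * `crossover_out_of_range` - the fitted crossover lies outside the task
#'   window,
#' * `ok` - a usable crossover estimate.
#'
#' The slope test uses the likelihood ratio rather than the Wald statistic
#' because a cleanly separated step response (the best case for this
#' analysis) has an unbounded slope estimate and a useless Wald standard
#' error, while its likelihood ratio against a flat model is decisive.
#'
#' @param probes A probe tibble (see [read_probes()]).
#' @param window Task window in seconds within which a crossover is
#'   considered interpretable (default `c(0, 960)`).
#' @param alpha Significance level of the slope test (default 0.05).
#' @return A `crossover_fits` tibble: `participant_id`, `condition`,
#'   `intercept`, `slope`, `crossover_s`, `converged`, `failure_reason`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 4), seed = 1)
#' fit_crossover(cohort$probes)
#' @export
fit_crossover <- function(probes, window = c(0, 960), alpha = 0.05) {
  groups <- dplyr::group_split(dplyr::group_by(probes, .data$participant_id,
                                               .data$condition))
  out <- purrr::map_dfr(groups, function(g) {
    res <- tibble(participant_id = g$participant_id[1],
                  condition = g$condition[1],
                  intercept = NA_real_, slope = NA_real_,
                  crossover_s = NA_real_, converged = NA,
                  failure_reason = NA_character_)
    ok <- !is.na(g$answer)
    y <- as.integer(g$answer[ok] == "yes")
    t <- g$time_s[ok]
    if (length(y) < 2L) {
      res$failure_reason <- "degenerate_responses"
      return(res)
    }
    if (length(unique(y)) == 1L) {
      res$failure_reason <- "degenerate_responses"
      return(res)
    }
    fit <- suppressWarnings(glm(y ~ t, family = binomial(),
                                control = list(maxit = 100)))
    res$intercept <- unname(coef(fit)[1])
    res$slope <- unname(coef(fit)[2])
    res$converged <- fit$converged
    if (!fit$converged) {
      res$failure_reason <- "nonconvergent"
      return(res)
    }
    lr <- suppressWarnings(anova(fit, test = "Chisq"))
    p_slope <- lr$`Pr(>Chi)`[2]
    if (is.na(p_slope) || p_slope >= alpha || res$slope == 0) {
      res$failure_reason <- "non_monotone"
      return(res)
    }
    cross <- -res$intercept / res$slope
    if (cross < window[1] || cross > window[2]) {
      res$failure_reason <- "crossover_out_of_range"
      return(res)
    }
    res$crossover_s <- cross
    res$failure_reason <- "ok"
    res
  })
  structure(out, class = c("crossover_fits", class(out)))
}

#' @exportS3Method generics::glance
glance.crossover_fits <- function(x, ...) {
  tibble(
    n_fits = nrow(x),
    n_ok = sum(x$failure_reason == "ok"),
    n_degenerate = sum(x$failure_reason == "degenerate_responses"),
    n_non_monotone = sum(x$failure_reason == "non_monotone"),
    n_nonconvergent = sum(x$failure_reason == "nonconvergent"),
    n_out_of_range = sum(x$failure_reason == "crossover_out_of_range"),
    median_crossover_s = median(x$crossover_s, na.rm = TRUE)
  )
}
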