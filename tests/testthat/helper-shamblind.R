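# Shared fixtures, all generated in code.

quick_cfg <- function(n = 8, ...) {
  cohort_config(n_participants = n, ...)
}

# A band tibble pair on the 30-s probe grid whose CIs are disjoint exactly
# at `distinct_at` (times in seconds) and overlapping everywhere else.
bands_with_distinct_at <- function(distinct_at, times = probe_schedule()) {
  make <- function(cond, lo, hi, lo_d, hi_d) {
    d <- times %in% distinct_at
    tibble::tibble(condition = cond, time_s = times,
                   n = 32L,
                   group_median = (ifelse(d, lo_d, lo) + ifelse(d, hi_d, hi)) / 2,
                   ci_lo = ifelse(d, lo_d, lo),
                   ci_hi = ifelse(d, hi_d, hi),
                   flagged = FALSE)
  }
  dplyr::bind_rows(
    make("active", lo = -1, hi = 6, lo_d = 5, hi_d = 6),
    make("sham", lo = -2, hi = 5, lo_d = -6, hi_d = -5)
  )
}

# Independent run-length scanner: an explicit left-to-right loop, used as
# the oracle for window merging.
scan_windows <- function(t, flag) {
  step <- if (length(t) > 1) min(diff(t)) else Inf
  out <- NULL
  start <- NA
  prev_t <- NA
  for (i in seq_along(t)) {
    if (flag[i]) {
      if (is.na(start) || (t[i] - prev_t) > step + 1e-9) {
        if (!is.na(start)) out <- rbind(out, c(start, prev_t))
        start <- t[i]
      }
      prev_t <- t[i]
    } else {
      if (!is.na(start)) {
        out <- rbind(out, c(start, prev_t))
        start <- NA
      }
    }
  }
  if (!is.na(start)) out <- rbind(out, c(start, prev_t))
  if (is.null(out)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  tibble::tibble(start_s = out[, 1], end_s = out[, 2])
}

# Exact Wilcoxon signed-rank p by characteristic-polynomial dynamic
# programming over half-ranks (handles midranks), independent of the
# package's expand.grid enumeration.
exact_wilcoxon_p_dp <- function(d) {
  d <- d[d != 0]
  r2 <- as.integer(round(2 * rank(abs(d))))   # ranks doubled to integers
  W2 <- sum(r2[d > 0])
  total <- sum(r2)
  # distribution of doubled positive-rank sum: convolve (1 + x^r) terms
  probs <- c(1, rep(0, total))
  for (r in r2) {
    shifted <- c(rep(0, r), probs[seq_len(length(probs) - r)])
    probs <- probs + shifted
  }
  probs <- probs / sum(probs)
  support <- 0:total
  mu2 <- total / 2
  sum(probs[abs(support - mu2) >= abs(W2 - mu2) - 1e-9])
}
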