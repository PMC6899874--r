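# Questionnaire statistics and design power: Wilcoxon signed-rank
# side-effect comparisons, the exact binomial guess-rate test, and
# noncentral-t sample-size calculation for paired designs.

#' Wilcoxon signed-rank test for paired ordinal ratings
#'
#' Classical signed-rank test: zero differences are discarded, the absolute
#' differences are ranked with midranks for ties, and the positive-rank sum
#' `W` is compared with its null distribution.  Two p-value methods are
#' available:
#'
#' * `"normal"` - z from the normal approximation with tie-corrected
#'   variance (two-sided); `z` is signed so that positive values mean `x`
#'   tends to exceed `y`.  No continuity correction is applied, matching
#'   the z statistics conventionally reported for this test.
#' * `"exact"` - full enumeration of all `2^m` sign assignments of the
#'   observed (midrank) ranks; the two-sided p is the probability of a
#'   |W - E(W)| at least as large as observed.  Available for m <= 16.
#'
#' `"auto"` uses the exact enumeration when m <= 16 and the normal
#' approximation otherwise.  Note the approximation is coarse for small m,
#' especially with heavy ties.
#'
#' @param x,y Paired numeric (typically ordinal 1-5) vectors.
#' @param method `"auto"`, `"normal"`, or `"exact"`.
#' @return A `wilcoxon_result` list: `statistic` (positive-rank sum `W`),
#'   `z`, `p`, `n_effective` (pairs after zero removal), `method`,
#'   `undefined` (TRUE when all differences are zero).
#' @examples
#' wilcoxon_signed_rank(c(3, 4, 2, 5, 4, 3, 2), c(2, 2, 2, 3, 4, 1, 1))
#' @export
wilcoxon_signed_rank <- function(x, y, method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  keep <- complete.cases(x, y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    return(structure(list(statistic = NA_real_, z = NA_real_, p = NA_real_,
                          n_effective = 0L, method = method, undefined = TRUE),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  tie_tab <- table(r)
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  if (method == "auto") method <- if (m <= 16L) "exact" else "normal"
  p <- if (method == "normal") {
    2 * pnorm(-abs(z))
  } else {
    if (m > 16L) abort("exact enumeration is limited to 16 effective pairs")
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    W_all <- as.vector(signs %*% r)
    mean(abs(W_all - mu) >= abs(W - mu) - 1e-9)
  }
  structure(list(statistic = W, z = z, p = min(p, 1), n_effective = m,
                 method = method, undefined = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$undefined) {
    cat("Wilcoxon signed-rank: undefined (all differences zero)\n")
  } else {
    cat(sprintf("Wilcoxon signed-rank (%s): W = %g, z = %.3f, p = %.4g (m = %d)\n",
                x$method, x$statistic, x$z, x$p, x$n_effective))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wilcoxon_result <- function(x, ...) {
  tibble(statistic = x$statistic, z = x$z, p.value = x$p,
         n_effective = x$n_effective, method = x$method,
         undefined = x$undefined)
}

#' Side-effect comparisons between active and sham sessions
#'
#' One Wilcoxon signed-rank test per sensory scale (headache, tingling,
#' itching, burning, pain) comparing the active-session rating against the
#' sham-session rating of the same participant.  No correction for the
#' five comparisons is applied; report accordingly.
#'
#' @param ratings A ratings tibble (see [read_ratings()]).
#' @param method Passed to [wilcoxon_signed_rank()]; the default `"normal"`
#'   mirrors the z statistics conventionally reported for these
#'   questionnaires.
#' @return A tibble with one row per scale: `scale`, `z`, `p.value`,
#'   `n_effective`, `undefined`.
#' @export
side_effect_tests <- function(ratings, method = "normal") {
  scales <- c("headache", "tingling", "itching", "burning", "pain")
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(ratings, dplyr::all_of(scales),
                        names_to = "scale", values_to = "rating"),
    names_from = "condition", values_from = "rating"
  )
  purrr::map_dfr(scales, function(sc) {
    sub <- wide[wide$scale == sc, , drop = FALSE]
    res <- wilcoxon_signed_rank(sub$active, sub$sham, method = method)
    tibble(scale = sc, z = res$z, p.value = res$p,
           n_effective = res$n_effective, undefined = res$undefined)
  })
}

#' Sham guess accuracy test
#'
#' Proportion of participants correctly guessing which session involved
#' sham, with an exact one-sided binomial test against chance (0.5),
#' "above chance" being the directional hypothesis.
#'
#' @param guesses A guesses tibble (see [read_guesses()]).
#' @return A `guess_test` list: `n_correct`, `n_total`, `percent`,
#'   `p_binomial`.
#' @examples
#' g <- tibble::tibble(participant_id = sprintf("P%02d", 1:32),
#'                     guessed_sham_session = "session1",
#'                     correct = rep(c(TRUE, FALSE), c(25, 7)),
#'                     confidence = 5)
#' guess_accuracy_test(g)
#' @export
guess_accuracy_test <- function(guesses) {
  n <- nrow(guesses)
  if (n < 1) abort("`guesses` is empty")
  k <- sum(guesses$correct)
  structure(list(
    n_correct = k, n_total = n, percent = 100 * k / n,
    p_binomial = binom.test(k, n, p = 0.5, alternative = "greater")$p.value
  ), class = "guess_test")
}

#' @export
print.guess_test <- function(x, ...) {
  cat(sprintf("Sham guesses: %d/%d correct (%.1f%%), one-sided binomial p vs 0.5 = %.4g\n",
              x$n_correct, x$n_total, x$percent, x$p_binomial))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.guess_test <- function(x, ...) {
  tibble(n_correct = x$n_correct, n_total = x$n_total,
         percent = x$percent, p.value = x$p_binomial)
}

#' Power of a paired t-test (noncentral t)
#'
#' Power to detect a standardised paired effect `d` with `n` pairs, using
#' the noncentral t distribution with noncentrality `d * sqrt(n)`.
#'
#' @param d Standardised effect size (Cohen's dz), > 0.
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @return Power in \[0, 1\].
#' @examples
#' paired_t_power(0.45, 32)  # just above 0.80
#' @export
paired_t_power <- function(d, n, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (d <= 0) abort("`d` must be positive")
  if (n < 2) abort("`n` must be at least 2")
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == "one") {
    pt(qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
}

#' Required sample size for a paired t-test
#'
#' Smallest number of pairs whose noncentral-t power at effect `d` reaches
#' the target.
#'
#' @inheritParams paired_t_power
#' @param power Target power in (0, 1).
#' @param n_max Search ceiling (an error is raised if the target is not
#'   reached by `n_max`).
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.45, 0.05, 0.8, "one")  # 32
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.8,
                                 tails = c("one", "two"), n_max = 1e6) {
  tails <- match.arg(tails)
  if (d <= 0) abort("`d` must be positive")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (power <= 0 || power >= 1) abort("`power` must lie in (0, 1)")
  n <- 2
  while (n <= n_max) {
    if (paired_t_power(d, n, alpha, tails) >= power) return(as.integer(n))
    n <- n + 1
  }
  abort(sprintf("target power %g not reached by n = %g", power, n_max))
}
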