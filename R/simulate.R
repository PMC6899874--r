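# Synthetic-cohort generator: a minimal perceptual and reaction-time model
# of a two-session, counterbalanced, within-subject tDCS crossover, rich
# enough that every analysis stage in the package runs on its output.

#' Generator configuration
#'
#' Parameters of the synthetic cohort.  The defaults emulate the standard
#' design this package analyses: 32 participants, two sessions (active:
#' 30 s ramp-up + 600 s at 1 mA + 30 s ramp-down; sham: 30 s + 20 s + 30 s),
#' 32 detection probes at 30-s intervals, and 100 baseline plus 320 in-task
#' forced-choice trials per session.
#'
#' The perceptual model is deliberately minimal.  A latent salience
#' \eqn{s(t)} is 1 during the ramp-up, decays exponentially with half-life
#' `desensitization_halflife_s` during the plateau (scalp desensitisation),
#' holds its plateau-end level through the ramp-down (desensitisation does
#' not reset while the current falls), and then collapses to 0 within
#' `persistence_s` with a cubic fade: the lingering sensation stays almost
#' fully salient shortly after the current stops and then vanishes quickly,
#' which is what makes the probe just after sham ramp-down still read "on"
#' while the next one reads "off".  The probability of answering "yes" to "Is the stimulation
#' on?" is `p_off + (p_on - p_off) * s(t)`; confidence is a truncated
#' normal on \[0, 10\] centred on `confidence_on_mean` ("yes") or
#' `confidence_off_mean` ("no").
#'
#' Reaction times are log-normal with a participant random intercept on the
#' log scale, a linear practice trend over the eight blocks a participant
#' performs across both sessions, and an additive anodal facilitation applied
#' to active Blocks 2-3.  The facilitation is calibrated so that `anodal_dz`
#' is the true standardised effect (Cohen's dz) of the paired
#' active-vs-sham contrast of baseline-corrected Block-3 median reaction
#' times; see [anodal_shift_ms()].
#'
#' @param n_participants Number of participants (default 32).
#' @param active,sham The two [stim_protocol()]s.
#' @param p_on Probability of "yes" while the current is on and fully
#'   salient, in (0.5, 1].
#' @param p_off Probability of "yes" when the current is off and no
#'   sensation lingers, in \[0, 0.5).
#' @param desensitization_halflife_s Half-life (s) of salience decay during
#'   a sustained plateau.
#' @param persistence_s Seconds over which the lingering sensation fades
#'   after ramp-down.
#' @param confidence_on_mean,confidence_off_mean,confidence_sd Truncated
#'   normal parameters of the 0-10 confidence report.
#' @param confidence_participant_sd SD of a per-participant offset added to
#'   both confidence means (raters anchor the 0-10 scale differently).
#' @param p_probe_missing Probability that a probe response lapses (the
#'   on-screen response window passes unanswered).
#' @param rt_median_ms,rt_sigma_log Median and log-scale SD of the
#'   within-participant reaction-time distribution.
#' @param participant_sd_log SD of the participant random intercept on the
#'   log-RT scale.
#' @param practice_slope_ms_per_block Additive practice trend (ms per block
#'   position across both sessions; non-positive).
#' @param anodal_dz True standardised effect of active stimulation on
#'   baseline-corrected Block-3 median RT (0 = null).
#' @param anodal_sd_ms Between-participant SD (ms) of the anodal
#'   facilitation.
#' @param accuracy_p Probability that a trial is answered correctly.
#' @param p_no_response Probability that a trial gets no response before the
#'   deadline (counted as an error; its RT is missing).
#' @param ratings_base_probs Baseline probabilities of ratings 1..5 on each
#'   side-effect scale.
#' @param ratings_shift_itching Integer shift (capped at 5) applied to the
#'   itching rating in the active session.
#' @param guess_informed_p Probability that the end-of-study sham guess is
#'   correct (0.5 = fully blinded).
#' @param seed Optional default seed echoed into [simulate_cohort()].
#' @return A `cohort_config` object (named list).
#' @examples
#' cfg <- cohort_config(n_participants = 4)
#' cohort <- simulate_cohort(cfg, seed = 1)
#' @export
cohort_config <- function(n_participants = 32,
                          active = active_protocol(),
                          sham = sham_protocol(),
                          p_on = 0.95,
                          p_off = 0.05,
                          desensitization_halflife_s = 300,
                          persistence_s = 30,
                          confidence_on_mean = 8,
                          confidence_off_mean = 7,
                          confidence_sd = 1.5,
                          confidence_participant_sd = 1.5,
                          p_probe_missing = 0.01,
                          rt_median_ms = 430,
                          rt_sigma_log = 0.18,
                          participant_sd_log = 0.13,
                          practice_slope_ms_per_block = -2,
                          anodal_dz = 0,
                          anodal_sd_ms = 35,
                          accuracy_p = 0.956,
                          p_no_response = 0.005,
                          ratings_base_probs = c(0.45, 0.30, 0.15, 0.07, 0.03),
                          ratings_shift_itching = 1,
                          guess_informed_p = 25 / 32,
                          seed = NULL) {
  stopifnot(inherits(active, "stim_protocol"), inherits(sham, "stim_protocol"))
  if (!(p_on > 0.5 && p_on <= 1)) abort("`p_on` must lie in (0.5, 1]")
  if (!(p_off >= 0 && p_off < 0.5)) abort("`p_off` must lie in [0, 0.5)")
  if (p_on <= p_off) abort("`p_on` must exceed `p_off`")
  for (m in c(confidence_on_mean, confidence_off_mean)) {
    if (m < 0 || m > 10) abort("confidence means must lie in [0, 10]")
  }
  if (accuracy_p <= 0 || accuracy_p > 1) abort("`accuracy_p` must lie in (0, 1]")
  if (accuracy_p + p_no_response > 1) {
    abort("`accuracy_p` + `p_no_response` must not exceed 1")
  }
  if (practice_slope_ms_per_block > 0) {
    abort("`practice_slope_ms_per_block` must be <= 0")
  }
  if (guess_informed_p < 0.5 || guess_informed_p > 1) {
    abort("`guess_informed_p` must lie in [0.5, 1]")
  }
  if (abs(sum(ratings_base_probs) - 1) > 1e-8 || length(ratings_base_probs) != 5) {
    abort("`ratings_base_probs` must be 5 probabilities summing to 1")
  }
  structure(
    list(n_participants = n_participants, active = active, sham = sham,
         p_on = p_on, p_off = p_off,
         desensitization_halflife_s = desensitization_halflife_s,
         persistence_s = persistence_s,
         confidence_on_mean = confidence_on_mean,
         confidence_off_mean = confidence_off_mean,
         confidence_sd = confidence_sd,
         confidence_participant_sd = confidence_participant_sd,
         p_probe_missing = p_probe_missing,
         rt_median_ms = rt_median_ms, rt_sigma_log = rt_sigma_log,
         participant_sd_log = participant_sd_log,
         practice_slope_ms_per_block = practice_slope_ms_per_block,
         anodal_dz = anodal_dz, anodal_sd_ms = anodal_sd_ms,
         accuracy_p = accuracy_p, p_no_response = p_no_response,
         ratings_base_probs = ratings_base_probs,
         ratings_shift_itching = ratings_shift_itching,
         guess_informed_p = guess_informed_p,
         n_baseline_trials = 100, n_task_trials = 320,
         trials_per_subblock = 10,
         task_total_s = 960, probe_interval_s = 30,
         seed = seed),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d participants, anodal_dz = %g, p_on/p_off = %g/%g\n",
              x$n_participants, x$anodal_dz, x$p_on, x$p_off))
  invisible(x)
}

protocol_for <- function(cfg, condition) {
  if (condition == "active") cfg$active else cfg$sham
}

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

# Counterbalancing: odd-indexed participants receive active in session 1.
active_first <- function(i) (i %% 2L) == 1L

#' Detection probability over the session
#'
#' Probability of answering "yes" to "Is the stimulation on?" at time `t`
#' under the generator's salience model: `p_off + (p_on - p_off) * s(t)`,
#' with salience 1 during the ramp-up, exponential decay (half-life
#' `desensitization_halflife_s`) during the plateau, the plateau-end level
#' held through the ramp-down, and a cubic collapse to 0 within
#' `persistence_s` afterwards.  Salience is therefore monotone
#' non-increasing from ramp-down onset.
#'
#' @param t Seconds since ramp-up onset (vectorised, non-negative).
#' @param protocol A [stim_protocol()].
#' @param cfg A [cohort_config()].
#' @return Detection probabilities in `[p_off, p_on]`.
#' @examples
#' cfg <- cohort_config()
#' detection_probability(c(15, 120, 400), sham_protocol(), cfg)
#' @export
detection_probability <- function(t, protocol, cfg) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(cfg, "cohort_config"))
  if (any(t < 0)) abort("`t` must be non-negative")
  up <- protocol$ramp_up_s
  pl <- protocol$plateau_s
  end <- up + pl + protocol$ramp_down_s
  s <- numeric(length(t))
  s[t <= up] <- 1
  in_pl <- t > up & t <= up + pl
  s[in_pl] <- 2^(-(t[in_pl] - up) / cfg$desensitization_halflife_s)
  # desensitisation does not reset while the current falls: the ramp-down
  # holds the plateau-end salience.  The lingering sensation then holds
  # almost fully before collapsing within the persistence window (cubic
  # fade), mirroring the sharp rise in "off" confidence once the sensation
  # is gone.
  s_end <- 2^(-pl / cfg$desensitization_halflife_s)
  s[t > up + pl & t <= end] <- s_end
  post <- t > end
  if (cfg$persistence_s > 0) {
    u <- (t[post] - end) / cfg$persistence_s
    s[post] <- s_end * pmax(0, 1 - pmin(u, 1)^3)
  } else {
    s[post] <- 0
  }
  cfg$p_off + (cfg$p_on - cfg$p_off) * s
}

# Truncated-normal sampler on [lo, hi] via inverse CDF; sd = 0 collapses to
# the (clamped) mean.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(pmin(hi, pmax(lo, rep(mean, n))))
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  qnorm(plo + runif(n) * (phi - plo)) * sd + mean
}

# As rtrunc_norm but with a per-draw mean vector.
rtrunc_norm_vec <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(pmin(hi, pmax(lo, mean)))
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  qnorm(plo + runif(n) * (phi - plo)) * sd + mean
}

#' Simulate probe responses
#'
#' One row per participant, session and probe: a yes/no answer drawn from
#' [detection_probability()] and a confidence report on \[0, 10\].  A small
#' fraction of probes lapse (both fields missing), mimicking the response
#' window passing unanswered.
#'
#' @param cfg A [cohort_config()].
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return A tibble of probe responses (see [read_probes()] for the schema).
#' @export
simulate_probes <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- probe_schedule(cfg$task_total_s, cfg$probe_interval_s)
  n <- cfg$n_participants
  grid <- tidyr::expand_grid(
    participant_id = participant_ids(n),
    condition = c("active", "sham"),
    probe_index = seq_along(times)
  )
  grid$time_s <- times[grid$probe_index]
  p_yes <- ifelse(grid$condition == "active",
                  detection_probability(grid$time_s, cfg$active, cfg),
                  detection_probability(grid$time_s, cfg$sham, cfg))
  m <- nrow(grid)
  offset <- rnorm(n, 0, cfg$confidence_participant_sd)
  grid_offset <- offset[match(grid$participant_id, participant_ids(n))]
  lapse <- runif(m) < cfg$p_probe_missing
  yes <- runif(m) < p_yes
  conf_mean <- ifelse(yes, cfg$confidence_on_mean, cfg$confidence_off_mean) +
    grid_offset
  conf <- rtrunc_norm_vec(m, conf_mean, cfg$confidence_sd, 0, 10)
  grid$answer <- ifelse(lapse, NA_character_, ifelse(yes, "yes", "no"))
  grid$confidence <- ifelse(lapse, NA_real_, conf)
  as_tibble(grid)
}

block_of_subblock <- function(sb) {
  dplyr::case_when(sb <= 11 ~ 2L, sb <= 22 ~ 3L, TRUE ~ 4L)
}

#' Calibrated anodal facilitation
#'
#' Mean additive speed-up (ms) applied to active Blocks 2-3 so that the
#' true standardised paired effect on baseline-corrected Block-3 median RTs
#' equals `anodal_dz`.  The standardiser is the SD of the paired contrast,
#' composed of the between-participant facilitation SD (`anodal_sd_ms`) and
#' the sampling noise of the four per-block medians entering the contrast.
#' The median-noise variance uses the asymptotic formula
#' \eqn{\pi \sigma^2 m^2 / (2n)} for a log-normal sample median, with the
#' participant-intercept inflation of \eqn{m^2} and the expected number of
#' analysable (correct) trials per block.
#'
#' @param cfg A [cohort_config()].
#' @return List with `shift_ms` (mean facilitation) and `sd_contrast_ms`
#'   (SD of the paired Block-3 contrast implied by the configuration).
#' @export
anodal_shift_ms <- function(cfg) {
  m2 <- cfg$rt_median_ms^2 * exp(2 * cfg$participant_sd_log^2)
  med_var <- function(n_trials) {
    n_eff <- n_trials * cfg$accuracy_p
    pi * cfg$rt_sigma_log^2 * m2 / (2 * n_eff)
  }
  n_b3 <- 11 * cfg$trials_per_subblock   # sub-blocks 12..22
  var_contrast <- cfg$anodal_sd_ms^2 +
    2 * (med_var(n_b3) + med_var(cfg$n_baseline_trials))
  sdc <- sqrt(var_contrast)
  list(shift_ms = cfg$anodal_dz * sdc, sd_contrast_ms = sdc)
}

#' Simulate reaction-time trials
#'
#' One row per forced-choice trial: 100 baseline trials (Block 1) then 320
#' in-task trials in 32 sub-blocks of 10 (Blocks 2-4), per participant and
#' session.  RTs are log-normal with a participant intercept, a practice
#' trend over block positions across both sessions, and the calibrated
#' anodal facilitation in active Blocks 2-3 (see [anodal_shift_ms()]).
#'
#' @inheritParams simulate_probes
#' @return A tibble of trials (see [read_trials()] for the schema).
#' @export
simulate_trials <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_participants
  ids <- participant_ids(n)
  b_i <- rnorm(n, 0, cfg$participant_sd_log)
  shift <- anodal_shift_ms(cfg)
  a_i <- rnorm(n, shift$shift_ms, cfg$anodal_sd_ms)

  n_trials <- cfg$n_baseline_trials + cfg$n_task_trials
  per_session <- tibble(
    trial = seq_len(n_trials),
    subblock = c(rep(NA_integer_, cfg$n_baseline_trials),
                 (seq_len(cfg$n_task_trials) - 1L) %/% cfg$trials_per_subblock + 1L)
  )
  per_session$block <- ifelse(is.na(per_session$subblock), 1L,
                              block_of_subblock(per_session$subblock))

  grid <- tidyr::expand_grid(
    participant_idx = seq_len(n),
    condition = c("active", "sham"),
    per_session
  )
  grid$participant_id <- ids[grid$participant_idx]
  first <- active_first(grid$participant_idx)
  grid$session <- ifelse((grid$condition == "active") == first, 1L, 2L)
  block_pos <- (grid$session - 1L) * 4L + grid$block

  m <- nrow(grid)
  base_rt <- exp(log(cfg$rt_median_ms) + b_i[grid$participant_idx] +
                   cfg$rt_sigma_log * rnorm(m))
  rt <- base_rt + cfg$practice_slope_ms_per_block * (block_pos - 1L)
  stim_on_block <- grid$condition == "active" & grid$block %in% c(2L, 3L)
  rt <- rt - ifelse(stim_on_block, a_i[grid$participant_idx], 0)
  rt <- pmax(rt, 1)

  stimulus <- ifelse(runif(m) < 0.5, "diamond", "square")
  u <- runif(m)
  outcome <- ifelse(u < cfg$accuracy_p, "correct",
                    ifelse(u < cfg$accuracy_p + cfg$p_no_response, "none", "wrong"))
  correct_resp <- ifelse(stimulus == "diamond", "left", "right")
  wrong_resp <- ifelse(stimulus == "diamond", "right", "left")
  response <- dplyr::case_when(
    outcome == "correct" ~ correct_resp,
    outcome == "wrong" ~ wrong_resp,
    TRUE ~ "none"
  )
  tibble(
    participant_id = grid$participant_id,
    condition = grid$condition,
    block = grid$block,
    subblock = grid$subblock,
    stimulus = stimulus,
    response = response,
    correct = outcome == "correct",
    rt_ms = ifelse(outcome == "none", NA_real_, rt)
  )
}

#' Simulate side-effect ratings
#'
#' Ordinal 1-5 ratings of headache, tingling, itching, burning and pain per
#' participant and session, drawn from `ratings_base_probs`, with the
#' itching rating in the active session shifted up by
#' `ratings_shift_itching` (capped at 5).
#'
#' @inheritParams simulate_probes
#' @return A tibble of ratings (see [read_ratings()] for the schema).
#' @export
simulate_ratings <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_participants
  grid <- tidyr::expand_grid(participant_id = participant_ids(n),
                             condition = c("active", "sham"))
  m <- nrow(grid)
  draw <- function() sample.int(5L, m, replace = TRUE, prob = cfg$ratings_base_probs)
  grid$headache <- draw()
  grid$tingling <- draw()
  itch <- draw()
  shift <- ifelse(grid$condition == "active", cfg$ratings_shift_itching, 0L)
  grid$itching <- pmin(5L, itch + as.integer(shift))
  grid$burning <- draw()
  grid$pain <- draw()
  as_tibble(grid)
}

#' Simulate end-of-study sham guesses
#'
#' Each participant guesses which session involved sham; the guess is
#' correct with probability `guess_informed_p` and carries a 1-10
#' confidence.
#'
#' @inheritParams simulate_probes
#' @return A tibble of guesses (see [read_guesses()] for the schema).
#' @export
simulate_guesses <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_participants
  idx <- seq_len(n)
  sham_session <- ifelse(active_first(idx), "session2", "session1")
  other <- ifelse(sham_session == "session1", "session2", "session1")
  correct <- runif(n) < cfg$guess_informed_p
  tibble(
    participant_id = participant_ids(n),
    guessed_sham_session = ifelse(correct, sham_session, other),
    correct = correct,
    confidence = rtrunc_norm(n, 7, 2, 1, 10)
  )
}

#' Simulate a complete synthetic cohort
#'
#' Generates the four linked tables (probes, trials, ratings, guesses) for a
#' counterbalanced two-session crossover.  With a fixed seed the output is
#' bit-reproducible.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed (defaults to `cfg$seed`, or 1).
#' @return A `sham_cohort` object: a list with elements `probes`, `trials`,
#'   `ratings`, `guesses`, plus the generating `config` and `seed`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 4), seed = 7)
#' dplyr::count(cohort$probes, condition)
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  seed <- seed %||% cfg$seed %||% 1L
  set.seed(seed)
  out <- list(
    probes = simulate_probes(cfg),
    trials = simulate_trials(cfg),
    ratings = simulate_ratings(cfg),
    guesses = simulate_guesses(cfg),
    config = cfg,
    seed = seed
  )
  class(out) <- "sham_cohort"
  out
}

#' @export
print.sham_cohort <- function(x, ...) {
  cat(sprintf("<sham_cohort> %d participants (seed %s): %d probes, %d trials, %d ratings, %d guesses\n",
              x$config$n_participants, format(x$seed), nrow(x$probes),
              nrow(x$trials), nrow(x$ratings), nrow(x$guesses)))
  invisible(x)
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `probes.csv`, `trials.csv`, `ratings.csv`, `guesses.csv` and a
#' `config.yaml` echo (protocol parameters and seed) to `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sham_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_probes(cohort$probes, file.path(dir, "probes.csv"))
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  write_ratings(cohort$ratings, file.path(dir, "ratings.csv"))
  write_guesses(cohort$guesses, file.path(dir, "guesses.csv"))
  cfg <- cohort$config
  echo <- list(
    n_participants = cfg$n_participants,
    active = cfg$active[c("ramp_up_s", "plateau_s", "ramp_down_s", "intensity_mA")],
    sham = cfg$sham[c("ramp_up_s", "plateau_s", "ramp_down_s", "intensity_mA")],
    seed = cohort$seed
  )
  yaml::write_yaml(echo, file.path(dir, "config.yaml"))
  invisible(dir)
}
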