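# One reproducible run: simulate (or read), blinding time course, reaction
# times, questionnaire outcomes, consolidated report.

#' Run configuration
#'
#' Bundles everything one end-to-end run needs: either a synthetic-cohort
#' generator configuration or paths to the four input CSVs, the protocol
#' timing, bootstrap settings, test levels, and an optional output
#' directory.
#'
#' @param generator A [cohort_config()], a list of arguments for it, or
#'   `NULL` when reading data from `inputs`.
#' @param inputs A named list of paths (`probes`, `trials`, `ratings`,
#'   `guesses`), or `NULL` when simulating.
#' @param active,sham The [stim_protocol()]s used for the
#'   percentage-of-difference denominator (and, when simulating, the
#'   generator; a `generator` that carries its own protocols wins).
#' @param n_boot,level Bootstrap settings for all bands and CIs.
#' @param seed Integer seed governing simulation and every bootstrap.
#' @param alpha Significance level for tests.
#' @param tost_bound_dz Equivalence bound (dz) of the baseline TOST.
#' @param out_dir Optional directory for per-stage CSV/JSON outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = list(), inputs = NULL,
                       active = active_protocol(), sham = sham_protocol(),
                       n_boot = 5000, level = 0.95, seed = 1,
                       alpha = 0.05, tost_bound_dz = 0.4, out_dir = NULL) {
  if (is.null(generator) && is.null(inputs)) {
    abort("supply either `generator` (to simulate) or `inputs` (to read CSVs)")
  }
  if (!is.null(inputs)) {
    needed <- c("probes", "trials", "ratings", "guesses")
    if (!all(needed %in% names(inputs))) {
      abort(paste("`inputs` must name paths:", paste(needed, collapse = ", ")))
    }
  }
  structure(list(generator = generator, inputs = inputs,
                 active = active, sham = sham,
                 n_boot = n_boot, level = level, seed = seed,
                 alpha = alpha, tost_bound_dz = tost_bound_dz,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML (or JSON) file
#'
#' Recognised keys mirror the arguments of [run_config()]; `active` and
#' `sham` may be given as mappings with `ramp_up_s`, `plateau_s`,
#' `ramp_down_s`, `intensity_mA`.
#'
#' @param path Path to a YAML or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_protocol <- function(x, label, default) {
    if (is.null(x)) return(default)
    stim_protocol(label,
                  ramp_up_s = x$ramp_up_s %||% 30,
                  plateau_s = x$plateau_s %||% default$plateau_s,
                  ramp_down_s = x$ramp_down_s %||% 30,
                  intensity_mA = x$intensity_mA %||% 1)
  }
  run_config(
    generator = raw$generator %||% (if (is.null(raw$inputs)) list() else NULL),
    inputs = raw$inputs,
    active = as_protocol(raw$active, "active", active_protocol()),
    sham = as_protocol(raw$sham, "sham", sham_protocol()),
    n_boot = raw$n_boot %||% 5000,
    level = raw$level %||% 0.95,
    seed = raw$seed %||% 1,
    alpha = raw$alpha %||% 0.05,
    tost_bound_dz = raw$tost_bound_dz %||% 0.4,
    out_dir = raw$out_dir
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> blinding time course -> reaction times ->
#' questionnaire outcomes, and consolidates the results.  With a fixed
#' configuration and seed the report (and any files written to `out_dir`)
#' is byte-identical across runs.
#'
#' @param config A [run_config()], a path to a YAML/JSON configuration, or
#'   a list of [run_config()] arguments.
#' @return A `sham_report` list with sections `meta` (seed, settings,
#'   configuration hash), `blinding` (bands, windows, total distinct time,
#'   percentage of the stimulation-time difference, crossover fits),
#'   `rt` (block tests, baseline TOST, accuracy, sub-block windows), and
#'   `outcomes` (side-effect tests, guess test).
#' @examples
#' report <- run_pipeline(run_config(
#'   generator = list(n_participants = 8), n_boot = 200, seed = 1))
#' report$blinding$percent_of_difference
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)

  data <- stage("load", {
    if (!is.null(config$inputs)) {
      list(probes = read_probes(config$inputs$probes),
           trials = read_trials(config$inputs$trials),
           ratings = read_ratings(config$inputs$ratings),
           guesses = read_guesses(config$inputs$guesses))
    } else {
      gen <- config$generator
      cfg <- if (inherits(gen, "cohort_config")) gen else {
        args <- gen
        args$active <- args$active %||% config$active
        args$sham <- args$sham %||% config$sham
        do.call(cohort_config, args)
      }
      cohort <- simulate_cohort(cfg, seed = config$seed)
      cohort[c("probes", "trials", "ratings", "guesses")]
    }
  })
  n_missing_probes <- sum(is.na(data$probes$answer))
  rlang::inform(sprintf("[load] %d probes (%d missing answers), %d trials",
                        nrow(data$probes), n_missing_probes, nrow(data$trials)))

  blinding <- stage("blinding", {
    bands <- probe_bands(data$probes, n_boot = config$n_boot,
                         level = config$level, seed = config$seed)
    win <- distinct_windows(bands)
    pct <- percent_of_stim_difference(win$total_distinct_s,
                                      config$active, config$sham)
    cross <- fit_crossover(data$probes, alpha = config$alpha)
    list(bands = bands, windows = win,
         total_distinct_s = win$total_distinct_s,
         percent_of_difference = pct, crossover = cross)
  })
  rlang::inform(sprintf("[blinding] %d distinct window(s), total %g s (%.1f%% of stim-time difference)",
                        nrow(blinding$windows$windows), blinding$total_distinct_s,
                        blinding$percent_of_difference))

  rt <- stage("rt", {
    summaries <- block_medians(data$trials)
    tests <- rt_block_tests(summaries)
    base <- tidyr::pivot_wider(
      summaries[summaries$block == 1L,
                c("participant_id", "condition", "median_rt_ms")],
      names_from = "condition", values_from = "median_rt_ms")
    tost <- tost_paired(base$active, base$sham,
                        bound_dz = config$tost_bound_dz, alpha = config$alpha)
    set.seed(config$seed)
    acc <- accuracy_summary(data$trials, n_boot = config$n_boot,
                            level = config$level)
    sub <- subblock_timecourse(data$trials, n_boot = config$n_boot,
                               level = config$level, seed = config$seed)
    list(block_summaries = summaries, block_tests = tests,
         baseline_tost = tost, accuracy = acc, subblock = sub)
  })
  rlang::inform(sprintf("[rt] accuracy %.1f%% [%.2f, %.2f]; baseline TOST p = %.3g",
                        rt$accuracy$mean_pct, rt$accuracy$ci_lo,
                        rt$accuracy$ci_hi, rt$baseline_tost$p))

  outcomes <- stage("outcomes", {
    list(side_effects = side_effect_tests(data$ratings),
         guesses = guess_accuracy_test(data$guesses))
  })
  rlang::inform(sprintf("[outcomes] guess accuracy %.1f%% (%d/%d)",
                        outcomes$guesses$percent, outcomes$guesses$n_correct,
                        outcomes$guesses$n_total))

  report <- structure(list(
    meta = list(seed = config$seed, n_boot = config$n_boot,
                level = config$level, alpha = config$alpha,
                tost_bound_dz = config$tost_bound_dz,
                config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])),
    blinding = blinding, rt = rt, outcomes = outcomes
  ), class = "sham_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.sham_report <- function(x, ...) {
  cat("== Sham-blinding analysis report ==\n")
  cat(sprintf("seed %s, %d bootstrap resamples, level %.2f\n",
              format(x$meta$seed), x$meta$n_boot, x$meta$level))
  w <- x$blinding$windows$windows
  cat(sprintf("\nDistinct windows (%d): total %g s = %.1f min, %.1f%% of the stimulation-time difference\n",
              nrow(w), x$blinding$total_distinct_s,
              x$blinding$total_distinct_s / 60, x$blinding$percent_of_difference))
  if (nrow(w) > 0) {
    for (i in seq_len(nrow(w))) {
      cat(sprintf("  %g-%g s\n", w$start_s[i], w$end_s[i]))
    }
  }
  cat("\nDelta-RT one-tailed paired tests (sham - active, H1: > 0):\n")
  print(x$rt$block_tests)
  cat("\nBaseline equivalence: ")
  print(x$rt$baseline_tost)
  cat(sprintf("\nAccuracy: %.1f%% [%.2f, %.2f]\n", x$rt$accuracy$mean_pct,
              x$rt$accuracy$ci_lo, x$rt$accuracy$ci_hi))
  cat("\nSide effects (Wilcoxon signed-rank):\n")
  print(x$outcomes$side_effects)
  cat("\n")
  print(x$outcomes$guesses)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes `bands.csv`, `windows.csv`, `crossover.csv`,
#' `block_summaries.csv`, `subblock_bands.csv` and a consolidated
#' `report.json` (full precision; numbers are rounded only at
#' presentation).
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sham_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(report$blinding$bands), file.path(dir, "bands.csv"))
  readr::write_csv(report$blinding$windows$windows, file.path(dir, "windows.csv"))
  readr::write_csv(as_tibble(report$blinding$crossover), file.path(dir, "crossover.csv"))
  readr::write_csv(as_tibble(report$rt$block_summaries),
                   file.path(dir, "block_summaries.csv"))
  readr::write_csv(as_tibble(report$rt$subblock$bands),
                   file.path(dir, "subblock_bands.csv"))
  summary <- list(
    meta = report$meta,
    blinding = list(
      total_distinct_s = report$blinding$total_distinct_s,
      percent_of_difference = report$blinding$percent_of_difference,
      windows = report$blinding$windows$windows,
      crossover = as.list(glance(report$blinding$crossover))
    ),
    rt = list(
      block_tests = report$rt$block_tests,
      baseline_tost = as.list(tidy(report$rt$baseline_tost)),
      accuracy = report$rt$accuracy[c("mean_pct", "ci_lo", "ci_hi",
                                      "n_participants")],
      subblock_windows = as.list(glance(report$rt$subblock$windows))
    ),
    outcomes = list(
      side_effects = report$outcomes$side_effects,
      guesses = as.list(tidy(report$outcomes$guesses))
    )
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
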