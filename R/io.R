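#' Read and write trial tables
#'
#' Trial logs are exchanged as plain CSV. `write_trials()` writes any trial
#' tibble; `read_trials()` validates that the schema of the given task is
#' present (naming the missing column otherwise) and restores stable column
#' types so that a write-read round trip is lossless even for degenerate
#' files (e.g. all-forced sessions with no recorded choices). Unknown columns
#' are preserved.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @param task `"experience"` or `"description"`, selecting the required
#'   schema.
#' @return `read_trials()` returns a tibble; `write_trials()` returns `path`
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, task = c("experience", "description")) {
  task <- match.arg(task)
  required <- switch(task,
    experience = c("trial", "block", "set", "trial_type", "option_left",
                   "option_right"),
    description = c("trial", "block", "gamble_id"))
  known <- list(
    trial = readr::col_integer(), block = readr::col_integer(),
    set = readr::col_integer(), trial_type = readr::col_character(),
    option_left = readr::col_character(),
    option_right = readr::col_character(),
    gamble_id = readr::col_integer(), chosen = readr::col_character(),
    reward = readr::col_double(), outcome = readr::col_double(),
    condition = readr::col_character()
  )
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  types <- do.call(readr::cols,
                   c(known[intersect(names(known), header)],
                     list(.default = readr::col_guess())))
  out <- readr::read_csv(path, col_types = types, na = "",
                         show_col_types = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0)
    stop("trial file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out
}

#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: the run seed, task
#' schedule settings, the two condition populations, cohort sizes, and
#' fitting/recovery settings. The configuration is fully serializable to
#' JSON, so a run is reproducible from its persisted config alone.
#'
#' @param seed Run seed.
#' @param n_subjects Subjects per condition cohort.
#' @param n_recovery Agents in the recovery stage.
#' @param schedule_args Arguments for [experience_schedule()].
#' @param description_args Arguments for [description_schedule()].
#' @param populations Two-condition population list, see
#'   [default_populations()].
#' @param fit_args Arguments for [fit_population_em()].
#' @return A list of class `peirs_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 8, n_recovery = 8,
                            schedule_args = list(),
                            description_args = list(),
                            populations = default_populations(),
                            fit_args = list(max_iter = 30)) {
  structure(list(seed = seed, n_subjects = n_subjects,
                 n_recovery = n_recovery, schedule_args = schedule_args,
                 description_args = description_args,
                 populations = populations, fit_args = fit_args),
            class = "peirs_config")
}

config_to_json <- function(config, path) {
  ser <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    n_recovery = config$n_recovery, schedule_args = config$schedule_args,
    description_args = config$description_args,
    populations = purrr::map(config$populations, function(p)
      list(condition = p$condition, location = as.list(p$location),
           scale = as.list(p$scale), n_subjects = p$n_subjects)),
    fit_args = config$fit_args
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the end-to-end workflow on synthetic data: (1) design both task
#' schedules, (2) simulate a within-subject two-condition cohort plus
#' description-task choices, (3) compute the behavioral risk-preference
#' statistics and the 2x2 hunger-by-context ANOVA, (4) fit RW and PEIRS
#' hierarchically per condition, (5) run a parameter-recovery check, and (6)
#' write a summary report. Every artifact is written under `out_dir` as CSV
#' or JSON together with a manifest of files and checksums; identical
#' configurations regenerate byte-identical CSV artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return The manifest tibble (`stage`, `file`, `md5`), invisibly a list
#'   with all in-memory stage results as attribute `"results"`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- list()
  add <- function(stage, name) files[[length(files) + 1]] <<-
    list(stage = stage, file = name)

  seeds <- derive_seeds(config$seed, 6)

  # 1: design
  say("stage 1/6: design")
  sched <- do.call(experience_schedule,
                   c(config$schedule_args, list(seed = seeds[1])))
  dsched <- do.call(description_schedule,
                    c(config$description_args, list(seed = seeds[1])))
  write_trials(sched, file.path(out_dir, "experience_schedule.csv"))
  write_trials(dsched, file.path(out_dir, "description_schedule.csv"))
  config_to_json(config, file.path(out_dir, "config.json"))
  add("design", "experience_schedule.csv")
  add("design", "description_schedule.csv")
  add("design", "config.json")

  # 2: simulate
  say("stage 2/6: simulate")
  pops <- config$populations
  cohort <- simulate_within_cohort(pops[[1]], pops[[2]],
                                   n = config$n_subjects, seed = seeds[2],
                                   schedule_args = config$schedule_args)
  desc_trials <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
    dplyr::mutate(
      simulate_description_choices(policy_prospect(), dsched,
                                   seed = seeds[3] + i),
      subject = i, .before = 1)
  })
  write_trials(cohort$trials, file.path(out_dir, "experience_trials.csv"))
  write_trials(desc_trials, file.path(out_dir, "description_trials.csv"))
  readr::write_csv(cohort$params, file.path(out_dir, "true_params.csv"))
  add("simulate", "experience_trials.csv")
  add("simulate", "description_trials.csv")
  add("simulate", "true_params.csv")

  # 3: behavioral analysis
  say("stage 3/6: analyze")
  prefs <- risk_preference_experience(cohort$trials)
  prefs_long <- tidyr::pivot_longer(prefs, c("p_risky_high", "p_risky_low"),
                                    names_to = "context",
                                    names_prefix = "p_risky_",
                                    values_to = "p_risky")
  anova_tbl <- rm_anova_2x2(prefs_long, dv = "p_risky",
                            within = c("condition", "context"))
  desc_prefs <- risk_preference_description(desc_trials)
  readr::write_csv(prefs, file.path(out_dir, "risk_preferences.csv"))
  readr::write_csv(anova_tbl, file.path(out_dir, "anova.csv"))
  readr::write_csv(desc_prefs,
                   file.path(out_dir, "description_preferences.csv"))
  add("analyze", "risk_preferences.csv")
  add("analyze", "anova.csv")
  add("analyze", "description_preferences.csv")

  # 4: fit
  say("stage 4/6: fit")
  conds <- unique(cohort$trials$condition)
  fits <- purrr::map(conds, function(cd) {
    d <- dplyr::filter(cohort$trials, .data$condition == cd)
    list(
      peirs = do.call(fit_population_em,
                      c(list(d, model = "peirs"), config$fit_args)),
      rw = do.call(fit_population_em,
                   c(list(d, model = "rw"), config$fit_args))
    )
  })
  names(fits) <- conds
  fit_tbl <- purrr::map_dfr(conds, function(cd) {
    dplyr::bind_rows(
      dplyr::mutate(fits[[cd]]$peirs$fits, condition = cd, .before = 1),
      dplyr::mutate(fits[[cd]]$rw$fits, condition = cd, .before = 1))
  })
  readr::write_csv(fit_tbl, file.path(out_dir, "subject_fits.csv"))
  add("fit", "subject_fits.csv")

  comparisons <- purrr::map(conds, function(cd)
    glance(compare_models(fits[[cd]]$rw, fits[[cd]]$peirs)))
  comp_tbl <- dplyr::bind_rows(comparisons) |>
    dplyr::mutate(condition = conds, .before = 1)
  readr::write_csv(comp_tbl, file.path(out_dir, "model_comparison.csv"))
  add("fit", "model_comparison.csv")

  # 5: recovery
  say("stage 5/6: recover")
  rec <- do.call(parameter_recovery,
                 c(list(spec = pops[[1]], n = config$n_recovery,
                        seed = seeds[5],
                        schedule_args = config$schedule_args),
                   config$fit_args))
  readr::write_csv(tidy(rec), file.path(out_dir, "recovery_correlations.csv"))
  add("recover", "recovery_correlations.csv")

  # 6: report
  say("stage 6/6: report")
  report <- list(
    seed = config$seed,
    behavioral = list(
      anova = anova_tbl,
      mean_p_risky = prefs_long |>
        dplyr::group_by(.data$condition, .data$context) |>
        dplyr::summarise(p_risky = mean(.data$p_risky), .groups = "drop")
    ),
    model_comparison = comp_tbl,
    recovery = list(diag_r = as.list(rec$diag_r),
                    max_abs_offdiag = rec$max_abs_offdiag)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  add("report", "report.json")

  manifest <- purrr::map_dfr(files, tibble::as_tibble)
  manifest$md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  res <- list(cohort = cohort, prefs = prefs, anova = anova_tbl,
              fits = fits, comparison = comp_tbl, recovery = rec)
  attr(manifest, "results") <- res
  manifest
}
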