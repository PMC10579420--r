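## End-to-end orchestration: generate a synthetic cohort, train replicate
## M-subjects, verify reproduction, run the lesion suite, and summarize.
## Every stage is deterministic given the master seed of the run
## configuration.

#' Study run configuration
#'
#' @param master_seed Master integer seed; every downstream RNG stream is
#'   derived from it.
#' @param n_subjects Synthetic subjects in the cohort (study default 17;
#'   smoke default 3).
#' @param n_replicates Trained replicates ("M-subjects") per subject (study
#'   default 10; smoke default 2).
#' @param n_test_per_condition Test sequences per task condition (study
#'   default 100, i.e. 1400 per M-subject; smoke default 20).
#' @param hyper Cohort [profile_hyper()].
#' @param enc [encoding_config()].
#' @param training [training_config()]; its seed is overridden by a derived
#'   seed per subject.
#' @param lesions Named list of [lesion_config()] (default [lesion_suite()]).
#' @param pass_threshold Reproduction-check RMSE threshold (default 0.2).
#' @param bins Histogram bins for distribution comparisons (default 11).
#' @param thresholds Classification thresholds `c(lower = -2, upper = 2)`.
#' @param profile `"full"` or `"smoke"`; presets for the size arguments any
#'   of which can still be overridden explicitly.
#' @return An object of class `soa_config`.
#' @export
soa_config <- function(master_seed = 1L, profile = c("full", "smoke"),
                       n_subjects = NULL, n_replicates = NULL,
                       n_test_per_condition = NULL,
                       hyper = profile_hyper(), enc = encoding_config(),
                       training = training_config(),
                       lesions = lesion_suite(seed = master_seed),
                       pass_threshold = 0.2, bins = 11L,
                       thresholds = c(lower = -2, upper = 2)) {
  profile <- match.arg(profile)
  defs <- if (profile == "full") c(17L, 10L, 100L) else c(3L, 2L, 20L)
  structure(list(master_seed = as.integer(master_seed), profile = profile,
                 n_subjects = as.integer(n_subjects %||% defs[1]),
                 n_replicates = as.integer(n_replicates %||% defs[2]),
                 n_test_per_condition =
                   as.integer(n_test_per_condition %||% defs[3]),
                 hyper = hyper, enc = enc, training = training,
                 lesions = lesions, pass_threshold = pass_threshold,
                 bins = as.integer(bins), thresholds = thresholds),
            class = "soa_config")
}

config_hash <- function(config) {
  # cheap content hash for artifact provenance
  s <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Generate the synthetic cohort of a run
#'
#' @param config An [soa_config()].
#' @param dir Optional output directory; when given, behavioral and profile
#'   CSVs plus a manifest (with the config hash) are written.
#' @return List of `soa_dataset`.
#' @export
soa_generate <- function(config, dir = NULL) {
  cohort <- generate_cohort(config$n_subjects, config$master_seed,
                            config$hyper)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_behavior_csv(cohort, file.path(dir, "behavior.csv"))
    write_profiles_csv(cohort, file.path(dir, "profiles.csv"))
    writeLines(c(paste("config_hash:", config_hash(config)),
                 paste("master_seed:", config$master_seed),
                 paste("n_subjects:", config$n_subjects)),
               file.path(dir, "MANIFEST.txt"))
  }
  cohort
}

#' Train and check all M-subjects of a run
#'
#' Each subject gets `n_replicates` independently initialized trainings on
#' its 140 sequences, followed by the reproduction check on a freshly
#' sampled test set (RTs resampled from the subject's RT distribution).
#'
#' @param config An [soa_config()].
#' @param cohort Output of [soa_generate()].
#' @param dir Optional directory for per-model JSON weight files and a
#'   manifest CSV.
#' @return List with `m_subjects` (all, checked), `passing` (subset),
#'   `test_sets` (one per subject, indexed by subject id).
#' @export
soa_train <- function(config, cohort, dir = NULL) {
  test_sets <- list()
  m_subjects <- list()
  for (i in seq_along(cohort)) {
    ds <- cohort[[i]]
    cfg_i <- config$training
    cfg_i$seed <- derive_seed(config$master_seed, 1000L + i)
    ms <- make_m_subjects(ds, config$n_replicates, cfg_i, config$enc)
    ts <- build_test_set(ds$profile, config$n_test_per_condition,
                         seed = derive_seed(config$master_seed, 2000L + i),
                         enc = config$enc)
    test_sets[[ds$subject_id]] <- ts
    ms <- lapply(ms, reproduction_check, test_set = ts, dataset = ds,
                 threshold = config$pass_threshold, enc = config$enc)
    m_subjects <- c(m_subjects, ms)
  }
  passing <- Filter(function(m) isTRUE(m$reproduction_pass), m_subjects)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    man <- do.call(rbind, lapply(m_subjects, function(m)
      data.frame(subject_id = m$source_subject_id,
                 replicate = m$replicate_index,
                 training_error = m$training_error,
                 generalization_error = m$generalization_error,
                 pass = m$reproduction_pass)))
    write.csv(man, file.path(dir, "m_subjects.csv"), row.names = FALSE)
    for (m in m_subjects)
      write_rnn_json(m$params, file.path(dir, sprintf("model_%s_%02d.json",
                                                      m$source_subject_id,
                                                      m$replicate_index)))
  }
  list(m_subjects = m_subjects, passing = passing, test_sets = test_sets)
}

#' Run the configured lesion suite of a run
#'
#' @param config An [soa_config()].
#' @param trained Output of [soa_train()].
#' @param dir Optional directory for per-lesion result CSVs.
#' @return Named list (per lesion kind) of lists of `lesion_result`.
#' @export
soa_lesion <- function(config, trained, dir = NULL) {
  passing <- trained$passing
  if (!length(passing)) {
    warning("no M-subjects passed the reproduction check; nothing to lesion")
    return(stats::setNames(list(), character(0)))
  }
  sets <- lapply(passing, function(m) trained$test_sets[[m$source_subject_id]])
  out <- lapply(config$lesions, function(les)
    run_lesion_experiment(passing, sets, les))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      write.csv(lesion_results_table(out[[nm]]),
                file.path(dir, paste0("lesion_", nm, ".csv")),
                row.names = FALSE)
  }
  out
}

#' Summarize a run
#'
#' Computes, per lesion kind: the MSE/KL distance between the window-average
#' distribution of the lesioned cohort and the synthetic mixed PS+NS
#' reference, and the classification counts. Also reports group mean curves
#' for the recurrent-delay lesion, the context-unit correlation report of
#' the healthy models, and the over-learning test.
#'
#' @param config An [soa_config()].
#' @param trained Output of [soa_train()].
#' @param lesioned Output of [soa_lesion()].
#' @param dir Optional directory; a `report.json` is written there.
#' @return A list report.
#' @export
soa_report <- function(config, trained, lesioned, dir = NULL) {
  sz_ref <- generate_sz_reference("mixed",
                                  seed = derive_seed(config$master_seed, 3000L))
  distances <- lapply(lesioned, function(results) {
    d <- distribution_distance(sz_ref,
                               lapply(results, `[[`, "curve_lesioned"),
                               bins = config$bins)
    list(mse = d$mse, kl = d$kl)
  })
  classifications <- lapply(lesioned, function(results)
    classify_lesion_results(results, thresholds = config$thresholds))
  class_counts <- lapply(classifications, function(cl) table(cl$label))
  groups <- NULL
  if ("td_context" %in% names(lesioned)) {
    res <- lesioned$td_context
    cl <- classifications$td_context
    groups <- group_curves(lapply(res, `[[`, "curve_lesioned"), cl$label)
  }
  unit_report <- unit_correlation_report(
    lapply(trained$passing, function(m) attr(m, "test_runs")))
  report <- list(config_hash = config_hash(config),
                 master_seed = config$master_seed,
                 n_m_subjects = length(trained$m_subjects),
                 n_passing = length(trained$passing),
                 distances = distances,
                 class_counts = lapply(class_counts, as.list),
                 group_curves = groups,
                 unit_report = list(
                   mean_soa_units = unit_report$mean_soa_units,
                   mean_latency_units = unit_report$mean_latency_units),
                 overlearning = overlearning_test(trained$m_subjects))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report), "group_curves")],
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Run the full study end to end
#'
#' @param config An [soa_config()].
#' @param dir Optional output directory for all stage artifacts.
#' @return List with `cohort`, `trained`, `lesioned`, `report`.
#' @export
soa_run <- function(config = soa_config(), dir = NULL) {
  cohort <- soa_generate(config, dir)
  trained <- soa_train(config, cohort, dir)
  lesioned <- soa_lesion(config, trained, dir)
  report <- soa_report(config, trained, lesioned, dir)
  list(cohort = cohort, trained = trained, lesioned = lesioned,
       report = report)
}
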