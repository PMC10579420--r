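## The simulated lesion experiments: run a lesion configuration over a
## cohort of trained M-subjects during the test phase and collect per-model
## lesioned and healthy yes-rate curves.

#' Standard lesion suite
#'
#' The four temporal-delay/noise experiments plus the reduced-gain probe:
#' `td_context` (random 0/1-step delay on the recurrent reads), `noise`
#' (multiplicative state noise, level 0.01), `td_output` (delay on the
#' judgment output's read), `td_input` (delay on the input reads), and
#' `reduced_gain` at `a = 0.99`.
#'
#' @param seed Base seed for the lesion RNG streams.
#' @param gain_value Gain for the reduced-gain probe (default 0.99).
#' @return Named list of [lesion_config()].
#' @export
lesion_suite <- function(seed = 1L, gain_value = 0.99) {
  list(td_context = lesion_config("td_context", seed = seed),
       noise = lesion_config("noise", noise_level = 0.01, seed = seed),
       td_output = lesion_config("td_output", seed = seed),
       td_input = lesion_config("td_input", seed = seed),
       reduced_gain = lesion_config("reduced_gain", gain_value = gain_value,
                                    seed = seed))
}

#' Run one lesion experiment over a cohort of M-subjects
#'
#' Each M-subject's full test set is run under the lesion; the healthy
#' (unlesioned) curve is taken from the M-subject's reproduction check when
#' available, otherwise computed once. The lesion RNG stream is independent
#' of the training and behavior streams: each M-subject's run is seeded with
#' a value derived from `lesion$seed` and its cohort index.
#'
#' @param m_subjects List of `m_subject` (normally only those passing the
#'   reproduction check).
#' @param test_sets Either one list of test sequences shared by all
#'   M-subjects or a list of per-M-subject test sets.
#' @param lesion A [lesion_config()].
#' @return List of objects of class `lesion_result`: list with
#'   `m_subject_id`, `lesion`, `curve_lesioned`, `curve_healthy`, and the
#'   lesioned runs as attribute `"runs"`.
#' @export
run_lesion_experiment <- function(m_subjects, test_sets, lesion) {
  stopifnot(inherits(lesion, "lesion_config"))
  per_subject <- length(test_sets) == length(m_subjects) &&
    !inherits(test_sets[[1]], "soa_sequence")
  lapply(seq_along(m_subjects), function(i) {
    m <- m_subjects[[i]]
    ts <- if (per_subject) test_sets[[i]] else test_sets
    healthy <- m$test_curve %||% yes_rate_curve(run_sequences(m$params, ts))
    les <- lesion
    les$seed <- derive_seed(lesion$seed %||% 0L, i)
    runs <- run_sequences(m$params, ts, les)
    res <- structure(list(m_subject_id = paste0(m$source_subject_id, ".",
                                                m$replicate_index),
                          lesion = lesion,
                          curve_lesioned = yes_rate_curve(runs),
                          curve_healthy = healthy),
                     class = "lesion_result")
    attr(res, "runs") <- runs
    res
  })
}

#' Tabulate a lesion experiment as a long data.frame
#'
#' @param results List of `lesion_result`.
#' @return data.frame with columns `m_subject_id`, `lesion_kind`,
#'   `trial_type`, `condition_ms`, `yes_rate_lesioned`, `yes_rate_healthy`.
#' @export
lesion_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(m_subject_id = r$m_subject_id, lesion_kind = r$lesion$kind,
               trial_type = r$curve_lesioned$trial_type,
               condition_ms = r$curve_lesioned$condition_ms,
               yes_rate_lesioned = r$curve_lesioned$yes_rate,
               yes_rate_healthy = r$curve_healthy$yes_rate,
               stringsAsFactors = FALSE)
  }))
}

#' Classify every result of a lesion experiment
#'
#' @param results List of `lesion_result`.
#' @param ... Passed to [classify_m_subject()].
#' @return data.frame with `m_subject_id`, `Y_short`, `Y_long`, `label`.
#' @export
classify_lesion_results <- function(results, ...) {
  do.call(rbind, lapply(results, function(r) {
    cl <- classify_m_subject(r$curve_lesioned, r$curve_healthy, ...)
    data.frame(m_subject_id = r$m_subject_id, Y_short = cl$Y_short,
               Y_long = cl$Y_long, label = cl$label,
               stringsAsFactors = FALSE)
  }))
}
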