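## Synthetic behavioral datasets for the agency-attribution (Keio-style)
## task. Each synthetic subject is a 4-parameter logistic psychometric curve
## over the press-to-jump latency, constant per-condition yes-probabilities
## for the EPA trials, and a normal reaction-time distribution.

#' Cohort-level parameter ranges for synthetic subjects
#'
#' Every field of a [subject_profile()] is drawn uniformly from the interval
#' given here. Defaults describe a healthy-control-like cohort: near-certain
#' "yes" at short latencies, near-certain "no" at long latencies, a
#' psychometric inflection between 300 and 700 ms, and low EPA yes rates.
#'
#' @param inflection_ms,slope,upper_asymptote,lower_asymptote,epa_yes_prob,rt_mean_ms,rt_sd_ms
#'   Length-2 numeric ranges (min, max) for the corresponding
#'   [subject_profile()] field. `epa_yes_prob` is sampled independently for
#'   each of the three EPA conditions.
#' @return An object of class `soa_hyper` (a named list of ranges).
#' @export
profile_hyper <- function(inflection_ms = c(300, 700),
                          slope = c(0.008, 0.02),
                          upper_asymptote = c(0.9, 0.99),
                          lower_asymptote = c(0.01, 0.1),
                          epa_yes_prob = c(0.1, 0.3),
                          rt_mean_ms = c(250, 450),
                          rt_sd_ms = c(30, 80)) {
  h <- list(inflection_ms = inflection_ms, slope = slope,
            upper_asymptote = upper_asymptote,
            lower_asymptote = lower_asymptote,
            epa_yes_prob = epa_yes_prob,
            rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms)
  for (nm in names(h)) {
    r <- h[[nm]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("invalid range for '", nm, "': must be numeric c(min, max)")
  }
  if (h$lower_asymptote[2] >= h$upper_asymptote[1])
    stop("lower_asymptote range must lie strictly below upper_asymptote range")
  if (h$inflection_ms[1] < 0 || h$inflection_ms[2] > 1000)
    stop("inflection_ms range must lie within [0, 1000]")
  if (h$slope[1] <= 0) stop("slope must be positive")
  if (h$rt_mean_ms[1] <= 0) stop("rt_mean_ms must be positive")
  if (h$rt_sd_ms[1] < 0) stop("rt_sd_ms must be non-negative")
  structure(h, class = "soa_hyper")
}

#' Construct a synthetic subject profile
#'
#' @param subject_id Character label.
#' @param inflection_ms Latency (ms) at which the yes-probability crosses the
#'   midpoint of the two asymptotes; in `[0, 1000]`.
#' @param slope Logistic steepness per ms (> 0).
#' @param upper_asymptote,lower_asymptote Yes-probability asymptotes at very
#'   short / very long latencies; `0 <= lower < upper <= 1`.
#' @param epa_yes_prob Length-3 yes-probabilities for the EPA offsets
#'   (-100, 0, +100 ms).
#' @param rt_mean_ms,rt_sd_ms Reaction-time mean (> 0) and SD (>= 0) in ms.
#' @return An object of class `soa_profile`.
#' @export
subject_profile <- function(subject_id, inflection_ms, slope,
                            upper_asymptote, lower_asymptote,
                            epa_yes_prob, rt_mean_ms, rt_sd_ms) {
  stopifnot(length(epa_yes_prob) == 3L)
  if (!(lower_asymptote >= 0 && lower_asymptote <= upper_asymptote &&
        upper_asymptote <= 1))
    stop("need 0 <= lower_asymptote <= upper_asymptote <= 1")
  if (inflection_ms < 0 || inflection_ms > 1000)
    stop("inflection_ms must be in [0, 1000]")
  if (slope <= 0) stop("slope must be > 0")
  if (rt_mean_ms <= 0) stop("rt_mean_ms must be > 0")
  if (rt_sd_ms < 0) stop("rt_sd_ms must be >= 0")
  if (any(epa_yes_prob < 0 | epa_yes_prob > 1))
    stop("epa_yes_prob must be probabilities")
  structure(list(subject_id = as.character(subject_id),
                 inflection_ms = inflection_ms, slope = slope,
                 upper_asymptote = upper_asymptote,
                 lower_asymptote = lower_asymptote,
                 epa_yes_prob = stats::setNames(as.numeric(epa_yes_prob),
                                                as.character(epa_offsets())),
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms),
            class = "soa_profile")
}

#' Draw a subject profile from cohort-level ranges
#'
#' Deterministic for a given `(seed, hyper)` pair; each field is drawn
#' independently and uniformly within its range.
#'
#' @param seed Integer seed.
#' @param hyper A [profile_hyper()] object.
#' @param subject_id Label for the subject (default derived from the seed).
#' @return An `soa_profile`.
#' @export
generate_subject_profile <- function(seed, hyper = profile_hyper(),
                                     subject_id = paste0("H", seed)) {
  if (!inherits(hyper, "soa_hyper")) hyper <- do.call(profile_hyper, hyper)
  set.seed(as.integer(seed))
  draw <- function(r) runif(1, r[1], r[2])
  subject_profile(
    subject_id = subject_id,
    inflection_ms = draw(hyper$inflection_ms),
    slope = draw(hyper$slope),
    upper_asymptote = draw(hyper$upper_asymptote),
    lower_asymptote = draw(hyper$lower_asymptote),
    epa_yes_prob = runif(3, hyper$epa_yes_prob[1], hyper$epa_yes_prob[2]),
    rt_mean_ms = draw(hyper$rt_mean_ms),
    rt_sd_ms = draw(hyper$rt_sd_ms))
}

#' Yes-probability of a subject for one task condition
#'
#' Action-linked trials follow a monotone decreasing 4-parameter logistic in
#' the jumping latency `L`:
#' `p(L) = lower + (upper - lower) / (1 + exp(slope * (L - inflection)))`.
#' EPA trials have a constant per-condition probability.
#'
#' @param profile An `soa_profile`.
#' @param trial_type `"action_linked"` or `"epa"`.
#' @param condition_ms Latency (action-linked) or beep offset (EPA), ms.
#' @return Probability in `[0, 1]` (vectorized over `condition_ms`).
#' @export
yes_probability <- function(profile, trial_type, condition_ms) {
  stopifnot(inherits(profile, "soa_profile"))
  trial_type <- match.arg(trial_type, c("action_linked", "epa"))
  if (trial_type == "action_linked") {
    if (any(!condition_ms %in% action_latencies()) &&
        any(condition_ms < 0 | condition_ms > 1000))
      stop("unknown action-linked condition: ", condition_ms[1])
    lo <- profile$lower_asymptote
    up <- profile$upper_asymptote
    lo + (up - lo) * plogis(-profile$slope *
                              (condition_ms - profile$inflection_ms))
  } else {
    if (any(!condition_ms %in% epa_offsets()))
      stop("unknown EPA condition: ", condition_ms[1])
    unname(profile$epa_yes_prob[as.character(condition_ms)])
  }
}

## RTs are plain normal draws truncated to >= 1 ms by rejection: negative
## reaction times are physically impossible.
draw_rts <- function(n, mean_ms, sd_ms) {
  out <- rnorm(n, mean_ms, sd_ms)
  bad <- which(out < 1)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean_ms, sd_ms)
    bad <- bad[out[bad] < 1]
  }
  out
}

#' Generate one subject's 140-trial behavioral dataset
#'
#' Eleven action-linked latency conditions and three EPA conditions, each
#' repeated 10 times, in a seeded random order. Responses are Bernoulli draws
#' from [yes_probability()]; reaction times are normal draws truncated to be
#' strictly positive.
#'
#' @param profile An `soa_profile`.
#' @param seed Integer seed.
#' @param n_reps Repetitions per condition (default 10).
#' @return An object of class `soa_dataset`: list with `subject_id`,
#'   `trials` (a 140-row data.frame with `trial_index`, `trial_type`,
#'   `condition_ms`, `rt_ms`, `response` in `{0,1}`) and the generating
#'   `profile`.
#' @export
generate_behavioral_dataset <- function(profile, seed, n_reps = 10L) {
  stopifnot(inherits(profile, "soa_profile"), n_reps >= 1L)
  grid <- condition_grid()
  trials <- grid[rep(seq_len(nrow(grid)), each = n_reps), ]
  set.seed(as.integer(seed))
  trials <- trials[sample.int(nrow(trials)), ]
  p <- ifelse(trials$trial_type == "action_linked",
              yes_probability(profile, "action_linked",
                              pmax(trials$condition_ms, 0)),
              NA_real_)
  epa <- trials$trial_type == "epa"
  p[epa] <- profile$epa_yes_prob[as.character(trials$condition_ms[epa])]
  trials$rt_ms <- draw_rts(nrow(trials), profile$rt_mean_ms, profile$rt_sd_ms)
  trials$response <- rbinom(nrow(trials), 1L, p)
  trials$trial_index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials <- trials[, c("trial_index", "trial_type", "condition_ms",
                       "rt_ms", "response")]
  structure(list(subject_id = profile$subject_id, trials = trials,
                 profile = profile),
            class = "soa_dataset")
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived from the master seed by a fixed counter
#' scheme (`seed + 7919 * i` for the profile, `+ 1` for the trials), so any
#' subject can be regenerated in isolation.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param seed Master integer seed.
#' @param hyper A [profile_hyper()] object.
#' @return List of `soa_dataset`, length `n_subjects`.
#' @export
generate_cohort <- function(n_subjects = 17L, seed = 1L,
                            hyper = profile_hyper()) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    base <- derive_seed(seed, i)
    prof <- generate_subject_profile(base, hyper,
                                     subject_id = sprintf("H%02d", i))
    generate_behavioral_dataset(prof, base + 1L)
  })
}

## Cohort ranges for the two synthetic schizophrenia-pattern phenotypes.
## These are qualitative stand-ins, not fits to any clinical dataset:
## PS-type keeps high yes rates at short latencies but stays elevated at long
## latencies and in EPA trials (excessive agency); NS-type has reduced yes
## rates at short latencies with a long-latency floor like controls
## (diminished agency).
ps_hyper <- function() {
  profile_hyper(inflection_ms = c(550, 950), slope = c(0.005, 0.015),
                upper_asymptote = c(0.9, 1.0), lower_asymptote = c(0.25, 0.55),
                epa_yes_prob = c(0.4, 0.8))
}
ns_hyper <- function() {
  profile_hyper(inflection_ms = c(250, 600), slope = c(0.005, 0.015),
                upper_asymptote = c(0.45, 0.75), lower_asymptote = c(0, 0.08),
                epa_yes_prob = c(0.05, 0.2))
}

#' Synthetic schizophrenia-pattern reference yes-rate curves
#'
#' Stand-in reference curves with the qualitative paranoid-type (PS,
#' excessive agency: elevated yes rates at long latencies and in EPA trials)
#' and negative-symptom-type (NS, diminished agency: reduced yes rates at
#' short latencies) signatures. The default mixed composition is 30 PS + 20
#' NS curves. These are configurable stand-ins, never ground truth.
#'
#' @param group `"mixed"`, `"PS"` or `"NS"`.
#' @param n_subjects Number of curves; defaults to 50 for `"mixed"` (30 PS +
#'   20 NS), 30 for `"PS"`, 20 for `"NS"`.
#' @param seed Integer seed.
#' @param n_reps Trials per condition used to sample empirical rates
#'   (default 10, the behavioral granularity).
#' @return List of `soa_curve` objects; each carries its generating profile
#'   and phenotype as attributes `"profile"` and `"phenotype"`.
#' @export
generate_sz_reference <- function(group = c("mixed", "PS", "NS"),
                                  n_subjects = NULL, seed = 1L,
                                  n_reps = 10L) {
  group <- match.arg(group)
  comp <- switch(group,
                 mixed = c(PS = 30L, NS = 20L),
                 PS = c(PS = n_subjects %||% 30L),
                 NS = c(NS = n_subjects %||% 20L))
  if (group == "mixed" && !is.null(n_subjects)) {
    ps <- round(n_subjects * 0.6)
    comp <- c(PS = ps, NS = n_subjects - ps)
  }
  labels <- rep(names(comp), comp)
  lapply(seq_along(labels), function(i) {
    hy <- if (labels[i] == "PS") ps_hyper() else ns_hyper()
    base <- derive_seed(seed, i) + 500000L
    prof <- generate_subject_profile(base, hy,
                                     subject_id = sprintf("%s%02d", labels[i], i))
    grid <- condition_grid()
    p <- mapply(function(tt, cm) yes_probability(prof, tt, cm),
                grid$trial_type, grid$condition_ms)
    set.seed(base + 1L)
    rate <- rbinom(length(p), n_reps, p) / n_reps
    cur <- soa_curve(grid$trial_type, grid$condition_ms, rate,
                     n_trials = n_reps)
    attr(cur, "profile") <- prof
    attr(cur, "phenotype") <- labels[i]
    cur
  })
}

#' Write / read behavioral and profile CSV files
#'
#' One row per trial: `subject_id, trial_index, trial_type, condition_ms,
#' rt_ms, response`; the profile table has one row per subject with all
#' profile fields (`epa_yes_prob` split into three columns).
#'
#' @param cohort List of `soa_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`read_behavior_csv` returns the data.frame).
#' @export
write_behavior_csv <- function(cohort, path) {
  if (inherits(cohort, "soa_dataset")) cohort <- list(cohort)
  rows <- do.call(rbind, lapply(cohort, function(d)
    cbind(subject_id = d$subject_id, d$trials)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_behavior_csv
#' @export
write_profiles_csv <- function(cohort, path) {
  if (inherits(cohort, "soa_dataset")) cohort <- list(cohort)
  rows <- do.call(rbind, lapply(cohort, function(d) {
    p <- d$profile
    data.frame(subject_id = p$subject_id, inflection_ms = p$inflection_ms,
               slope = p$slope, upper_asymptote = p$upper_asymptote,
               lower_asymptote = p$lower_asymptote,
               epa_yes_prob_m100 = p$epa_yes_prob[["-100"]],
               epa_yes_prob_0 = p$epa_yes_prob[["0"]],
               epa_yes_prob_p100 = p$epa_yes_prob[["100"]],
               rt_mean_ms = p$rt_mean_ms, rt_sd_ms = p$rt_sd_ms)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Empirical yes-rate curve of a behavioral dataset
#'
#' @param dataset An `soa_dataset`.
#' @return An `soa_curve` with one row per task condition.
#' @export
empirical_curve <- function(dataset) {
  stopifnot(inherits(dataset, "soa_dataset"))
  tr <- dataset$trials
  grid <- condition_grid()
  rate <- numeric(nrow(grid))
  n <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sel <- tr$trial_type == grid$trial_type[i] &
      tr$condition_ms == grid$condition_ms[i]
    n[i] <- sum(sel)
    rate[i] <- if (n[i]) mean(tr$response[sel]) else NA_real_
  }
  soa_curve(grid$trial_type, grid$condition_ms, rate, n_trials = n)
}
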