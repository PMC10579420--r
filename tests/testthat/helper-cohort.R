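# Shared trained cohort for the acceptance suite. Built once per test run
# and cached; subjects are trained in batches (two replicates each) until at
# least 52 M-subjects pass the reproduction check, capped at 50 subjects.
# Test sets use 50 sequences per condition — a scaled-down reproduction test
# that keeps the whole suite inside a desk-scale run.
.soasim_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (!is.null(.soasim_cache$cohort)) return(.soasim_cache$cohort)
  master <- 20240901L
  n_replicates <- 2L
  max_subjects <- 50L
  target_passing <- 52L

  datasets <- generate_cohort(max_subjects, seed = master)
  m_subjects <- list()
  test_sets <- list()
  n_used <- 0L
  for (i in seq_len(max_subjects)) {
    ds <- datasets[[i]]
    cfg <- training_config(seed = derive_seed_h(master, 1000L + i))
    ms <- make_m_subjects(ds, n_replicates, cfg)
    ts <- build_test_set(ds$profile, n_per_condition = 50L,
                         seed = derive_seed_h(master, 2000L + i))
    test_sets[[ds$subject_id]] <- ts
    ms <- lapply(ms, reproduction_check, test_set = ts, dataset = ds)
    m_subjects <- c(m_subjects, ms)
    n_used <- i
    n_pass <- sum(vapply(m_subjects, `[[`, TRUE, "reproduction_pass"))
    if (n_pass >= target_passing) break
  }
  passing <- Filter(function(m) isTRUE(m$reproduction_pass), m_subjects)
  .soasim_cache$cohort <- list(
    datasets = datasets[seq_len(n_used)],
    m_subjects = m_subjects,
    passing = passing,
    passing_sets = lapply(passing,
                          function(m) test_sets[[m$source_subject_id]]),
    test_sets = test_sets,
    master = master)
  .soasim_cache$cohort
}

# lesion results over the passing cohort, cached per lesion kind
acceptance_lesion <- function(kind) {
  key <- paste0("lesion_", kind)
  if (!is.null(.soasim_cache[[key]])) return(.soasim_cache[[key]])
  co <- acceptance_cohort()
  les <- if (kind == "reduced_gain")
    lesion_config(kind, gain_value = 0.99,
                  seed = derive_seed_h(co$master, 4000L))
  else lesion_config(kind, seed = derive_seed_h(co$master, 4000L))
  .soasim_cache[[key]] <- run_lesion_experiment(co$passing, co$passing_sets,
                                                les)
  .soasim_cache[[key]]
}

derive_seed_h <- function(seed, index) seed + 7919L * index

generating_curve <- function(profile) {
  grid <- condition_grid()
  p <- mapply(function(tt, cm) yes_probability(profile, tt, cm),
              grid$trial_type, grid$condition_ms)
  soa_curve(grid$trial_type, grid$condition_ms, p)
}
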