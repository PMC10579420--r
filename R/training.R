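## Backpropagation-through-time training of simulated subjects
## ("M-subjects") against one synthetic subject's 140 training sequences,
## plus the reproduction and over-learning checks.

#' Training configuration
#'
#' Full-batch training (all sequences in one batch per update) on the mean
#' per-step squared output error. The default optimizer is iRprop- (signed
#' per-weight step-size adaptation), which is robust for full-batch
#' schedules; plain gradient descent with classical momentum is available
#' as `optimizer = "momentum"`.
#'
#' @param learning_rate Initial per-weight step size for `"rprop"`, or the
#'   step size for `"momentum"`/`"adam"` (default 0.001).
#' @param momentum Momentum coefficient, used by `"momentum"` only
#'   (default 0.9).
#' @param epochs Number of full-batch updates (default 12000).
#' @param weight_init_scale Half-width of the uniform weight initialization
#'   (default 0.1).
#' @param loss_weights Length-4 per-output-channel loss weights (beep,
#'   button, position, judgment); the judgment channel gets weight 3 by
#'   default so the behavioral readout is not dominated by the three
#'   sensory-prediction channels.
#' @param optimizer `"rprop"` (default), `"adam"`, or `"momentum"`.
#' @param rprop_step_max Ceiling on the adaptive per-weight step
#'   (default 1).
#' @param seed Integer seed for the initialization.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, momentum = 0.9,
                            epochs = 12000L, weight_init_scale = 0.1,
                            loss_weights = c(1, 1, 1, 3),
                            optimizer = c("rprop", "adam", "momentum"),
                            rprop_step_max = 1, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (weight_init_scale <= 0) stop("weight_init_scale must be > 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  stopifnot(length(loss_weights) == 4L, all(loss_weights >= 0))
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 weight_init_scale = weight_init_scale,
                 loss_weights = as.numeric(loss_weights),
                 optimizer = optimizer,
                 rprop_step_max = rprop_step_max,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train a network on a set of sensorimotor sequences
#'
#' Minimizes the mean (over sequences and steps) weighted squared error
#' between the four output channels and their targets, with gradients
#' computed by full unrolling of the recurrence (BPTT). Deterministic for a
#' given configuration and data.
#'
#' @param sequences List of `soa_sequence` with complete targets.
#' @param cfg A [training_config()].
#' @param params Optional initial [rnn_params()]; by default drawn uniformly
#'   in `[-weight_init_scale, weight_init_scale]` from `cfg$seed`.
#' @return Trained `rnn_params`; the loss trace is attached as attribute
#'   `"loss_history"`.
#' @export
train_bptt <- function(sequences, cfg = training_config(), params = NULL) {
  stopifnot(length(sequences) >= 1L)
  X_list <- lapply(sequences, function(s) s$inputs)
  Y_list <- lapply(sequences, function(s) s$targets)
  if (is.null(params))
    params <- rnn_params(init_scale = cfg$weight_init_scale, seed = cfg$seed)
  fit <- ctrnn_train_cpp(params$W_cx, params$W_cc, params$W_oc,
                         params$tau, params$gain, X_list, Y_list,
                         cfg$loss_weights, cfg$learning_rate, cfg$momentum,
                         cfg$epochs, record_every = 10L,
                         optimizer = switch(cfg$optimizer, momentum = 0L,
                                            rprop = 1L, adam = 2L),
                         rprop_step_max = cfg$rprop_step_max)
  out <- rnn_params(W_cx = fit$W_cx, W_cc = fit$W_cc, W_oc = fit$W_oc,
                    tau = params$tau, gain = params$gain,
                    meta = c(params$meta, list(training_seed = cfg$seed)))
  attr(out, "loss_history") <- fit$loss_history
  attr(out, "final_loss") <- fit$loss
  out
}

#' Train replicate M-subjects for one synthetic subject
#'
#' Each replicate is an independently initialized training run (derived
#' seeds `cfg$seed + replicate`) on the same training sequences.
#'
#' @param dataset An `soa_dataset`.
#' @param n_replicates Replicates per subject (default 10).
#' @param cfg A [training_config()]; the per-replicate seed is derived from
#'   `cfg$seed` and the replicate index.
#' @param enc An [encoding_config()].
#' @return List of objects of class `m_subject`: list with `params`,
#'   `source_subject_id`, `replicate_index`, and (after
#'   [reproduction_check()]) `training_error`, `generalization_error`,
#'   `reproduction_pass`.
#' @export
make_m_subjects <- function(dataset, n_replicates = 10L,
                            cfg = training_config(),
                            enc = encoding_config()) {
  stopifnot(inherits(dataset, "soa_dataset"), n_replicates >= 1L)
  train_seqs <- build_training_set(dataset, enc)
  lapply(seq_len(n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, r)
    params <- tryCatch(train_bptt(train_seqs, cfg_r),
                       error = function(e)
                         stop("replicate ", r, ": ", conditionMessage(e)))
    params$meta$source_subject_id <- dataset$subject_id
    params$meta$replicate_index <- r
    structure(list(params = params,
                   source_subject_id = dataset$subject_id,
                   replicate_index = r,
                   training_error = NA_real_,
                   generalization_error = NA_real_,
                   reproduction_pass = NA),
              class = "m_subject")
  })
}

#' Root-mean-square difference between two yes-rate curves
#'
#' @param a,b `soa_curve` objects over the full condition grid.
#' @return RMSE over the 14 conditions.
#' @export
curve_rmse <- function(a, b) {
  stopifnot(inherits(a, "soa_curve"), inherits(b, "soa_curve"))
  sqrt(mean((a$yes_rate - b$yes_rate)^2))
}

#' Reproduction check of one trained M-subject
#'
#' The training error is the RMSE between the subject's empirical
#' per-condition yes rates and the model's yes rates on the training
#' sequences; the generalization error is the same RMSE on the independent
#' test set. The M-subject passes when its generalization error does not
#' exceed `threshold`.
#'
#' @param m An `m_subject`.
#' @param test_set List of test `soa_sequence` (typically 1400).
#' @param dataset The source `soa_dataset`.
#' @param threshold Pass threshold on the generalization RMSE over the
#'   14-condition curve (default 0.2, sized to sit above the binomial
#'   sampling noise of a 10-repetition empirical curve plus the
#'   discretization floor of a thresholded deterministic readout).
#' @param enc An [encoding_config()].
#' @return The `m_subject` with errors and pass flag filled; the model's
#'   test-set curve is attached as `$test_curve` and the test runs as
#'   attribute `"test_runs"`.
#' @export
reproduction_check <- function(m, test_set, dataset, threshold = 0.2,
                               enc = encoding_config()) {
  stopifnot(inherits(m, "m_subject"), inherits(dataset, "soa_dataset"))
  emp <- empirical_curve(dataset)
  train_seqs <- build_training_set(dataset, enc)
  train_runs <- run_sequences(m$params, train_seqs)
  test_runs <- run_sequences(m$params, test_set)
  m$training_error <- curve_rmse(emp, yes_rate_curve(train_runs))
  m$test_curve <- yes_rate_curve(test_runs)
  m$generalization_error <- curve_rmse(emp, m$test_curve)
  m$reproduction_pass <- m$generalization_error <= threshold
  attr(m, "test_runs") <- test_runs
  m
}

#' Over-learning check across a cohort of M-subjects
#'
#' Two-sided Mann-Whitney U test comparing the cohort's training errors with
#' its generalization errors (treated as independent samples). A
#' non-significant result indicates the models did not over-learn.
#'
#' @param m_subjects List of `m_subject` with both errors filled.
#' @return List with `statistic` (U for the training errors) and `p.value`.
#' @export
overlearning_test <- function(m_subjects) {
  tr <- vapply(m_subjects, `[[`, 0, "training_error")
  ge <- vapply(m_subjects, `[[`, 0, "generalization_error")
  if (length(tr) < 2L || any(is.na(tr)) || any(is.na(ge)))
    stop("need >= 2 M-subjects with both errors computed")
  mann_whitney_u(tr, ge)
}
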