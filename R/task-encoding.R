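## Trial -> sensorimotor sequence encoding. A trial becomes a time series of
## three input channels (beep, button, object position) and four target
## channels (one-step predictions of the three inputs plus the agency
## judgment), all mapped to [0.1, 0.9].

#' Encoding configuration for sensorimotor sequences
#'
#' @param dt_ms Milliseconds per time step; must divide 100 so every latency
#'   condition falls on an integer step (default 100).
#' @param n_steps Sequence length in steps (default 22, i.e. 2.2 s: enough
#'   for the beep, the longest plausible reaction time and a 1000 ms
#'   latency, while keeping the judgment readout close after the jump --
#'   with a long post-jump settling window the judgment saturates so deeply
#'   that run-time perturbations cannot move it).
#' @param beep_step Step index (1-based) of the single-step beep pulse
#'   (default 3, i.e. 300 ms into the trial).
#' @param jump_increment Extra instantaneous position increment at the jump
#'   step, added to the linear ramp before renormalization (default 0.2).
#' @return An object of class `soa_encoding`.
#' @export
encoding_config <- function(dt_ms = 100, n_steps = 22L, beep_step = 3L,
                            jump_increment = 0.2) {
  if (100 %% dt_ms != 0) stop("dt_ms must divide 100 ms")
  if (n_steps < 5L) stop("n_steps too short to hold the task events")
  if (beep_step < 1L || beep_step > n_steps) stop("beep_step outside sequence")
  if (jump_increment < 0) stop("jump_increment must be >= 0")
  structure(list(dt_ms = dt_ms, n_steps = as.integer(n_steps),
                 beep_step = as.integer(beep_step),
                 jump_increment = jump_increment),
            class = "soa_encoding")
}

## RT rounding to nearest step, ties round half up.
rt_to_steps <- function(rt_ms, dt_ms) as.integer(floor(rt_ms / dt_ms + 0.5))

#' Encode one trial as a sensorimotor sequence
#'
#' Beep and button channels are 0.9 during their single-step pulse and 0.1
#' otherwise. The position channel ramps linearly from 0.1 to 0.9 with an
#' extra increment at the jump step, renormalized to exact endpoints. The
#' agency-judgment target interpolates linearly from 0.5 at the first step to
#' 0.9 ("yes") or 0.1 ("no") at the last; with `response = NA` the judgment
#' target is NA throughout (test sequences, where the model's output is read
#' instead).
#'
#' The jump step is the button-press step plus the latency (action-linked
#' trials) or the beep step plus the offset (EPA trials); the press step is
#' the beep step plus the reaction time rounded to the nearest step.
#'
#' @param trial A list or one-row data.frame with `trial_type`,
#'   `condition_ms` and `rt_ms`.
#' @param response 1/0, `"yes"`/`"no"`, logical, or NA.
#' @param enc An [encoding_config()].
#' @return An object of class `soa_sequence`: list with `inputs` (T x 3
#'   matrix: beep, button, position), `targets` (T x 4: beep, button,
#'   position, soa), `events` (1-based step indices `beep_step`,
#'   `press_step`, `jump_step`), `trial_type`, `condition_ms`, `rt_ms`,
#'   `response`, `dt_ms`.
#' @export
encode_trial <- function(trial, response = trial$response,
                         enc = encoding_config()) {
  stopifnot(inherits(enc, "soa_encoding"))
  tt <- match.arg(trial$trial_type, c("action_linked", "epa"))
  T_ <- enc$n_steps
  if (is.character(response)) response <- response == "yes"
  response <- if (is.na(response)) NA else as.logical(response)

  press_step <- enc$beep_step + rt_to_steps(trial$rt_ms, enc$dt_ms)
  jump_step <- if (tt == "action_linked") {
    press_step + trial$condition_ms %/% enc$dt_ms
  } else {
    enc$beep_step + trial$condition_ms %/% enc$dt_ms
  }
  ev <- c(beep_step = as.integer(enc$beep_step),
          press_step = as.integer(press_step),
          jump_step = as.integer(jump_step))
  bad <- names(ev)[ev < 1L | ev > T_]
  if (length(bad))
    stop("encoding error: event(s) outside the sequence window: ",
         paste(bad, collapse = ", "))

  lo <- 0.1; hi <- 0.9
  beep <- rep(lo, T_); beep[enc$beep_step] <- hi
  button <- rep(lo, T_); button[press_step] <- hi
  ramp <- seq(0, 1, length.out = T_) +
    enc$jump_increment * (seq_len(T_) >= jump_step)
  pos <- lo + (hi - lo) * (ramp - ramp[1]) / (ramp[T_] - ramp[1])

  soa_end <- if (is.na(response)) NA_real_ else if (response) hi else lo
  soa <- if (is.na(soa_end)) rep(NA_real_, T_) else
    seq(0.5, soa_end, length.out = T_)

  inputs <- cbind(beep = beep, button = button, position = pos)
  targets <- cbind(beep = beep, button = button, position = pos, soa = soa)
  structure(list(inputs = inputs, targets = targets, events = ev,
                 trial_type = tt, condition_ms = trial$condition_ms,
                 rt_ms = trial$rt_ms, response = response,
                 dt_ms = enc$dt_ms),
            class = "soa_sequence")
}

#' Recover the latency condition from an encoded sequence's event times
#'
#' @param seq An `soa_sequence`.
#' @return The condition in ms implied by the event steps.
#' @export
decode_condition <- function(seq) {
  stopifnot(inherits(seq, "soa_sequence"))
  ev <- seq$events
  if (seq$trial_type == "action_linked")
    (ev[["jump_step"]] - ev[["press_step"]]) * seq$dt_ms
  else
    (ev[["jump_step"]] - ev[["beep_step"]]) * seq$dt_ms
}

#' Build the training set of one behavioral dataset
#'
#' One sequence per trial (140 under the default task), with the judgment
#' target set to the subject's recorded response.
#'
#' @param dataset An `soa_dataset`.
#' @param enc An [encoding_config()].
#' @return List of `soa_sequence`.
#' @export
build_training_set <- function(dataset, enc = encoding_config()) {
  stopifnot(inherits(dataset, "soa_dataset"))
  tr <- dataset$trials
  lapply(seq_len(nrow(tr)), function(i) {
    tryCatch(encode_trial(tr[i, ], response = tr$response[i], enc = enc),
             error = function(e)
               stop("trial ", tr$trial_index[i], ": ", conditionMessage(e)))
  })
}

#' Build a reproduction-test set for one subject profile
#'
#' `n_per_condition` sequences per task condition (default 100, i.e. 1400
#' sequences over the 14 conditions), shuffled, with reaction times resampled
#' from the subject's normal RT distribution. Judgment targets are NA: at
#' test time the model's judgment output is read, not trained.
#'
#' @param profile An `soa_profile`.
#' @param n_per_condition Sequences per condition (default 100).
#' @param seed Integer seed for RT draws and the shuffle.
#' @param enc An [encoding_config()].
#' @return List of `soa_sequence`.
#' @export
build_test_set <- function(profile, n_per_condition = 100L, seed = 1L,
                           enc = encoding_config()) {
  stopifnot(inherits(profile, "soa_profile"), n_per_condition >= 1L)
  grid <- condition_grid()
  grid <- grid[rep(seq_len(nrow(grid)), each = n_per_condition), ]
  set.seed(as.integer(seed))
  grid <- grid[sample.int(nrow(grid)), ]
  grid$rt_ms <- draw_rts(nrow(grid), profile$rt_mean_ms, profile$rt_sd_ms)
  lapply(seq_len(nrow(grid)), function(i)
    encode_trial(grid[i, ], response = NA, enc = enc))
}
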