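## R surface over the compiled continuous-time RNN. The network has three
## input units (beep, button, object position), ten recurrently connected
## context units (every context unit projects to every context unit,
## including itself) and four output units (predictions of the three inputs
## plus the agency judgment). Inputs and outputs are connected only via the
## context units.

#' Construct (or initialize) the network parameters
#'
#' Leaky-integrator dynamics with time constant `tau` (default 10.0) and
#' sigmoid gain `gain` (default 1.0):
#' `u_i(t) = (1 - 1/tau) u_i(t-1) + (1/tau) [sum_j Wcx[i,j] x_j(t) +
#' sum_k Wcc[i,k] c_k(t-1)]`, `c_i(t) = f(u_i(t))` with
#' `f(u) = 1/(1 + exp(-gain * u))`; outputs read context activations from
#' the previous step: `o_i(t) = f(sum_j Woc[i,j] c_j(t-1))`.
#'
#' @param n_context,n_input,n_output Unit counts (defaults 10, 3, 4).
#' @param tau Membrane time constant, >= 1 (default 10).
#' @param gain Sigmoid gain, > 0 (default 1).
#' @param W_cx,W_cc,W_oc Optional explicit weight matrices
#'   (context x input, context x context, output x context). When omitted
#'   they are drawn uniformly from `[-init_scale, init_scale]` using `seed`.
#' @param init_scale Half-width of the uniform initialization (default 0.1).
#' @param seed Integer seed for the initialization draw.
#' @param meta Optional named list of provenance metadata kept through
#'   serialization (e.g. training seed, source subject id).
#' @return An object of class `rnn_params`.
#' @export
rnn_params <- function(n_context = 10L, n_input = 3L, n_output = 4L,
                       tau = 10, gain = 1, W_cx = NULL, W_cc = NULL,
                       W_oc = NULL, init_scale = 0.1, seed = NULL,
                       meta = list()) {
  if (tau < 1) stop("tau must be >= 1")
  if (gain <= 0) stop("gain must be > 0")
  if (is.null(W_cx) || is.null(W_cc) || is.null(W_oc)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    W_cx <- W_cx %||% matrix(runif(n_context * n_input, -init_scale,
                                   init_scale), n_context, n_input)
    W_cc <- W_cc %||% matrix(runif(n_context * n_context, -init_scale,
                                   init_scale), n_context, n_context)
    W_oc <- W_oc %||% matrix(runif(n_output * n_context, -init_scale,
                                   init_scale), n_output, n_context)
  }
  W_cx <- as.matrix(W_cx); W_cc <- as.matrix(W_cc); W_oc <- as.matrix(W_oc)
  storage.mode(W_cx) <- "double"
  storage.mode(W_cc) <- "double"
  storage.mode(W_oc) <- "double"
  tau <- as.numeric(tau); gain <- as.numeric(gain)
  stopifnot(nrow(W_cx) == nrow(W_cc), ncol(W_cc) == nrow(W_cc),
            ncol(W_oc) == nrow(W_cc))
  if (!all(is.finite(W_cx), is.finite(W_cc), is.finite(W_oc)))
    stop("weights must be finite")
  structure(list(W_cx = W_cx, W_cc = W_cc, W_oc = W_oc,
                 tau = tau, gain = gain,
                 n_context = nrow(W_cc), n_input = ncol(W_cx),
                 n_output = nrow(W_oc), meta = meta),
            class = "rnn_params")
}

#' Sigmoid activation with gain
#'
#' `f(u) = 1 / (1 + exp(-gain * u))`.
#'
#' @param u Membrane potential(s).
#' @param gain Gain parameter `a` (> 0).
#' @return Activation value(s) in `(0, 1)`.
#' @export
activation <- function(u, gain = 1) plogis(gain * u)

#' Simulated-lesion configuration
#'
#' Lesions modify only the run-time dynamics; weights are never changed.
#'
#' * `td_context`: the recurrent read of each context unit uses
#'   `c(t-1-D_i)` with `D_i ~ Bernoulli(delta_prob)` resampled per receiving
#'   unit per step (temporal delay in predictive signal transduction).
#' * `noise`: every membrane potential is multiplied by `(1 + eta)` with
#'   `eta` zero-mean uniform on `[-noise_level, noise_level]` (or gaussian
#'   with SD `noise_level`), resampled per unit per step.
#' * `td_output`: only the judgment output unit reads `c(t-1-D)`, one
#'   `D ~ Bernoulli(delta_prob)` per step.
#' * `td_input`: each input channel is read as `x_j(t-D_j)`,
#'   `D_j ~ Bernoulli(delta_prob)` per channel per step.
#' * `reduced_gain`: the sigmoid gain is replaced by `gain_value`
#'   everywhere.
#'
#' @param kind One of `"none"`, `"td_context"`, `"noise"`, `"td_output"`,
#'   `"td_input"`, `"reduced_gain"`.
#' @param delta_prob Probability that a delay draw is 1 (default 0.5).
#' @param noise_level Noise amplitude (default 0.01).
#' @param noise_dist `"uniform"` (default) or `"gaussian"`.
#' @param gain_value Replacement gain for `reduced_gain` (e.g. 0.99, 0.9,
#'   0.5); required for that kind.
#' @param seed Optional integer seed for the lesion's own RNG stream.
#' @return An object of class `lesion_config`.
#' @export
lesion_config <- function(kind = c("none", "td_context", "noise",
                                   "td_output", "td_input", "reduced_gain"),
                          delta_prob = 0.5, noise_level = 0.01,
                          noise_dist = c("uniform", "gaussian"),
                          gain_value = NULL, seed = NULL) {
  kind <- match.arg(kind)
  noise_dist <- match.arg(noise_dist)
  if (delta_prob < 0 || delta_prob > 1) stop("delta_prob must be in [0, 1]")
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (kind == "reduced_gain") {
    if (is.null(gain_value)) stop("reduced_gain requires gain_value")
    if (gain_value <= 0) stop("gain_value must be > 0")
  }
  structure(list(kind = kind, delta_prob = delta_prob,
                 noise_level = noise_level, noise_dist = noise_dist,
                 gain_value = gain_value, seed = seed),
            class = "lesion_config")
}

lesion_kind_code <- function(lesion) {
  switch(lesion$kind, none = 0L, td_context = 1L, noise = 2L,
         td_output = 3L, td_input = 4L, reduced_gain = 0L)
}

lesion_is_stochastic <- function(lesion) {
  lesion$kind %in% c("td_context", "td_output", "td_input") &&
    lesion$delta_prob > 0 ||
    (lesion$kind == "noise" && lesion$noise_level > 0)
}

effective_gain <- function(params, lesion) {
  if (lesion$kind == "reduced_gain") lesion$gain_value else params$gain
}

#' Run the network over one sensorimotor sequence
#'
#' Inputs are the task's actual sensory signals at every step (outputs are
#' never fed back). The judgment is decoded from the final-step value of the
#' fourth output channel: strictly above 0.5 counts as "yes".
#'
#' @param params An [rnn_params()].
#' @param seq An `soa_sequence` (or a plain T x 3 input matrix).
#' @param lesion A [lesion_config()] (default: no lesion). If it carries a
#'   `seed`, the RNG is seeded before the run.
#' @return An object of class `rnn_trajectory`: list with `U`, `C` (T x
#'   n_context), `O` (T x n_output), `final_soa`, logical `judgment`, and
#'   the sequence's `events`, `trial_type`, `condition_ms` when available.
#' @export
run_sequence <- function(params, seq, lesion = lesion_config("none")) {
  stopifnot(inherits(params, "rnn_params"), inherits(lesion, "lesion_config"))
  X <- if (inherits(seq, "soa_sequence")) seq$inputs else as.matrix(seq)
  if (nrow(X) < 1L) stop("sequence must have at least one step")
  if (!is.null(lesion$seed)) set.seed(as.integer(lesion$seed))
  res <- ctrnn_forward_cpp(params$W_cx, params$W_cc, params$W_oc,
                           params$tau, effective_gain(params, lesion), X,
                           lesion_kind_code(lesion), lesion$delta_prob,
                           lesion$noise_level,
                           lesion$noise_dist == "gaussian",
                           params$n_output - 1L)
  soa <- res$O[nrow(X), params$n_output]
  structure(list(U = res$U, C = res$C, O = res$O, final_soa = soa,
                 judgment = soa > 0.5,
                 events = if (inherits(seq, "soa_sequence")) seq$events,
                 trial_type = if (inherits(seq, "soa_sequence")) seq$trial_type,
                 condition_ms = if (inherits(seq, "soa_sequence"))
                   seq$condition_ms),
            class = "rnn_trajectory")
}

#' Run the network over a batch of sequences
#'
#' @param params An [rnn_params()].
#' @param seqs List of `soa_sequence`.
#' @param lesion A [lesion_config()].
#' @param seed Optional seed set once before the whole batch (overrides
#'   `lesion$seed`).
#' @return A data.frame with one row per sequence: `trial_type`,
#'   `condition_ms`, `rt_ms`, `final_soa`, logical `judgment`; the matrix of
#'   context activations at the step immediately before the jump is attached
#'   as attribute `"prejump"` (rows = sequences).
#' @export
run_sequences <- function(params, seqs, lesion = lesion_config("none"),
                          seed = lesion$seed) {
  stopifnot(length(seqs) >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lesion_local <- lesion
  lesion_local$seed <- NULL  # seed once for the batch, not per sequence
  n <- length(seqs)
  prejump <- matrix(NA_real_, n, params$n_context)
  out <- data.frame(trial_type = character(n), condition_ms = numeric(n),
                    rt_ms = numeric(n), final_soa = numeric(n),
                    judgment = logical(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- run_sequence(params, seqs[[i]], lesion_local)
    out$trial_type[i] <- seqs[[i]]$trial_type
    out$condition_ms[i] <- seqs[[i]]$condition_ms
    out$rt_ms[i] <- seqs[[i]]$rt_ms
    out$final_soa[i] <- tr$final_soa
    out$judgment[i] <- tr$judgment
    js <- seqs[[i]]$events[["jump_step"]]
    prejump[i, ] <- if (js > 1L) tr$C[js - 1L, ] else rep(0.5, params$n_context)
  }
  attr(out, "prejump") <- prejump
  out
}

#' Serialize network parameters to / from JSON
#'
#' A plain-text container holding the named weight matrices `W_cx`, `W_cc`,
#' `W_oc`, the scalars `tau` and `gain`, and any provenance metadata. The
#' round trip is bit-exact (digits are not truncated).
#'
#' @param params An [rnn_params()].
#' @param path Output file path.
#' @return `path` invisibly; `read_rnn_json` returns the `rnn_params`.
#' @export
write_rnn_json <- function(params, path) {
  stopifnot(inherits(params, "rnn_params"))
  obj <- list(W_cx = params$W_cx, W_cc = params$W_cc, W_oc = params$W_oc,
              tau = params$tau, gain = params$gain, meta = params$meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rnn_json
#' @export
read_rnn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rnn_params(W_cx = obj$W_cx, W_cc = obj$W_cc, W_oc = obj$W_oc,
             tau = as.numeric(obj$tau), gain = as.numeric(obj$gain),
             meta = as.list(obj$meta %||% list()))
}
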