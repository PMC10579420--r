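# Deliberately naive, loop-based re-implementation of the leaky-integrator
# dynamics, independent of the compiled path. Histories before the first
# step: u = 0, c = 0.5, x = 0.1.
oracle_forward <- function(params, X, gain = params$gain) {
  T_ <- nrow(X)
  n_c <- params$n_context
  n_out <- params$n_output
  f <- function(u) 1 / (1 + exp(-gain * u))
  U <- matrix(0, T_, n_c); C <- matrix(0, T_, n_c); O <- matrix(0, T_, n_out)
  u_prev <- rep(0, n_c)
  c_prev <- rep(0.5, n_c)
  for (t in seq_len(T_)) {
    for (i in seq_len(n_out)) {
      s <- 0
      for (j in seq_len(n_c)) s <- s + params$W_oc[i, j] * c_prev[j]
      O[t, i] <- f(s)
    }
    u_new <- numeric(n_c)
    for (i in seq_len(n_c)) {
      s <- 0
      for (j in seq_len(ncol(X))) s <- s + params$W_cx[i, j] * X[t, j]
      for (k in seq_len(n_c)) s <- s + params$W_cc[i, k] * c_prev[k]
      u_new[i] <- (1 - 1 / params$tau) * u_prev[i] + s / params$tau
    }
    U[t, ] <- u_new
    c_prev <- f(u_new)
    C[t, ] <- c_prev
    u_prev <- u_new
  }
  list(U = U, C = C, O = O)
}

# Brute-force Mann-Whitney U: count of (x, y) pairs with x > y, plus half
# the ties.
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# Brute-force Spearman rho: Pearson correlation of the rank vectors.
brute_force_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

random_params <- function(seed, n_context = 5L, n_input = 3L, n_output = 4L,
                          scale = 1) {
  rnn_params(n_context = n_context, n_input = n_input, n_output = n_output,
             seed = seed, init_scale = scale)
}

random_inputs <- function(seed, T_ = 12L, n_input = 3L) {
  set.seed(seed)
  matrix(runif(T_ * n_input, 0.1, 0.9), T_, n_input)
}

default_profile <- function(subject_id = "Hx") {
  subject_profile(subject_id, inflection_ms = 500, slope = 0.01,
                  upper_asymptote = 0.95, lower_asymptote = 0.05,
                  epa_yes_prob = c(0.2, 0.2, 0.2),
                  rt_mean_ms = 350, rt_sd_ms = 50)
}

make_trial <- function(trial_type = "action_linked", condition_ms = 300,
                       rt_ms = 350) {
  list(trial_type = trial_type, condition_ms = condition_ms, rt_ms = rt_ms)
}
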