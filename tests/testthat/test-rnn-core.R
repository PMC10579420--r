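test_that("activation is the gained sigmoid", {
  expect_equal(activation(0), 0.5)
  expect_equal(activation(0, gain = 7), 0.5)
  u <- seq(-5, 5, by = 0.5)
  expect_equal(activation(u) + activation(-u), rep(1, length(u)))
  # frozen closed form: 1 / (1 + exp(-1)) at a = 0.5, u = 2
  expect_equal(activation(2, gain = 0.5), 0.7310585786, tolerance = 1e-9)
  expect_true(all(diff(activation(u)) > 0))
})

test_that("compiled dynamics match the naive loop oracle", {
  for (s in 1:20) {
    params <- random_params(s)
    X <- random_inputs(s + 100, T_ = 15L)
    tr <- run_sequence(params, X)
    or <- oracle_forward(params, X)
    expect_equal(tr$U, or$U, tolerance = 1e-12)
    expect_equal(tr$C, or$C, tolerance = 1e-12)
    expect_equal(tr$O, or$O, tolerance = 1e-12)
  }
  # and for non-unit gain
  params <- rnn_params(n_context = 6, seed = 3, gain = 0.5, init_scale = 1)
  X <- random_inputs(9, T_ = 10L)
  expect_equal(run_sequence(params, X)$O, oracle_forward(params, X)$O,
               tolerance = 1e-12)
})

test_that("leaky integration follows its closed form", {
  # constant bracketed input s: u(t) = s * (1 - (1 - 1/tau)^t)
  params <- rnn_params(n_context = 2, n_input = 1, n_output = 1,
                       W_cx = matrix(c(2, 0.5), 2, 1),
                       W_cc = matrix(0, 2, 2), W_oc = matrix(0, 1, 2),
                       tau = 10)
  X <- matrix(0.5, 20, 1)
  tr <- run_sequence(params, X)
  s_in <- c(2, 0.5) * 0.5
  for (t in 1:20)
    expect_equal(tr$U[t, ], s_in * (1 - 0.9^t), tolerance = 1e-12)
  # first step from rest with bracketed input 1 gives u = 1/tau
  params1 <- rnn_params(n_context = 1, n_input = 1, n_output = 1,
                        W_cx = matrix(2, 1, 1), W_cc = matrix(0, 1, 1),
                        W_oc = matrix(0, 1, 1), tau = 10)
  tr1 <- run_sequence(params1, matrix(0.5, 3, 1))
  expect_equal(tr1$U[1, 1], 0.1, tolerance = 1e-14)
})

test_that("activations and outputs stay inside (0, 1); zero weights give 0.5", {
  params <- random_params(5, scale = 8)
  X <- random_inputs(6)
  tr <- run_sequence(params, X)
  expect_true(all(tr$C > 0 & tr$C < 1))
  expect_true(all(tr$O > 0 & tr$O < 1))
  z <- rnn_params(W_cx = matrix(0, 10, 3), W_cc = matrix(0, 10, 10),
                  W_oc = matrix(0, 4, 10))
  expect_true(all(run_sequence(z, X)$O == 0.5))
})

test_that("degenerate lesions are bit-identical to the unlesioned run", {
  for (s in 1:10) {
    params <- random_params(s + 40, n_context = 10L)
    X <- random_inputs(s + 400, T_ = 12L)
    base <- run_sequence(params, X)
    for (les in list(lesion_config("td_context", delta_prob = 0, seed = 1),
                     lesion_config("td_output", delta_prob = 0, seed = 1),
                     lesion_config("td_input", delta_prob = 0, seed = 1),
                     lesion_config("noise", noise_level = 0, seed = 1),
                     lesion_config("reduced_gain", gain_value = 1))) {
      tr <- run_sequence(params, X, les)
      expect_identical(tr$U, base$U)
      expect_identical(tr$O, base$O)
    }
  }
})

test_that("runs are deterministic: seeded lesions and lesion-free reruns", {
  params <- random_params(2)
  X <- random_inputs(3)
  les <- lesion_config("td_context", seed = 77)
  expect_identical(run_sequence(params, X, les)$O,
                   run_sequence(params, X, les)$O)
  # no stochasticity without a lesion, whatever the RNG state
  set.seed(1); a <- run_sequence(params, X)
  set.seed(99); b <- run_sequence(params, X)
  expect_identical(a$O, b$O)
  # a stochastic lesion with different seeds differs
  les2 <- lesion_config("td_context", seed = 78)
  expect_false(identical(run_sequence(params, X, les)$O,
                         run_sequence(params, X, les2)$O))
})

test_that("lesion configs validate their parameters", {
  expect_error(lesion_config("reduced_gain"), "gain_value")
  expect_error(lesion_config("noise", noise_level = -1), "noise_level")
  expect_error(lesion_config("td_context", delta_prob = 2), "delta_prob")
  expect_error(lesion_config("banana"))
})

test_that("weight serialization round-trips bit-exactly", {
  params <- random_params(11, n_context = 10L)
  params$meta <- list(training_seed = 42L, subject_id = "H03")
  f <- tempfile(fileext = ".json")
  write_rnn_json(params, f)
  back <- read_rnn_json(f)
  expect_identical(back$W_cx, params$W_cx)
  expect_identical(back$W_cc, params$W_cc)
  expect_identical(back$W_oc, params$W_oc)
  expect_identical(back$tau, params$tau)
  expect_identical(back$gain, params$gain)
  expect_equal(back$meta$subject_id, "H03")
})
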