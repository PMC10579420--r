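test_that("encoded channels respect the 0.1-0.9 coding conventions", {
  enc <- encoding_config()
  s <- encode_trial(make_trial(condition_ms = 300, rt_ms = 350), "yes", enc)
  expect_true(all(s$inputs >= 0.1 & s$inputs <= 0.9))
  expect_true(all(s$inputs[, "beep"] %in% c(0.1, 0.9)))
  expect_true(all(s$inputs[, "button"] %in% c(0.1, 0.9)))
  # single-step pulses at the right steps
  expect_identical(which(s$inputs[, "beep"] == 0.9), 3L)
  expect_identical(which(s$inputs[, "button"] == 0.9), 7L)  # beep 3 + round(350/100)
  # position: exact endpoints, non-decreasing, with the jump increment
  pos <- s$inputs[, "position"]
  expect_equal(pos[1], 0.1)
  expect_equal(pos[length(pos)], 0.9)
  expect_true(all(diff(pos) >= 0))
  expect_identical(which.max(diff(pos)) + 1L,
                   unname(s$events[["jump_step"]]))
  # judgment target: neutral start, response-coded end
  expect_equal(unname(s$targets[1, "soa"]), 0.5)
  expect_equal(unname(s$targets[nrow(s$targets), "soa"]), 0.9)
  sn <- encode_trial(make_trial(), "no", enc)
  expect_equal(unname(sn$targets[nrow(sn$targets), "soa"]), 0.1)
  # sensory targets are the inputs themselves (one-step prediction)
  expect_identical(s$targets[, c("beep", "button", "position")], s$inputs)
})

test_that("no-beep windows stay at baseline and NA responses blank the target", {
  s <- encode_trial(make_trial(), NA)
  expect_true(all(is.na(s$targets[, "soa"])))
  beep <- s$inputs[, "beep"]
  expect_true(all(beep[-s$events[["beep_step"]]] == 0.1))
})

test_that("event timing arithmetic covers the whole condition grid", {
  enc <- encoding_config()
  # zero latency: jump coincides with the press
  s0 <- encode_trial(make_trial(condition_ms = 0), "yes", enc)
  expect_identical(s0$events[["jump_step"]], s0$events[["press_step"]])
  # round-trip: every condition decodes exactly
  grid <- condition_grid()
  for (i in seq_len(nrow(grid))) {
    tr <- make_trial(grid$trial_type[i], grid$condition_ms[i], rt_ms = 420)
    s <- encode_trial(tr, "yes", enc)
    expect_identical(decode_condition(s), as.numeric(grid$condition_ms[i]))
  }
  # EPA offsets are beep-locked
  sm <- encode_trial(make_trial("epa", -100, 350), "no", enc)
  expect_identical(sm$events[["jump_step"]], sm$events[["beep_step"]] - 1L)
  # events outside the window raise a named encoding error
  expect_error(encode_trial(make_trial(condition_ms = 1000, rt_ms = 2500),
                            "yes", enc), "jump_step")
})

test_that("RT rounding is to the nearest step with ties up", {
  expect_identical(soasim:::rt_to_steps(349, 100), 3L)
  expect_identical(soasim:::rt_to_steps(350, 100), 4L)
  expect_identical(soasim:::rt_to_steps(50, 100), 1L)
})

test_that("training sets mirror the dataset trial for trial", {
  d <- generate_behavioral_dataset(default_profile(), 5)
  seqs <- build_training_set(d)
  expect_length(seqs, 140)
  ends <- vapply(seqs, function(s) s$targets[nrow(s$targets), "soa"], 0)
  expect_identical(unname(ends), ifelse(d$trials$response == 1, 0.9, 0.1))
  conds <- vapply(seqs, decode_condition, 0)
  expect_identical(unname(conds), as.numeric(d$trials$condition_ms))
})

test_that("test sets are balanced, shuffled and reproducible", {
  p <- default_profile()
  ts <- build_test_set(p, 100, seed = 2)
  expect_length(ts, 1400)
  conds <- table(vapply(ts, function(s) paste(s$trial_type, s$condition_ms), ""))
  expect_true(all(conds == 100))
  expect_length(build_test_set(p, 1, seed = 2), 14)
  rt1 <- vapply(build_test_set(p, 5, seed = 7), `[[`, 0, "rt_ms")
  rt2 <- vapply(build_test_set(p, 5, seed = 7), `[[`, 0, "rt_ms")
  expect_identical(rt1, rt2)
  # judgment targets absent at test time
  expect_true(all(is.na(ts[[1]]$targets[, "soa"])))
})
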