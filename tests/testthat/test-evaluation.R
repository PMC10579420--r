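make_runs <- function(rates, n = 10L) {
  # build a runs data.frame whose per-condition yes fractions equal `rates`
  grid <- condition_grid()
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    k <- round(rates[i] * n)
    data.frame(trial_type = grid$trial_type[i],
               condition_ms = grid$condition_ms[i],
               judgment = rep(c(TRUE, FALSE), c(k, n - k)))
  }))
}

flat_curve <- function(r) {
  grid <- condition_grid()
  soa_curve(grid$trial_type, grid$condition_ms, rep(r, nrow(grid)))
}

test_that("yes-rate curves count strict-majority judgments per condition", {
  rates <- c(seq(1, 0, length.out = 11), 0.2, 0.3, 0.4)
  cur <- yes_rate_curve(make_runs(rates, n = 10L))
  expect_equal(cur$yes_rate, rates, tolerance = 1e-12)
  expect_true(all(cur$n_trials == 10L))
  # missing condition is a named error
  runs <- make_runs(rates)
  expect_error(yes_rate_curve(runs[runs$condition_ms != 400 |
                                     runs$trial_type != "action_linked", ]),
               "400")
  # a final output of exactly 0.5 is "no" under the strict rule
  params <- rnn_params(W_cx = matrix(0, 10, 3), W_cc = matrix(0, 10, 10),
                       W_oc = matrix(0, 4, 10))
  s <- encode_trial(make_trial(), "yes")
  expect_identical(run_sequence(params, s)$judgment, FALSE)
})

test_that("window summaries are unweighted 3-condition means", {
  grid <- condition_grid()
  rates <- rep(0, 14)
  rates[grid$trial_type == "action_linked" &
          grid$condition_ms %in% c(0, 100, 200)] <- c(0.9, 0.8, 0.7)
  rates[grid$trial_type == "action_linked" &
          grid$condition_ms %in% c(800, 900, 1000)] <- 1
  ws <- window_summary(soa_curve(grid$trial_type, grid$condition_ms, rates))
  expect_equal(ws$short_avg, 0.8)
  expect_equal(ws$long_avg, 1)
  wsc <- window_summary(flat_curve(0.37))
  expect_equal(wsc$short_avg, 0.37)
  expect_equal(wsc$long_avg, 0.37)
})

test_that("rate histograms normalize and bin edges go to the upper bin", {
  d <- rate_distribution(rep(1, 5))
  expect_equal(sum(d$probabilities), 1)
  expect_equal(d$probabilities[11], 1)
  d2 <- rate_distribution(c(0, 1))
  expect_equal(d2$probabilities[c(1, 11)], c(0.5, 0.5))
  # an interior edge value lands in the bin above it
  d3 <- rate_distribution(1 / 11, bins = 11L)
  expect_equal(d3$probabilities[2], 1)
  expect_error(rate_distribution(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  v <- runif(1000)
  du <- rate_distribution(v)
  se <- sqrt((1 / 11) * (10 / 11) / 1000)
  expect_true(all(abs(du$probabilities - 1 / 11) < 3 * se))
})

test_that("distribution MSE matches hand-computed cases and is symmetric", {
  p <- rate_distribution(c(0.2, 0.3), bins = 2L)  # (1, 0)
  q <- rate_distribution(c(0.7, 0.8), bins = 2L)  # (0, 1)
  expect_equal(mse_distributions(p, q), 1)
  expect_equal(mse_distributions(p, p), 0)
  expect_equal(mse_distributions(p, q), mse_distributions(q, p))
  expect_error(mse_distributions(p, rate_distribution(0.5, bins = 3L)),
               "mismatched")
})

test_that("KL divergence is smoothed, directional, and non-negative", {
  p <- rate_distribution(c(0.2, 0.7), bins = 2L)    # (0.5, 0.5)
  q <- rate_distribution(c(rep(0.2, 9), 0.7), bins = 2L)  # (0.9, 0.1)
  expect_equal(kl_distributions(p, p), 0)
  # frozen hand evaluation of the smoothed formula
  eps <- 1e-6
  ps <- (c(0.5, 0.5) + eps) / (1 + 2 * eps)
  qs <- (c(0.9, 0.1) + eps) / (1 + 2 * eps)
  expect_equal(kl_distributions(p, q), sum(ps * log(ps / qs)),
               tolerance = 1e-12)
  expect_equal(kl_distributions(p, q), 0.510822068234, tolerance = 1e-9)
  # directional: the two orders disagree on an asymmetric pair
  expect_false(isTRUE(all.equal(kl_distributions(p, q),
                                kl_distributions(q, p))))
  set.seed(2)
  for (i in 1:20) {
    a <- rate_distribution(runif(20))
    b <- rate_distribution(runif(20))
    expect_gte(kl_distributions(a, b), 0)
  }
})

test_that("classification implements the windowed change score", {
  h <- flat_curve(0.5)
  expect_identical(classify_m_subject(h, h)$label, "no_change")
  expect_equal(classify_m_subject(h, h)$Y_short, 0)
  grid <- condition_grid()
  short <- grid$trial_type == "action_linked" & grid$condition_ms <= 200
  long <- grid$trial_type == "action_linked" & grid$condition_ms >= 800
  # healthy short (1,1,1) -> lesioned (0.5,0.5,0.5): Y_short = -5
  healthy <- rep(0, 14); healthy[short] <- 1
  lesioned <- rep(0, 14); lesioned[short] <- 0.5
  mk <- function(r) soa_curve(grid$trial_type, grid$condition_ms, r)
  cl <- classify_m_subject(mk(lesioned), mk(healthy))
  expect_equal(cl$Y_short, -5)
  expect_identical(cl$label, "diminished")
  # healthy long (0,0,0) -> lesioned (0.6,0.6,0.6): Y_long = +6
  lesioned2 <- healthy; lesioned2[long] <- 0.6
  cl2 <- classify_m_subject(mk(lesioned2), mk(healthy))
  expect_equal(cl2$Y_long, 6)
  expect_identical(cl2$label, "excessive")
  # both shifts -> the schizophrenia pattern
  lesioned3 <- lesioned; lesioned3[long] <- 0.6
  expect_identical(classify_m_subject(mk(lesioned3), mk(healthy))$label,
                   "sz_pattern")
  # scale consistency: scaling rates-scale and thresholds together
  cl10 <- classify_m_subject(mk(lesioned3), mk(healthy),
                             thresholds = c(lower = -0.2, upper = 0.2),
                             scale = 1)
  expect_identical(cl10$label, "sz_pattern")
})

test_that("group curves average with correct standard errors", {
  grid <- condition_grid()
  mk <- function(r) soa_curve(grid$trial_type, grid$condition_ms, r)
  cs <- list(mk(rep(0.2, 14)), mk(rep(0.4, 14)), mk(rep(0.6, 14)))
  g <- group_curves(cs, c("a", "a", "a"))
  expect_equal(unique(g$mean_rate), 0.4)
  expect_equal(unique(g$se_rate), sd(c(0.2, 0.4, 0.6)) / sqrt(3))
  g1 <- group_curves(cs[1], "solo")
  expect_true(all(g1$se_rate == 0))
  g2 <- group_curves(cs[c(1, 1)], c("b", "b"))
  expect_true(all(g2$se_rate == 0) && all(g2$mean_rate == 0.2))
})

test_that("unit correlation report flags exactly the informative units", {
  # unit 1: constant -> never significant. unit 2: equals latency/1000 ->
  # perfect Spearman. unit 3: equals the judgment -> separates yes/no.
  n <- 220
  lat <- rep(seq(0, 1000, 100), each = 20)
  judge <- rep(c(TRUE, FALSE), n / 2)
  runs <- data.frame(trial_type = "action_linked", condition_ms = lat,
                     rt_ms = 300, final_soa = 0.5, judgment = judge)
  pj <- cbind(0.5, lat / 1000, ifelse(judge, 0.8, 0.2))
  attr(runs, "prejump") <- pj
  rep1 <- unit_correlation_report(list(runs))
  expect_identical(rep1$per_subject$n_soa_units, 1L)
  expect_identical(rep1$per_subject$n_latency_units, 1L)
  # spearman sanity against the brute-force rank formula
  set.seed(4)
  x <- runif(30); y <- x + rnorm(30, 0, 0.2)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(unname(ct$estimate), brute_force_spearman(x, y),
               tolerance = 1e-12)
})
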