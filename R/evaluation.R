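## Summary statistics: yes-rate curves, short/long latency-window averages,
## histogram distances (MSE, KL), the bidirectional excessive/diminished
## classification, and context-unit functional correlation reports.

short_window <- function() c(0, 100, 200)
long_window <- function() c(800, 900, 1000)

#' Construct a yes-rate curve
#'
#' @param trial_type,condition_ms,yes_rate,n_trials Parallel vectors, one
#'   entry per condition; all 14 task conditions must be present.
#' @return An object of class `soa_curve` (a data.frame).
#' @export
soa_curve <- function(trial_type, condition_ms, yes_rate, n_trials = NA_integer_) {
  df <- data.frame(trial_type = as.character(trial_type),
                   condition_ms = as.numeric(condition_ms),
                   yes_rate = as.numeric(yes_rate),
                   n_trials = n_trials, stringsAsFactors = FALSE)
  grid <- condition_grid()
  key <- paste(df$trial_type, df$condition_ms)
  want <- paste(grid$trial_type, grid$condition_ms)
  missing <- setdiff(want, key)
  if (length(missing))
    stop("yes-rate curve is missing condition(s): ",
         paste(missing, collapse = ", "))
  df <- df[match(want, key), ]
  rownames(df) <- NULL
  if (any(df$yes_rate < 0 | df$yes_rate > 1, na.rm = TRUE))
    stop("yes rates must lie in [0, 1]")
  class(df) <- c("soa_curve", "data.frame")
  df
}

#' Yes-rate curve from a batch of model runs
#'
#' A run counts as "yes" iff its final-step judgment output is strictly
#' greater than 0.5 (the neutral starting value of the judgment channel).
#'
#' @param runs A data.frame from [run_sequences()] (columns `trial_type`,
#'   `condition_ms`, `judgment`).
#' @return An `soa_curve`.
#' @export
yes_rate_curve <- function(runs) {
  grid <- condition_grid()
  rate <- numeric(nrow(grid))
  n <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sel <- runs$trial_type == grid$trial_type[i] &
      runs$condition_ms == grid$condition_ms[i]
    n[i] <- sum(sel)
    if (n[i] == 0L)
      stop("no runs for condition ", grid$trial_type[i], " ",
           grid$condition_ms[i])
    rate[i] <- mean(runs$judgment[sel])
  }
  soa_curve(grid$trial_type, grid$condition_ms, rate, n_trials = n)
}

#' Mean yes rates over the short and long latency windows
#'
#' Unweighted means over the 0/100/200 ms (short) and 800/900/1000 ms (long)
#' action-linked conditions.
#'
#' @param curve An `soa_curve`.
#' @return List with `short_avg` and `long_avg`.
#' @export
window_summary <- function(curve) {
  stopifnot(inherits(curve, "soa_curve"))
  al <- curve[curve$trial_type == "action_linked", ]
  list(short_avg = mean(al$yes_rate[al$condition_ms %in% short_window()]),
       long_avg = mean(al$yes_rate[al$condition_ms %in% long_window()]))
}

#' Normalized histogram of window-averaged yes rates
#'
#' Values on an interior bin edge go to the upper bin; 1.0 goes to the last
#' bin.
#'
#' @param values Numeric vector of values in `[0, 1]`.
#' @param bins Number of equal bins on `[0, 1]` (default 11).
#' @return An object of class `soa_distribution`: list with `bin_edges` and
#'   `probabilities` (summing to 1).
#' @export
rate_distribution <- function(values, bins = 11L) {
  if (length(values) < 1L) stop("need at least one value")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  idx <- pmin(floor(values * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  structure(list(bin_edges = seq(0, 1, length.out = bins + 1L),
                 probabilities = counts / sum(counts)),
            class = "soa_distribution")
}

check_same_bins <- function(p, q) {
  stopifnot(inherits(p, "soa_distribution"), inherits(q, "soa_distribution"))
  if (length(p$bin_edges) != length(q$bin_edges) ||
      any(p$bin_edges != q$bin_edges))
    stop("distributions have mismatched bin edges")
}

#' Mean squared error between two binned distributions
#'
#' @param p,q `soa_distribution` objects on identical bins.
#' @return Mean over bins of the squared probability difference.
#' @export
mse_distributions <- function(p, q) {
  check_same_bins(p, q)
  mean((p$probabilities - q$probabilities)^2)
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' `KL(P || Q)` with `P` the data/reference distribution and `Q` the
#' model/lesion distribution. Both are smoothed by adding `eps` to every bin
#' and renormalizing, so empty bins are well defined.
#'
#' @param p Reference distribution (`P`).
#' @param q Model distribution (`Q`).
#' @param eps Additive smoothing constant (default 1e-6).
#' @return Non-negative divergence.
#' @export
kl_distributions <- function(p, q, eps = 1e-6) {
  check_same_bins(p, q)
  ps <- p$probabilities + eps; ps <- ps / sum(ps)
  qs <- q$probabilities + eps; qs <- qs / sum(qs)
  sum(ps * log(ps / qs))
}

#' Short/long-window distribution distance between two cohorts
#'
#' Builds the short- and long-window histograms of both cohorts of curves
#' and returns the MSE and KL averaged over the two windows (one number per
#' index per comparison).
#'
#' @param ref_curves,model_curves Lists of `soa_curve` (reference first; the
#'   reference is the `P` of the KL direction).
#' @param bins Number of histogram bins (default 11).
#' @return List with `mse`, `kl`, and the four component distributions.
#' @export
distribution_distance <- function(ref_curves, model_curves, bins = 11L) {
  ws_ref <- lapply(ref_curves, window_summary)
  ws_mod <- lapply(model_curves, window_summary)
  d <- function(vals) rate_distribution(vals, bins)
  ref_s <- d(vapply(ws_ref, `[[`, 0, "short_avg"))
  ref_l <- d(vapply(ws_ref, `[[`, 0, "long_avg"))
  mod_s <- d(vapply(ws_mod, `[[`, 0, "short_avg"))
  mod_l <- d(vapply(ws_mod, `[[`, 0, "long_avg"))
  list(mse = mean(c(mse_distributions(ref_s, mod_s),
                    mse_distributions(ref_l, mod_l))),
       kl = mean(c(kl_distributions(ref_s, mod_s),
                   kl_distributions(ref_l, mod_l))),
       ref_short = ref_s, ref_long = ref_l,
       model_short = mod_s, model_long = mod_l)
}

#' Classify one lesioned model against its healthy baseline
#'
#' The change score over a window is the summed per-condition yes-rate
#' difference (lesioned minus healthy), on a count-equivalent scale (rates
#' multiplied by `scale`, default 10, the behavioral repetition count),
#' divided by 3: `Y = sum_j (x_lesioned[j] - x_healthy[j]) * scale / 3`.
#' With the default thresholds a score of +/-2 corresponds to a 0.2 mean
#' rate change. Labels: `excessive` iff `Y_long > upper`, `diminished` iff
#' `Y_short < lower`, `sz_pattern` iff both, otherwise `no_change`.
#'
#' @param lesioned,healthy `soa_curve` objects for the same model.
#' @param thresholds Named numeric `c(lower = -2, upper = 2)`.
#' @param scale Rate multiplier before scoring (default 10).
#' @return An object of class `soa_classification`: list with `Y_short`,
#'   `Y_long`, `label`.
#' @export
classify_m_subject <- function(lesioned, healthy,
                               thresholds = c(lower = -2, upper = 2),
                               scale = 10) {
  stopifnot(inherits(lesioned, "soa_curve"), inherits(healthy, "soa_curve"))
  dy <- function(window) {
    l <- lesioned[lesioned$trial_type == "action_linked" &
                    lesioned$condition_ms %in% window, "yes_rate"]
    h <- healthy[healthy$trial_type == "action_linked" &
                   healthy$condition_ms %in% window, "yes_rate"]
    sum((l - h) * scale) / 3
  }
  y_short <- dy(short_window())
  y_long <- dy(long_window())
  exc <- y_long > thresholds[["upper"]]
  dim_ <- y_short < thresholds[["lower"]]
  label <- if (exc && dim_) "sz_pattern" else if (exc) "excessive" else
    if (dim_) "diminished" else "no_change"
  structure(list(Y_short = y_short, Y_long = y_long, label = label),
            class = "soa_classification")
}

#' Per-label mean and standard-error yes-rate curves
#'
#' @param curves List of `soa_curve`.
#' @param labels Character vector of group labels, parallel to `curves`.
#' @return A data.frame with columns `label`, `trial_type`, `condition_ms`,
#'   `mean_rate`, `se_rate`, `n`; groups with no members are simply absent.
#' @export
group_curves <- function(curves, labels) {
  stopifnot(length(curves) == length(labels))
  out <- list()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    mat <- sapply(curves[idx], function(cu) cu$yes_rate)
    mat <- matrix(mat, ncol = length(idx))
    grid <- condition_grid()
    se <- if (length(idx) > 1L) apply(mat, 1, sd) / sqrt(length(idx)) else
      rep(0, nrow(mat))
    out[[lab]] <- data.frame(label = lab, trial_type = grid$trial_type,
                             condition_ms = grid$condition_ms,
                             mean_rate = rowMeans(mat), se_rate = se,
                             n = length(idx), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

## Mann-Whitney U via the normal approximation with tie correction; returns
## U (for the first sample) and the two-sided p. Degenerate all-tied input
## yields p = 1 rather than an error.
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (sd(c(x, y)) == 0)
    return(list(statistic = u, p.value = 1))
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Context-unit functional correlation report
#'
#' For each model, each context unit's activation at the step immediately
#' before the piece jump is collected across action-linked test trials. Two
#' per-unit tests are run without multiple-testing correction: a two-sided
#' Mann-Whitney U between yes-judged and no-judged trials (alpha 0.05), and
#' a Spearman rank correlation of activation against the latency condition
#' (alpha 0.01).
#'
#' @param runs_list List (one element per model) of [run_sequences()]
#'   results carrying the `"prejump"` attribute.
#' @param alpha_soa,alpha_latency Significance levels (defaults 0.05, 0.01).
#' @return An object of class `soa_unit_report`: list with `per_subject` (a
#'   data.frame of per-model significant-unit counts, NA where a test was
#'   undefined), `mean_soa_units`, `mean_latency_units`.
#' @export
unit_correlation_report <- function(runs_list, alpha_soa = 0.05,
                                    alpha_latency = 0.01) {
  stats_one <- function(runs) {
    pj <- attr(runs, "prejump")
    al <- runs$trial_type == "action_linked"
    pj <- pj[al, , drop = FALSE]
    judge <- runs$judgment[al]
    lat <- runs$condition_ms[al]
    n_units <- ncol(pj)
    soa_sig <- NA_integer_
    if (length(unique(judge)) == 2L) {
      soa_sig <- 0L
      for (u in seq_len(n_units)) {
        act <- pj[, u]
        if (sd(act) == 0) next
        p <- mann_whitney_u(act[judge], act[!judge])$p.value
        if (is.finite(p) && p < alpha_soa) soa_sig <- soa_sig + 1L
      }
    }
    lat_sig <- 0L
    for (u in seq_len(n_units)) {
      act <- pj[, u]
      if (sd(act) == 0) next
      ct <- suppressWarnings(cor.test(act, lat, method = "spearman",
                                      exact = FALSE))
      if (is.finite(ct$p.value) && ct$p.value < alpha_latency)
        lat_sig <- lat_sig + 1L
    }
    c(soa = soa_sig, latency = lat_sig)
  }
  per <- t(vapply(runs_list, stats_one, c(soa = 0L, latency = 0L)))
  per_df <- data.frame(m_subject = seq_len(nrow(per)),
                       n_soa_units = per[, "soa"],
                       n_latency_units = per[, "latency"])
  structure(list(per_subject = per_df,
                 mean_soa_units = mean(per_df$n_soa_units, na.rm = TRUE),
                 mean_latency_units = mean(per_df$n_latency_units)),
            class = "soa_unit_report")
}
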