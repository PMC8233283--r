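# Independent oracles: deliberately naive, loop-based re-evaluations used
# to cross-check the package implementations.

# Literal re-evaluation of the responder rule on one trace: moving-average
# smooth, finite-difference derivative, baseline mean / population SD, and
# the two strict criteria. No code shared with classify_responders().
naive_classify <- function(time, ca, baseline_start, baseline_end,
                           app_start, app_end,
                           amp_min = 50, sd_mult = 3, smooth = 3) {
  n <- length(ca)
  s <- numeric(n)
  h <- (smooth - 1) / 2
  for (i in seq_len(n)) {
    hh <- min(h, i - 1, n - i)
    acc <- 0
    for (j in (i - hh):(i + hh)) acc <- acc + ca[j]
    s[i] <- acc / (2 * hh + 1)
  }
  d <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) {
      d[i] <- (s[2] - s[1]) / (time[2] - time[1])
    } else if (i == n) {
      d[i] <- (s[n] - s[n - 1]) / (time[n] - time[n - 1])
    } else {
      d[i] <- (s[i + 1] - s[i - 1]) / (time[i + 1] - time[i - 1])
    }
  }
  bidx <- which(time >= baseline_start & time <= baseline_end)
  aidx <- which(time >= app_start & time <= app_end)
  baseline <- sum(ca[bidx]) / length(bidx)
  peak <- max(ca[aidx])
  amplitude <- peak - baseline
  db <- d[bidx]
  mu <- sum(db) / length(db)
  sdv <- sqrt(sum((db - mu)^2) / length(db))
  maxd <- max(d[aidx])
  amp_ok <- amplitude > amp_min
  der_ok <- maxd > sd_mult * sdv
  list(is_responder = amp_ok && der_ok, amplitude = amplitude,
       max_derivative = maxd, baseline_sd = sdv,
       amplitude_criterion_met = amp_ok, derivative_criterion_met = der_ok)
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (at fixed margins) no more likely
# than the observed one.
enumerate_fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  support <- max(0, m - n2):min(m, n1)
  probs <- dhyper(support, m, n1 + n2 - m, n1)
  p_obs <- dhyper(k1, m, n1 + n2 - m, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a calcium_traces data frame from raw vectors, for single-cell tests
make_ca <- function(time, ca, cell = "c1", exp = "e1") {
  out <- data.frame(experiment_id = exp, cell_id = cell,
                    time_s = time, ca_nM = ca, stringsAsFactors = FALSE)
  class(out) <- c("calcium_traces", "data.frame")
  out
}

# baseline [0, baseline_end], application [app_start, t_max]; pick the
# split points between sample times so window membership is unambiguous
two_window_protocol <- function(baseline_end, app_start, t_max,
                                agonist = "THC") {
  protocol_windows(label = c("baseline", "application"),
                   t_start = c(0, app_start), t_end = c(baseline_end, t_max),
                   agonist = c("", agonist))
}
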