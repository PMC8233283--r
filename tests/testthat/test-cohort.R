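make_calls <- function(df) {
  df$excluded <- FALSE
  df$amplitude <- ifelse(df$is_responder, 150, 10)
  class(df) <- c("responder_calls", "data.frame")
  df
}

test_that("experiment summaries count responders per experiment and agonist", {
  calls <- make_calls(data.frame(
    experiment_id = rep(c("e1", "e2"), c(10, 4)),
    cell_id = sprintf("c%02d", 1:14),
    agonist = "THC",
    is_responder = c(rep(TRUE, 7), rep(FALSE, 3), TRUE, TRUE, FALSE, FALSE)
  ))
  s <- summarize_experiments(calls)
  expect_equal(nrow(s), 2)
  expect_equal(s$fraction_responders[s$experiment_id == "e1"], 0.7)
  expect_equal(s$n_responders[s$experiment_id == "e2"], 2)
})

test_that("pooled counts are conserved and identical fractions have zero SEM", {
  calls <- make_calls(data.frame(
    experiment_id = rep(c("e1", "e2", "e3"), each = 10),
    cell_id = sprintf("c%02d", 1:30),
    agonist = "MIB",
    is_responder = rep(c(rep(TRUE, 6), rep(FALSE, 4)), 3)
  ))
  s <- summarize_experiments(calls)
  pooled <- pool_cohort(s)
  expect_equal(pooled$pooled_responders, sum(s$n_responders))
  expect_equal(pooled$pooled_total, sum(s$n_cells))
  expect_equal(pooled$pooled_percent, 60)
  expect_equal(pooled$mean_percent, 60)
  expect_equal(pooled$sem_percent, 0)
})

test_that("pooled percentages reproduce the published legend counts", {
  counts <- data.frame(
    agonist = c("MIB", "THC", "GSK", "EA"),
    n_responders = c(1302, 956, 43, 11),
    n_cells = c(1336, 1470, 1475, 990)
  )
  pooled <- pool_cohort(counts)
  expect_equal(round(pooled$pooled_percent), c(97, 65, 3, 1))
})

test_that("cohort mean fraction recovers the generator's responder fraction", {
  cfg <- trace_sim_config(n_cells = 40, n_experiments = 6,
                          responder_fraction = 0.65, seed = 23)
  sim <- simulate_calcium_traces(cfg, default_windows())
  calls <- classify_responders(calibrate_traces(sim$traces, cfg$params),
                               default_windows())
  pooled <- pool_cohort(summarize_experiments(calls))
  # binomial SEM at n = 40 per experiment, 6 experiments
  sem_pct <- 100 * sqrt(0.65 * 0.35 / 40) / sqrt(6)
  expect_lt(abs(pooled$mean_percent - 65), 4 * sem_pct)
})

test_that("two-group comparisons delegate to the standard tests", {
  # identical proportions: Fisher p = 1
  same <- compare_groups(c(7, 10), c(7, 10), test = "fisher_counts")
  expect_equal(same$p, 1)
  expect_equal(same$test, "fisher_exact")
  # overwhelming difference
  diff <- compare_groups(c(90, 100), c(10, 100), test = "fisher_counts")
  expect_lt(diff$p, 0.001)
  # identical paired vectors: zero-variance differences, no numeric p
  eq <- compare_groups(c(1, 2, 3), c(1, 2, 3), design = "paired", test = "t")
  expect_equal(eq$statistic, 0)
  expect_true(is.na(eq$p))
  expect_match(eq$note, "no difference")
  # small-n guard
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("fisher route equals exact hypergeometric enumeration on small tables", {
  for (n1 in c(3, 7, 12)) {
    for (n2 in c(4, 9, 15)) {
      for (k1 in 0:n1) {
        for (k2 in c(0, floor(n2 / 2), n2)) {
          p_pkg <- compare_groups(c(k1, n1), c(k2, n2),
                                  test = "fisher_counts")$p
          p_enum <- enumerate_fisher_p(k1, n1, k2, n2)
          expect_equal(p_pkg, p_enum, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("normality gate swaps in Mann-Whitney for skewed data", {
  set.seed(29)
  a <- exp(rnorm(40, 0, 1.5))
  b <- exp(rnorm(40, 0.2, 1.5))
  res <- compare_groups(a, b, test = "t", normality_gate = TRUE)
  expect_equal(res$test, "mann_whitney")
  expect_match(res$note, "normality rejected")
})

test_that("D'Agostino-Pearson omnibus matches the reference implementation", {
  # frozen reference values from an independent implementation of the
  # K2 = Z(skew)^2 + Z(kurt)^2 omnibus statistic
  x <- c(1.0331452014731253, 1.0284469981065203, 1.0286755723528125,
         1.0569060950748415, 0.61781707641809869, 0.5579937594391795,
         0.42224882666301805, 0.22578442350186986, 1.2414832487312046,
         2.6761423895465253, 0.58095374327080318, 0.57200071417593912,
         0.72870752385413828, 0.63087991648027253, 0.23781320913443349,
         3.9161460983809095, 1.5511551129718937, 0.49081155305133134,
         1.3460464786095623, 0.64503076050652974, 0.80925805434437437,
         1.4390221660574374, 2.5933863479682846, 4.5700499244843966,
         5.4953893955048603, 0.77969013002389953, 0.60668316606820516,
         1.104726178414714, 1.1369431486015091, 0.47987871099152835,
         0.53768881968343452, 2.2552790678029062, 5.1644624091677906,
         0.79731866588415035, 0.52310911123126025, 0.75324012823197006,
         0.36967488087319006, 0.76119038897503488, 1.5256859946428849,
         0.92187746865973097)
  res <- dagostino_pearson(x)
  expect_equal(res$statistic, 27.2264018572283, tolerance = 1e-10)
  expect_equal(res$p, 1.22422700604619e-06, tolerance = 1e-9)

  y <- c(0.22870345477560539, 0.13767446474226841, 0.42437113892701128,
         0.15153875301930686, 0.87327294878805162, 0.17912675748780149,
         0.030294661612327189, 0.55924967713366547, 0.4288062533520195,
         0.85859742155935415, 0.1608313755289944, 0.36035369939180739,
         0.6405099368325804, 0.93107934961176009, 0.2618010220904331,
         0.68809841358184698, 0.14905265235536258, 0.74015497342107628,
         0.29318128302105961, 0.24374510457040732, 0.22982143784491704,
         0.37065116516756513, 0.32855508748114748, 0.61264167181815099,
         0.544715400191636, 0.74964310489090868, 0.29495428542604019,
         0.96055372837503039, 0.54348275860010575, 0.67942414840951748)
  res2 <- dagostino_pearson(y)
  expect_equal(res2$statistic, 4.0208734738786, tolerance = 1e-10)
  expect_equal(res2$p, 0.133930169641713, tolerance = 1e-9)
})

test_that("many-to-one trend comparisons flag only real shifts", {
  set.seed(37)
  # all groups identical constants: nothing significant
  flat <- multi_group_trend(rep(5, 16) + rnorm(16, 0, 1e-8),
                            rep(c("E10.5", "E12.5", "E14.5", "E18.5"), each = 4),
                            "E10.5")
  expect_true(all(flat$p_adj > 0.05))
  # one group shifted by 5 cycles at noise 0.1: that comparison significant
  vals <- c(rnorm(4, 10, 0.1), rnorm(4, 10, 0.1), rnorm(4, 15, 0.1))
  cond <- rep(c("E10.5", "E12.5", "E18.5"), each = 4)
  res <- multi_group_trend(vals, cond, "E10.5")
  expect_lt(res$p_adj[res$comparison == "E18.5 - E10.5"], 0.05)
  expect_gt(res$p_adj[res$comparison == "E12.5 - E10.5"], 0.05)
  # non-parametric route: at n = 4 per group the rank test cannot beat
  # 0.05 after Holm (exact minimum is 2/35), but the shifted group must
  # carry the smallest adjusted p and sit near that floor
  resk <- multi_group_trend(vals, cond, "E10.5", method = "kruskal")
  expect_equal(which.min(resk$p_adj),
               which(resk$comparison == "E18.5 - E10.5"))
  expect_lt(resk$p_adj[resk$comparison == "E18.5 - E10.5"], 0.1)
  # guards
  expect_error(multi_group_trend(1:8, rep(c("a", "b"), 4), "a"),
               "at least 3")
  expect_error(multi_group_trend(1:12, rep(c("a", "b", "c"), 4), "zz"),
               "not present")
})
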