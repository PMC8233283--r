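ct_df <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], gene = r[[2]], replicate = 1,
               ct = r[[3]], stringsAsFactors = FALSE)
  }))
}

test_that("delta-Ct uses the geometric mean of housekeeping Cts", {
  # hand-computed: geomean(20, 24.2) = sqrt(484) = 22.0 exactly
  df <- ct_df(list(list("s1", "Actb", 20), list("s1", "Gapdh", 24.2),
                   list("s1", "Trpm7", 22), list("s1", "Trpv2", 25)))
  res <- relative_expression(ct_table(df))
  v2 <- res[res$gene == "Trpv2", ]
  expect_equal(v2$delta_ct, 3)
  expect_equal(v2$rel_expression, 0.125)
  # gene at the geometric mean: rel = 1
  m7 <- res[res$gene == "Trpm7", ]
  expect_equal(m7$rel_expression, 1)
})

test_that("one extra cycle halves relative expression", {
  df <- ct_df(list(list("s1", "Actb", 20), list("s1", "Gapdh", 20),
                   list("s1", "geneA", 20), list("s1", "geneB", 21)))
  res <- relative_expression(ct_table(df))
  expect_equal(res$rel_expression[res$gene == "geneA"], 1)
  expect_equal(res$rel_expression[res$gene == "geneB"], 0.5)
})

test_that("relative expression is invariant to a constant Ct shift", {
  base <- ct_df(list(list("s1", "Actb", 19), list("s1", "Gapdh", 21.3),
                     list("s1", "Trpm7", 23), list("s1", "Trpv4", 26.5)))
  shifted <- base
  shifted$ct <- shifted$ct + 2.7
  r1 <- relative_expression(ct_table(base))
  r2 <- relative_expression(ct_table(shifted))
  # the shift moves the housekeeping geomean by (roughly) the same 2.7
  # cycles only when applied to raw Cts of gene and controls alike; the
  # geometric mean of shifted Cts is not exactly shifted by 2.7, so test
  # the exact invariance on equal housekeepers
  eq <- ct_df(list(list("s1", "Actb", 20), list("s1", "Gapdh", 20),
                   list("s1", "g", 24)))
  eqs <- eq; eqs$ct <- eqs$ct + 3
  expect_equal(relative_expression(ct_table(eq))$rel_expression[1],
               relative_expression(ct_table(eqs))$rel_expression[1])
  expect_s3_class(r1, "expression_result")
  expect_s3_class(r2, "expression_result")
})

test_that("replicates are averaged and undetected replicates dropped", {
  df <- data.frame(
    sample_id = "s1",
    gene = rep(c("Actb", "Gapdh", "geneA", "geneB"), each = 3),
    replicate = rep(1:3, 4),
    ct = c(20, 20, 20, 20, 20, 20, 24, 25, 26, 39, NA, 41)
  )
  res <- relative_expression(ct_table(df))
  expect_equal(res$mean_ct[res$gene == "geneA"], 25)
  # geneB: one replicate at 39 detected, others undetected (NA / >= 40)
  expect_equal(res$mean_ct[res$gene == "geneB"], 39)
  # all replicates undetected -> not_detected
  df$ct[df$gene == "geneB"] <- c(40, NA, 42)
  res2 <- relative_expression(ct_table(df))
  expect_false(res2$detected[res2$gene == "geneB"])
  expect_true(is.na(res2$rel_expression[res2$gene == "geneB"]))
})

test_that("percent-of-Trpm7 uses the scope-mean reference delta-Ct", {
  # two conditions; Trpm7 delta-Ct differs, the reference is its mean
  df <- rbind(
    ct_df(list(list("s1", "Actb", 20), list("s1", "Gapdh", 20),
               list("s1", "Trpm7", 24), list("s1", "Trpv2", 23))),
    ct_df(list(list("s2", "Actb", 20), list("s2", "Gapdh", 20),
               list("s2", "Trpm7", 26), list("s2", "Trpv2", 24)))
  )
  df$day <- rep(c("E10.5", "E18.5"), each = 4)
  res <- percent_of_trpm7(relative_expression(
    ct_table(df, condition = "day")))
  # reference delta-Ct = mean(4, 6) = 5
  v2 <- res[res$gene == "Trpv2", ]
  expect_equal(v2$percent_of_reference[v2$day == "E10.5"], 100 * 2^(5 - 3))
  expect_equal(v2$fold_change_vs_reference[v2$day == "E10.5"], 4)
  # a gene exactly at the reference mean reads 100%
  m7 <- res[res$gene == "Trpm7", ]
  expect_equal(mean(m7$percent_of_reference), 100 * mean(2^c(-1, 1)) / 1,
               tolerance = 1e-12)
  # one delta-delta-Ct cycle = 50%
  dd1 <- ct_df(list(list("s1", "Actb", 20), list("s1", "Gapdh", 20),
                    list("s1", "Trpm7", 24), list("s1", "g", 25)))
  r <- percent_of_trpm7(relative_expression(ct_table(dd1)))
  expect_equal(r$percent_of_reference[r$gene == "g"], 50)
})

test_that("category bands follow the published cutoffs", {
  expect_equal(as.character(categorize(c(150, 101, 100, 50, 5, 4.9, 1, 0.99, 0.5))),
               c("high", "high", "moderate", "moderate", "moderate",
                 "low", "low", "below_detection", "below_detection"))
  expect_equal(as.character(categorize(NA)), "not_detected")
  expect_error(categorize(-1), ">= 0")
  # total monotone step function: category index never decreases as
  # percent falls
  p <- sort(runif(100, 0, 200), decreasing = TRUE)
  idx <- as.integer(categorize(p))
  expect_true(all(diff(idx) >= 0))
})

test_that("fold changes vs a baseline condition follow the doubling law", {
  df <- rbind(
    ct_df(list(list("s1", "Actb", 20), list("s1", "Gapdh", 20),
               list("s1", "Trpm7", 24), list("s1", "Trpv6", 30))),
    ct_df(list(list("s2", "Actb", 20), list("s2", "Gapdh", 20),
               list("s2", "Trpm7", 24), list("s2", "Trpv6", 30 - log2(10))))
  )
  df$day <- rep(c("E10.5", "E18.5"), each = 4)
  res <- relative_expression(ct_table(df, condition = "day"))
  fc <- fold_change_vs_baseline(res, "E10.5")
  v6 <- fc[fc$gene == "Trpv6", ]
  expect_equal(v6$fold_change[v6$day == "E10.5"], 1)
  expect_equal(v6$fold_change[v6$day == "E18.5"], 10, tolerance = 1e-12)
  expect_error(fold_change_vs_baseline(res, "E99"), "not present")
})

test_that("zero-noise generator round trips fractions exactly", {
  fr <- c(gA = 0.5, gB = 0.03, gC = 0.005)
  res <- percent_of_trpm7(relative_expression(
    simulate_ct_table(fr, ct_noise_sd = 0)))
  got <- res$percent_of_reference[match(names(fr), res$gene)]
  expect_equal(got, unname(100 * fr), tolerance = 1e-12)
  # 50-fold design across two conditions
  m <- cbind(c1 = c(g = 0.01), c2 = c(g = 0.5))
  rownames(m) <- "g"
  res2 <- relative_expression(simulate_ct_table(m, ct_noise_sd = 0))
  fc <- fold_change_vs_baseline(res2, "c1")
  expect_equal(fc$fold_change[fc$condition == "c2" & fc$gene == "g"], 50,
               tolerance = 1e-12)
})

test_that("strain contrasts recover designed expression differences", {
  build <- function(strain, level) {
    df <- ct_df(list(list(paste0(strain, "_1"), "Actb", 20),
                     list(paste0(strain, "_1"), "Gapdh", 20),
                     list(paste0(strain, "_1"), "Trpm7", 24),
                     list(paste0(strain, "_1"), "Trpm4", 24 - log2(level))))
    df$day <- "E14.5"
    df$strain <- strain
    df
  }
  # identical strains: 0% difference
  same <- relative_expression(ct_table(rbind(build("A", 1), build("B", 1)),
                                       condition = "day"))
  expect_equal(strain_contrast(same, "A", "B")$mean_percent_diff[
    strain_contrast(same, "A", "B")$gene == "Trpm4"], 0)
  # one strain at 2x: +100%
  twox <- relative_expression(ct_table(rbind(build("A", 2), build("B", 1)),
                                       condition = "day"))
  sc <- strain_contrast(twox, "A", "B")
  expect_equal(sc$mean_percent_diff[sc$gene == "Trpm4"], 100)
  # -33% design
  down <- relative_expression(ct_table(rbind(build("A", 0.67), build("B", 1)),
                                       condition = "day"))
  sc2 <- strain_contrast(down, "A", "B")
  expect_equal(sc2$mean_percent_diff[sc2$gene == "Trpm4"], -33,
               tolerance = 1e-9)
})

test_that("ct table validation guards housekeeping genes and columns", {
  df <- ct_df(list(list("s1", "Actb", 20), list("s1", "geneA", 25)))
  expect_error(ct_table(df), "Gapdh")
  expect_error(ct_table(df[, -4], housekeeping = "Actb"), "ct")
  bad <- ct_df(list(list("s1", "Actb", 20), list("s1", "Gapdh", -3),
                    list("s1", "g", 25)))
  expect_error(ct_table(bad), "> 0")
})
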