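#' Per-experiment responder summaries
#'
#' @param calls a `responder_calls` data frame from
#'   [classify_responders()]. Excluded cells are dropped before counting.
#' @return Data frame with one row per (experiment, agonist):
#'   `n_cells`, `n_responders`, `fraction_responders`,
#'   `mean_amplitude_responders`.
#' @export
summarize_experiments <- function(calls) {
  stopifnot(inherits(calls, "responder_calls"))
  kept <- calls[!calls$excluded & !is.na(calls$is_responder), , drop = FALSE]
  groups <- unique(calls[c("experiment_id", "agonist")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- kept[kept$experiment_id == groups$experiment_id[i] &
                  kept$agonist == groups$agonist[i], , drop = FALSE]
    n <- nrow(sub)
    r <- sum(sub$is_responder)
    data.frame(
      experiment_id = groups$experiment_id[i],
      agonist = groups$agonist[i],
      n_cells = n,
      n_responders = r,
      fraction_responders = if (n > 0) r / n else NA_real_,
      mean_amplitude_responders = if (r > 0) {
        mean(sub$amplitude[sub$is_responder])
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Pool per-experiment summaries into a cohort summary
#'
#' Reports, per agonist, both conventions used for responder percentages:
#' the mean ± SEM of per-experiment fractions (the headline convention) and
#' the pooled-count percentage `100 * sum(responders) / sum(cells)`.
#' Percentages are kept at full precision; round only at presentation.
#'
#' @param summaries output of [summarize_experiments()], or any data frame
#'   with columns `agonist`, `n_cells`, `n_responders` (e.g. published
#'   pooled counts entered as one row per agonist).
#' @return A `cohort_summary` data frame with columns `agonist`,
#'   `n_experiments`, `mean_percent`, `sem_percent`, `pooled_responders`,
#'   `pooled_total`, `pooled_percent`, `mean_amplitude`, `sem_amplitude`.
#' @export
pool_cohort <- function(summaries) {
  need <- c("agonist", "n_cells", "n_responders")
  missing <- setdiff(need, names(summaries))
  if (length(missing) > 0) {
    stop("summaries missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(summaries) == 0) stop("need at least one experiment summary")
  rows <- lapply(unique(summaries$agonist), function(ag) {
    sub <- summaries[summaries$agonist == ag, , drop = FALSE]
    total <- sum(sub$n_cells)
    resp <- sum(sub$n_responders)
    fr <- if ("fraction_responders" %in% names(sub)) {
      sub$fraction_responders
    } else sub$n_responders / sub$n_cells
    amp <- if ("mean_amplitude_responders" %in% names(sub)) {
      sub$mean_amplitude_responders
    } else NA_real_
    data.frame(
      agonist = ag,
      n_experiments = nrow(sub),
      mean_percent = 100 * mean(fr, na.rm = TRUE),
      sem_percent = 100 * sem(fr),
      pooled_responders = resp,
      pooled_total = total,
      pooled_percent = if (total > 0) 100 * resp / total else NA_real_,
      mean_amplitude = mean(amp, na.rm = TRUE),
      sem_amplitude = sem(amp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %s: %.0f%% pooled (%d of %d cells); mean %.0f +/- %.0f%% over %d experiments\n",
      x$agonist[i], x$pooled_percent[i], x$pooled_responders[i],
      x$pooled_total[i], x$mean_percent[i],
      ifelse(is.na(x$sem_percent[i]), 0, x$sem_percent[i]),
      x$n_experiments[i]))
  }
  invisible(x)
}

#' Two-group comparison
#'
#' Thin dispatcher over the standard tests used for responder cohorts:
#' Student/paired t, Mann-Whitney (Wilcoxon rank-sum), or Fisher's exact on
#' responder counts. Optionally gates the t-test on a D'Agostino-Pearson
#' normality check and falls back to Mann-Whitney.
#'
#' @param a,b numeric vectors of per-experiment values, or for
#'   `test = "fisher_counts"` length-2 vectors `c(responders, total)`.
#' @param design `"unpaired"` or `"paired"` (t test only; requires equal
#'   lengths in matched order).
#' @param test `"t"`, `"mann_whitney"` or `"fisher_counts"`.
#' @param normality_gate if `TRUE` and `test = "t"`, switch to
#'   Mann-Whitney when either group fails normality at p < 0.05.
#' @return A list with `test` (the test actually run), `statistic`, `p`,
#'   and `note` where applicable.
#' @export
compare_groups <- function(a, b, design = c("unpaired", "paired"),
                           test = c("t", "mann_whitney", "fisher_counts"),
                           normality_gate = FALSE) {
  design <- match.arg(design)
  test <- match.arg(test)
  if (test == "fisher_counts") {
    if (length(a) != 2 || length(b) != 2) {
      stop("fisher_counts expects c(responders, total) for each group")
    }
    if (a[1] > a[2] || b[1] > b[2]) stop("responders cannot exceed totals")
    tab <- rbind(c(a[1], a[2] - a[1]), c(b[1], b[2] - b[1]))
    ft <- stats::fisher.test(tab)
    return(list(test = "fisher_exact", statistic = unname(ft$estimate),
                p = ft$p.value, note = "statistic is the odds ratio"))
  }
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (design == "paired" && length(a) != length(b)) {
    stop("paired design requires equal-length, matched vectors")
  }
  if (test == "t" && normality_gate) {
    pa <- tryCatch(dagostino_pearson(a)$p, error = function(e) NA_real_)
    pb <- tryCatch(dagostino_pearson(b)$p, error = function(e) NA_real_)
    if (!is.na(pa) && !is.na(pb) && (pa < 0.05 || pb < 0.05)) {
      res <- compare_groups(a, b, design, "mann_whitney")
      res$note <- "normality rejected; fell back to Mann-Whitney"
      return(res)
    }
  }
  if (test == "t") {
    if (design == "paired" && stats::sd(a - b) == 0) {
      # zero-variance differences: t statistic undefined
      return(list(test = "paired_t", statistic = 0, p = NA_real_,
                  note = "no difference (zero-variance paired differences)"))
    }
    tt <- stats::t.test(a, b, paired = design == "paired")
    return(list(test = if (design == "paired") "paired_t" else "t",
                statistic = unname(tt$statistic), p = tt$p.value,
                note = NA_character_))
  }
  wt <- stats::wilcox.test(a, b, paired = design == "paired", exact = FALSE)
  list(test = "mann_whitney", statistic = unname(wt$statistic),
       p = wt$p.value, note = NA_character_)
}

#' Many-to-one trend comparisons against a control condition
#'
#' Compares every condition against a designated control with multiplicity
#' adjustment, operating on the values as given (for qPCR trends this
#' should be delta-Ct values, not fold changes). The parametric route is
#' one-way ANOVA followed by Dunnett's many-to-one procedure; the
#' non-parametric route is a Kruskal-Wallis gate followed by pairwise
#' Wilcoxon rank-sum tests against the control with Holm adjustment (a
#' substitute for Dunn's test).
#'
#' @param values numeric response vector (e.g. delta-Ct).
#' @param condition condition label per value.
#' @param control_label the reference condition (e.g. `"E10.5"`).
#' @param method `"dunnett"` or `"kruskal"`.
#' @return Data frame with one row per non-control condition: `comparison`,
#'   `estimate` (difference vs control, Dunnett route only), `p_adj`,
#'   `method`.
#' @export
multi_group_trend <- function(values, condition, control_label,
                              method = c("dunnett", "kruskal")) {
  method <- match.arg(method)
  condition <- as.character(condition)
  if (length(values) != length(condition)) stop("length mismatch")
  levs <- unique(condition)
  if (length(levs) < 3) stop("need at least 3 condition groups")
  if (!control_label %in% levs) {
    stop("control group '", control_label, "' not present")
  }
  grp <- factor(condition, levels = c(control_label,
                                      setdiff(levs, control_label)))
  others <- levels(grp)[-1]
  if (method == "dunnett") {
    fit <- stats::aov(values ~ grp, data = data.frame(values, grp))
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
    sm <- summary(gl)
    data.frame(
      comparison = paste(others, "-", control_label),
      estimate = unname(sm$test$coefficients),
      p_adj = unname(as.numeric(sm$test$pvalues)),
      method = "anova_dunnett",
      stringsAsFactors = FALSE
    )
  } else {
    stats::kruskal.test(values, grp)  # omnibus gate, reported via p_adj rows
    p <- vapply(others, function(g) {
      stats::wilcox.test(values[grp == g],
                         values[grp == control_label], exact = FALSE)$p.value
    }, numeric(1))
    data.frame(
      comparison = paste(others, "-", control_label),
      estimate = NA_real_,
      p_adj = stats::p.adjust(p, method = "holm"),
      method = "kruskal_wilcoxon_holm",
      stringsAsFactors = FALSE
    )
  }
}
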