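#' Construct a validated Ct table
#'
#' @param df data frame with columns `sample_id`, `gene`, `replicate`,
#'   `ct`, plus optional condition columns (gestational day, strain,
#'   culture day). Undetected replicates may be `NA` or carry
#'   `ct >= detection_ct`.
#' @param housekeeping character vector of housekeeping gene names present
#'   for every sample (`Actb`/`Gapdh` for tissue and primary cells,
#'   `Actb`/`Sdha` for mTSC).
#' @param reference reference gene for percent-of-reference
#'   categorization; `"Trpm7"` by convention.
#' @param condition name of the condition column, if any.
#' @param detection_ct Ct at or above which a replicate is treated as
#'   undetected (conventional qPCR floor, default 40).
#' @return A `ct_table` data frame with attributes `housekeeping`,
#'   `reference`, `condition`, `detection_ct`.
#' @export
ct_table <- function(df, housekeeping = c("Actb", "Gapdh"),
                     reference = "Trpm7", condition = NULL,
                     detection_ct = 40) {
  need <- c("sample_id", "gene", "replicate", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(condition) && !condition %in% names(df)) {
    stop("condition column '", condition, "' not found")
  }
  if (any(!is.na(df$ct) & df$ct <= 0)) stop("detected Ct values must be > 0")
  for (s in unique(df$sample_id)) {
    have <- unique(df$gene[df$sample_id == s])
    lack <- setdiff(housekeeping, have)
    if (length(lack) > 0) {
      stop("sample '", s, "' lacks housekeeping gene(s): ",
           paste(lack, collapse = ", "))
    }
  }
  structure(df, housekeeping = housekeeping, reference = reference,
            condition = condition, detection_ct = detection_ct,
            class = c("ct_table", "data.frame"))
}

geo_mean <- function(x) exp(mean(log(x)))

#' Relative expression from a Ct table
#'
#' Replicate Cts are averaged per (sample, gene) over detected replicates;
#' then \eqn{\Delta Ct = \bar{Ct}_{gene} - } geometric mean of the
#' housekeeping mean Cts, and relative expression \eqn{= 2^{-\Delta Ct}}.
#' A gene is `not_detected` in a sample when all its replicates are
#' undetected (missing or at/above the detection floor).
#'
#' @param ct a [ct_table()].
#' @return An `expression_result` data frame: one row per (sample, gene)
#'   with `mean_ct`, `delta_ct`, `rel_expression`, `detected`, carrying the
#'   condition column and the `ct_table` attributes forward. Housekeeping
#'   genes are consumed, not reported.
#' @export
relative_expression <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  hk <- attr(ct, "housekeeping")
  cond <- attr(ct, "condition")
  floor_ct <- attr(ct, "detection_ct")
  df <- as.data.frame(ct)
  df$detected_rep <- !is.na(df$ct) & df$ct < floor_ct

  agg_key <- paste(df$sample_id, df$gene, sep = "\r")
  mean_ct <- tapply(ifelse(df$detected_rep, df$ct, NA_real_), agg_key,
                    mean, na.rm = TRUE)
  any_det <- tapply(df$detected_rep, agg_key, any)

  pairs <- unique(df[c("sample_id", "gene")])
  pairs$mean_ct <- as.numeric(mean_ct[paste(pairs$sample_id, pairs$gene,
                                            sep = "\r")])
  pairs$detected <- as.logical(any_det[paste(pairs$sample_id, pairs$gene,
                                             sep = "\r")])
  pairs$mean_ct[!pairs$detected] <- NA_real_

  rows <- list()
  for (s in unique(pairs$sample_id)) {
    sub <- pairs[pairs$sample_id == s, , drop = FALSE]
    hk_ct <- sub$mean_ct[match(hk, sub$gene)]
    if (any(is.na(hk_ct))) {
      stop("housekeeping gene(s) undetected in sample '", s, "'")
    }
    ref_ct <- geo_mean(hk_ct)
    targets <- sub[!sub$gene %in% hk, , drop = FALSE]
    targets$delta_ct <- targets$mean_ct - ref_ct
    targets$rel_expression <- 2^(-targets$delta_ct)
    # carry per-sample metadata columns (condition, strain, ...) forward
    meta <- setdiff(names(df), c("sample_id", "gene", "replicate", "ct",
                                 "detected_rep"))
    for (mcol in meta) {
      targets[[mcol]] <- df[[mcol]][match(s, df$sample_id)]
    }
    rows[[length(rows) + 1]] <- targets
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, housekeeping = hk, reference = attr(ct, "reference"),
            condition = cond,
            class = c("expression_result", "data.frame"))
}

#' Percent of reference-gene (Trpm7) expression
#'
#' The reference \eqn{\Delta Ct} is the mean \eqn{\Delta Ct} of the
#' reference gene over all samples in scope (by convention the average
#' Trpm7 expression across all gestational days); then
#' \eqn{\%\,=\,100 \cdot 2^{-(\Delta Ct - \Delta Ct_{ref})}} and the fold
#' change vs the reference is the same quantity / 100.
#'
#' @param res an `expression_result` from [relative_expression()].
#' @param scope optional vector of condition values defining the reference
#'   scope; defaults to every sample.
#' @return `res` with columns `percent_of_reference`,
#'   `fold_change_vs_reference` and `category` added (see [categorize()]).
#' @export
percent_of_trpm7 <- function(res, scope = NULL) {
  stopifnot(inherits(res, "expression_result"))
  refgene <- attr(res, "reference")
  cond <- attr(res, "condition")
  sel <- res$gene == refgene & res$detected
  if (!is.null(scope)) {
    if (is.null(cond)) stop("no condition column to scope on")
    sel <- sel & res[[cond]] %in% scope
    if (!any(res$gene == refgene & res[[cond]] %in% scope)) {
      stop("empty reference scope")
    }
  }
  if (!any(sel)) stop("reference gene '", refgene, "' not detected in scope")
  ref_delta <- mean(res$delta_ct[sel])
  res$percent_of_reference <- 100 * 2^(-(res$delta_ct - ref_delta))
  res$fold_change_vs_reference <- res$percent_of_reference / 100
  res$category <- categorize(res$percent_of_reference)
  res
}

#' Expression category from percent-of-Trpm7
#'
#' Bands: above the reference itself (> 100%) is `high`; 5–100% is
#' `moderate`; 1–5% is `low`; below 1% is `below_detection`. Touching band
#' edges are closed on the lower side (5% is moderate, 1% is low) and 100%
#' belongs to moderate. `NA` (gene undetected) maps to `not_detected`.
#'
#' @param percent numeric vector of percent-of-reference values.
#' @return Factor with levels `high`, `moderate`, `low`, `below_detection`,
#'   `not_detected`.
#' @export
categorize <- function(percent) {
  if (any(!is.na(percent) & percent < 0)) stop("percent must be >= 0")
  out <- ifelse(is.na(percent), "not_detected",
         ifelse(percent > 100, "high",
         ifelse(percent >= 5, "moderate",
         ifelse(percent >= 1, "low", "below_detection"))))
  factor(out, levels = c("high", "moderate", "low", "below_detection",
                         "not_detected"))
}

#' Fold change of each gene versus a baseline condition
#'
#' \eqn{2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = \Delta Ct_{condition} - \Delta Ct_{baseline}},
#' per gene. Conditions with replicate samples use the mean
#' \eqn{\Delta Ct} per condition. The baseline condition itself yields 1.
#'
#' @param res an `expression_result`.
#' @param baseline_condition condition label used as baseline (e.g.
#'   `"E10.5"`).
#' @return Data frame `gene`, condition, `fold_change`; genes undetected at
#'   baseline get `NA` with `baseline_detected = FALSE`.
#' @export
fold_change_vs_baseline <- function(res, baseline_condition) {
  stopifnot(inherits(res, "expression_result"))
  cond <- attr(res, "condition")
  if (is.null(cond)) stop("expression result has no condition column")
  if (!baseline_condition %in% res[[cond]]) {
    stop("baseline condition '", baseline_condition, "' not present")
  }
  key <- paste(res$gene, res[[cond]], sep = "\r")
  mean_delta <- tapply(res$delta_ct, key, mean, na.rm = TRUE)
  combos <- unique(res[c("gene", cond)])
  combos$delta <- as.numeric(mean_delta[paste(combos$gene, combos[[cond]],
                                              sep = "\r")])
  rows <- lapply(unique(combos$gene), function(g) {
    sub <- combos[combos$gene == g, , drop = FALSE]
    base <- sub$delta[sub[[cond]] == baseline_condition]
    ok <- length(base) == 1 && is.finite(base)
    data.frame(
      gene = g, condition = sub[[cond]],
      fold_change = if (ok) 2^(-(sub$delta - base)) else NA_real_,
      baseline_detected = ok,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "condition"] <- cond
  rownames(out) <- NULL
  out
}

#' Percent expression difference between two strains
#'
#' Per gene, computes the percent difference of relative expression
#' (`100 * (a - b) / b`) at every condition shared by the two strains, then
#' reports the across-condition mean ± SEM.
#'
#' @param res an `expression_result` whose table has a `strain` column.
#' @param strain_a,strain_b strain labels; the contrast is a vs b.
#' @param strain_col name of the strain column.
#' @return Data frame `gene`, `mean_percent_diff`, `sem_percent_diff`,
#'   `n_conditions`.
#' @export
strain_contrast <- function(res, strain_a, strain_b, strain_col = "strain") {
  stopifnot(inherits(res, "expression_result"))
  cond <- attr(res, "condition")
  if (is.null(cond)) stop("expression result has no condition column")
  if (!strain_col %in% names(res)) {
    stop("no '", strain_col, "' column in expression result")
  }
  rows <- lapply(unique(res$gene), function(g) {
    sub <- res[res$gene == g & res$detected, , drop = FALSE]
    a <- sub[sub[[strain_col]] == strain_a, , drop = FALSE]
    b <- sub[sub[[strain_col]] == strain_b, , drop = FALSE]
    shared <- intersect(a[[cond]], b[[cond]])
    if (length(shared) == 0) return(NULL)
    diffs <- vapply(shared, function(cc) {
      ea <- mean(a$rel_expression[a[[cond]] == cc])
      eb <- mean(b$rel_expression[b[[cond]] == cc])
      100 * (ea - eb) / eb
    }, numeric(1))
    data.frame(gene = g, mean_percent_diff = mean(diffs),
               sem_percent_diff = sem(diffs), n_conditions = length(shared),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no conditions shared by both strains")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
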