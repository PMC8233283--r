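# CSV/TSV/YAML readers and writers for the pipeline's table dialects.
# All files are UTF-8, header row required, '.' decimal separator.

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

read_csv_checked <- function(path, cols, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, cols, path)
}

#' Read / write fluorescence traces
#'
#' Trace CSV columns: `experiment_id`, `cell_id`, `time_s`, `F340`,
#' `F380`; background CSV columns: `experiment_id`, `background_340`,
#' `background_380`.
#'
#' @param traces_csv,background_csv file paths.
#' @return A [trace_set()].
#' @export
read_traces <- function(traces_csv, background_csv) {
  tr <- read_csv_checked(traces_csv,
                         c("experiment_id", "cell_id", "time_s", "F340", "F380"))
  bg <- read_csv_checked(background_csv,
                         c("experiment_id", "background_340", "background_380"))
  trace_set(tr, bg)
}

#' @rdname read_traces
#' @param ts a [trace_set()].
#' @export
write_traces <- function(ts, traces_csv, background_csv) {
  stopifnot(inherits(ts, "trace_set"))
  cols <- c("experiment_id", "cell_id", "time_s", "F340", "F380")
  utils::write.csv(ts$traces[cols], traces_csv, row.names = FALSE)
  utils::write.csv(ts$background, background_csv, row.names = FALSE)
  invisible(c(traces_csv, background_csv))
}

#' Read / write protocol windows
#'
#' Windows CSV columns: `label`, `t_start_s`, `t_end_s`, `agonist_name`.
#' Overlapping or mis-ordered windows fail validation on read.
#'
#' @param path file path.
#' @return A [protocol_windows()].
#' @export
read_windows <- function(path) {
  df <- read_csv_checked(path, c("label", "t_start_s", "t_end_s",
                                 "agonist_name"))
  df$agonist_name[is.na(df$agonist_name)] <- ""
  protocol_windows(df$label, df$t_start_s, df$t_end_s, df$agonist_name)
}

#' @rdname read_windows
#' @param windows a [protocol_windows()].
#' @export
write_windows <- function(windows, path) {
  out <- data.frame(label = windows$label, t_start_s = windows$t_start,
                    t_end_s = windows$t_end, agonist_name = windows$agonist)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write calibrated calcium traces
#'
#' Columns: `experiment_id`, `cell_id`, `time_s`, `ca_nM`.
#'
#' @param path file path.
#' @return A `calcium_traces` data frame.
#' @export
read_calcium <- function(path) {
  df <- read_csv_checked(path, c("experiment_id", "cell_id", "time_s", "ca_nM"))
  class(df) <- c("calcium_traces", "data.frame")
  df
}

#' @rdname read_calcium
#' @param ca a `calcium_traces` data frame.
#' @export
write_calcium <- function(ca, path) {
  utils::write.csv(as.data.frame(ca), path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-cell responder calls
#'
#' @param path file path.
#' @return A `responder_calls` data frame.
#' @export
read_calls <- function(path) {
  df <- read_csv_checked(path, c("experiment_id", "cell_id", "agonist",
                                 "excluded", "amplitude", "is_responder"))
  class(df) <- c("responder_calls", "data.frame")
  df
}

#' @rdname read_calls
#' @param calls a `responder_calls` data frame.
#' @export
write_calls <- function(calls, path) {
  utils::write.csv(as.data.frame(calls), path, row.names = FALSE)
  invisible(path)
}

#' Read / write qPCR Ct tables
#'
#' Ct CSV columns: `sample_id`, `gene`, `replicate`, `ct` plus any
#' condition columns; the housekeeping set, reference gene and optional
#' condition column are given alongside (typically from a YAML config).
#'
#' @param path file path.
#' @inheritParams ct_table
#' @return A [ct_table()].
#' @export
read_ct <- function(path, housekeeping = c("Actb", "Gapdh"),
                    reference = "Trpm7", condition = NULL,
                    detection_ct = 40) {
  df <- read_csv_checked(path, c("sample_id", "gene", "replicate", "ct"))
  ct_table(df, housekeeping = housekeeping, reference = reference,
           condition = condition, detection_ct = detection_ct)
}

#' @rdname read_ct
#' @param ct a [ct_table()].
#' @export
write_ct <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE)
  invisible(path)
}

#' Read / write count matrices
#'
#' Counts TSV: first column `gene`, remaining columns one per sample.
#' Lengths TSV: columns `gene`, `length_bp`, optionally `total_reads` rows
#' are supplied via `totals_tsv` (columns `sample`, `total_reads`).
#'
#' @param counts_tsv,lengths_tsv,totals_tsv file paths (`totals_tsv`
#'   optional).
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_tsv, lengths_tsv, totals_tsv = NULL) {
  cts <- read_csv_checked(counts_tsv, "gene", sep = "\t")
  lens <- read_csv_checked(lengths_tsv, c("gene", "length_bp"), sep = "\t")
  m <- as.matrix(cts[-1])
  rownames(m) <- cts$gene
  idx <- match(rownames(m), lens$gene)
  if (any(is.na(idx))) {
    stop("genes without length: ",
         paste(utils::head(rownames(m)[is.na(idx)]), collapse = ", "))
  }
  totals <- NULL
  if (!is.null(totals_tsv)) {
    tt <- read_csv_checked(totals_tsv, c("sample", "total_reads"), sep = "\t")
    totals <- tt$total_reads[match(colnames(m), tt$sample)]
  }
  count_matrix(m, lens$length_bp[idx], total_reads = totals)
}

#' @rdname read_counts
#' @param cm a [count_matrix()].
#' @export
write_counts <- function(cm, counts_tsv, lengths_tsv, totals_tsv = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  cts <- data.frame(gene = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(cts, counts_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  lens <- data.frame(gene = rownames(cm$counts), length_bp = cm$gene_lengths)
  utils::write.table(lens, lengths_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(totals_tsv)) {
    tt <- data.frame(sample = colnames(cm$counts),
                     total_reads = cm$total_reads)
    utils::write.table(tt, totals_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(counts_tsv)
}

#' Write a heatmap matrix as TSV
#'
#' @param hm a `heatmap_matrix` from [row_centered_log2()].
#' @param path output TSV.
#' @export
write_heatmap <- function(hm, path) {
  out <- data.frame(gene = rownames(hm), unclass(hm), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
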