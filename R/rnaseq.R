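#' RNA-seq count matrix with gene lengths and library totals
#'
#' @param counts gene x sample matrix of non-negative integer counts with
#'   row and column names.
#' @param gene_lengths transcript lengths in bp, one per gene.
#' @param total_reads total mapped reads per sample; defaults to the
#'   column sums, but may exceed them (reads mapped outside the matrix).
#' @param sample_info optional data frame of sample annotations (cell
#'   type, differentiation day), one row per sample.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, gene_lengths, total_reads = NULL,
                         sample_info = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(gene_lengths) != nrow(counts)) {
    stop("need one gene length per row")
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (is.null(total_reads)) total_reads <- colSums(counts)
  total_reads <- rep_len(total_reads, ncol(counts))
  if (any(total_reads < colSums(counts))) {
    stop("total mapped reads cannot be below the column sums")
  }
  structure(list(counts = counts, gene_lengths = as.numeric(gene_lengths),
                 total_reads = as.numeric(total_reads),
                 sample_info = sample_info),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; library sizes",
      paste(format(x$total_reads, big.mark = ","), collapse = ", "), "\n")
  invisible(x)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' \eqn{RPKM_{gs} = counts_{gs} / (length_g/10^3 \times total_s/10^6)}.
#'
#' @param cm a [count_matrix()].
#' @return Gene x sample numeric matrix of RPKM values.
#' @export
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$total_reads <= 0)) stop("zero total mapped reads")
  len_kb <- cm$gene_lengths / 1000
  per_million <- cm$total_reads / 1e6
  sweep(cm$counts / len_kb, 2, per_million, "/")
}

#' Row-centered log2 expression matrix for heatmaps
#'
#' \eqn{v = \log_2(RPKM + pseudocount)} with each row centered on its mean,
#' the transformation behind "mean row-centered log2 RPKM" heatmaps. Row
#' means of the result are 0; centering an already centered matrix is a
#' no-op.
#'
#' @param mat gene x sample RPKM matrix (or any non-negative matrix).
#' @param pseudocount added before the log to keep zeros finite; > 0.
#' @return A `heatmap_matrix` (numeric matrix subclass).
#' @export
row_centered_log2 <- function(mat, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  v <- log2(as.matrix(mat) + pseudocount)
  out <- v - rowMeans(v)
  class(out) <- c("heatmap_matrix", class(out))
  out
}

#' @export
plot.heatmap_matrix <- function(x, ...) {
  m <- unclass(x)
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  axes = FALSE, ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Naive fold-change ranking between two sample groups
#'
#' A deliberately simple screen — log2 fold change of group-mean RPKM (with
#' pseudocount) plus a Wilcoxon rank-sum p-value, Benjamini-Hochberg
#' adjusted. This is \emph{not} a DESeq2-style negative-binomial model and
#' should not be used for inferential differential expression.
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b column indices or names of the two groups.
#' @param pseudocount added before the log.
#' @return Data frame `gene`, `log2_fc`, `p`, `p_adj`, ordered by `p_adj`.
#' @export
simple_fold_table <- function(cm, group_a, group_b, pseudocount = 1) {
  r <- rpkm(cm)
  a <- r[, group_a, drop = FALSE]
  b <- r[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 samples per group")
  lfc <- log2(rowMeans(a) + pseudocount) - log2(rowMeans(b) + pseudocount)
  p <- vapply(seq_len(nrow(r)), function(i) {
    stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value
  }, numeric(1))
  out <- data.frame(gene = rownames(r), log2_fc = lfc, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p_adj), ]
}
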