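#' Dominant behavior of each gene
#'
#' The dominant behavior is the one with the largest weight in the gene's
#' row of `W`; ties break to the lowest behavior id. Genes whose weight row
#' is entirely zero are labeled unexpressed (dominant behavior `NA`).
#'
#' @param model fitted `nmf_model`.
#' @return `behavior_assignment`: data.frame with `gene_id`,
#'   `dominant_behavior` (integer, `NA` for unexpressed), `dominant_weight`,
#'   `unexpressed`; the full weight matrix is attached as attribute
#'   `weights`.
#' @export
dominant_behavior <- function(model) {
  W <- model$W
  dom <- max.col(W, ties.method = "first")
  wmax <- W[cbind(seq_len(nrow(W)), dom)]
  unexpressed <- rowSums(W) == 0
  dom[unexpressed] <- NA_integer_
  out <- data.frame(gene_id = rownames(W),
                    dominant_behavior = dom,
                    dominant_weight = wmax,
                    unexpressed = unexpressed,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "weights") <- W
  class(out) <- c("behavior_assignment", "data.frame")
  out
}

#' Display order of behaviors by peak condition and time
#'
#' Each behavior is keyed by the condition block containing its global
#' expression maximum (GCSF ranks before IL3; an exact tie goes to GCSF
#' because its block comes first) and by the peak time within that block.
#' Behaviors are sorted by (condition rank, peak time), ties by original id.
#'
#' @param model fitted `nmf_model` carrying timepoint column labels (fit on
#'   a [timepoint_matrix]).
#' @return `behavior_ordering`: data.frame with one row per behavior in
#'   display order: `behavior`, `peak_condition`, `peak_time_h`.
#' @export
order_behaviors <- function(model) {
  if (is.null(model$condition)) {
    stop("model carries no condition labels; fit on a timepoint_matrix")
  }
  H <- model$H
  peak_col <- apply(H, 1L, which.max)  # first max: GCSF block, earliest time
  keys <- data.frame(
    behavior = seq_len(nrow(H)),
    peak_condition = model$condition[peak_col],
    peak_time_h = model$timepoint_h[peak_col],
    stringsAsFactors = FALSE)
  ord <- order(match(keys$peak_condition, c("GCSF", "IL3")),
               keys$peak_time_h, keys$behavior)
  out <- keys[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("behavior_ordering", "data.frame")
  out
}

#' Gene permutation for heatmap display
#'
#' Groups genes by their dominant behavior (in the supplied display order of
#' behaviors), sorts within each group by descending dominant weight (ties
#' by gene id), and places unexpressed genes last.
#'
#' @param assignment [dominant_behavior()] output.
#' @param ordering [order_behaviors()] output.
#' @return Character vector: gene ids in display order (a bijection).
#' @export
sort_genes_for_display <- function(assignment, ordering) {
  rank_of <- match(assignment$dominant_behavior, ordering$behavior)
  rank_of[assignment$unexpressed] <- length(ordering$behavior) + 1L
  ord <- order(rank_of, -assignment$dominant_weight, assignment$gene_id)
  assignment$gene_id[ord]
}

#' Top genes of one behavior
#'
#' Genes whose maximum normalized (pre-scaling) expression reaches
#' `expr_floor` are ranked by their weight for the behavior, descending
#' (ties by gene id), and truncated to `n`.
#'
#' @param model fitted `nmf_model`.
#' @param behavior behavior index.
#' @param n list size cap (default 500).
#' @param expr_floor minimum of the gene's maximum normalized expression
#'   (default 3).
#' @param gene_max named per-gene maxima of normalized expression before
#'   max-scaling (the `per_gene_max` of a scaled [timepoint_matrix]).
#' @return data.frame `gene_id`, `weight`, ranked.
#' @export
top_genes <- function(model, behavior, n = 500, expr_floor = 3, gene_max) {
  if (behavior < 1 || behavior > ncol(model$W)) {
    stop("behavior id out of range")
  }
  w <- model$W[, behavior]
  eligible <- names(w)[gene_max[names(w)] >= expr_floor]
  eligible <- eligible[!is.na(eligible)]
  w <- w[eligible]
  ord <- order(-w, names(w))
  head(data.frame(gene_id = names(w)[ord], weight = unname(w[ord]),
                  stringsAsFactors = FALSE), n)
}

#' Cluster transcription factors by temporal co-expression
#'
#' Restricts the timepoint matrix to a TF catalogue, computes pairwise
#' Pearson correlation between the concatenated two-condition expression
#' vectors, clusters on the 1 - r distance, and annotates each TF with its
#' dominant behavior.
#'
#' @param tm `timepoint_matrix`.
#' @param tf_ids character vector of TF gene ids (absent ids dropped with a
#'   warning).
#' @param assignment [dominant_behavior()] output.
#' @param linkage passed to [hierarchical_cluster()].
#' @return list with `correlation` (`correlation_matrix`), `clustering`
#'   ([hierarchical_cluster()] output) and `annotation` (TF rows of the
#'   assignment).
#' @export
cluster_tfs <- function(tm, tf_ids, assignment, linkage = "complete") {
  present <- intersect(tf_ids, rownames(tm$values))
  if (length(present) < length(unique(tf_ids))) {
    warning(length(unique(tf_ids)) - length(present),
            " TF id(s) absent from matrix; dropped")
  }
  if (length(present) < 2L) stop("need at least 2 TFs present")
  sub <- t(tm$values[present, , drop = FALSE])  # items in columns
  cm <- pairwise_timepoint_correlation(sub)
  list(correlation = cm,
       clustering = hierarchical_cluster(cm, linkage = linkage),
       annotation = assignment[match(present, assignment$gene_id), ,
                               drop = FALSE])
}

#' Threshold an externally produced differential-expression table
#'
#' A gene is up-regulated if `padj < alpha` and `log2FoldChange > lfc`,
#' down-regulated if `padj < alpha` and `log2FoldChange < -lfc`; both
#' comparisons are strict. The default `lfc = 0.58` corresponds to a +/-50%
#' change.
#'
#' @param table data.frame with columns `gene_id` (or `gene`),
#'   `log2FoldChange`, `padj`.
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 0.58).
#' @return list with character vectors `up` and `down`.
#' @export
filter_deg_table <- function(table, alpha = 0.05, lfc = 0.58) {
  gene_col <- intersect(c("gene_id", "gene"), names(table))[1L]
  if (is.na(gene_col) || !all(c("log2FoldChange", "padj") %in% names(table))) {
    stop("DE table needs columns gene_id (or gene), log2FoldChange, padj")
  }
  ok <- !is.na(table$padj) & table$padj < alpha
  list(up = table[[gene_col]][ok & table$log2FoldChange > lfc],
       down = table[[gene_col]][ok & table$log2FoldChange < -lfc])
}

#' Write per-behavior assignments to TSV
#' @param assignment [dominant_behavior()] output.
#' @param path TSV path.
#' @export
write_assignment <- function(assignment, path) {
  write.table(as.data.frame(assignment), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
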