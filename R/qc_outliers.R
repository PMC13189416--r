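#' Per-sample principal-component scores on standardized genes
#'
#' Genes are standardized to zero mean and unit variance across samples
#' (`prcomp` with `scale. = TRUE`); zero-variance genes are dropped with a
#' warning since standardization is undefined for them. The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive.
#'
#' @param mat normalized, filtered genes x samples matrix.
#' @return list with `scores` (samples x PCs), `variance_explained`
#'   (fractions summing to 1) and `rotation` (gene loadings).
#' @export
pca_scores <- function(mat) {
  v <- apply(mat, 1L, sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) dropped before PCA")
    mat <- mat[v > 0, , drop = FALSE]
  }
  p <- prcomp(t(mat), center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(k) {
    load <- p$rotation[, k]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, "*")
  rotation <- sweep(p$rotation, 2L, flip, "*")
  list(scores = scores,
       variance_explained = p$sdev^2 / sum(p$sdev^2),
       rotation = rotation)
}

#' Replicate outlier detection by z-scores on top principal components
#'
#' Within every (condition, timepoint) group of N replicates and for each of
#' the top `n_pcs` components, the z-score of a replicate is its absolute
#' deviation from the group mean PC score divided by the population standard
#' deviation (divisor N). A replicate is flagged if any of its z-scores
#' exceeds `threshold`.
#'
#' Note the structural bound: within a group of N replicates every z-score
#' is at most `sqrt(N - 1)`, so at the default threshold of 2 no replicate
#' can ever be flagged unless N >= 6.
#'
#' @param pca result of [pca_scores()] (rows named by sample id).
#' @param sheet validated sample sheet.
#' @param n_pcs number of leading components examined (default 4).
#' @param threshold flagging threshold on z (default 2).
#' @return `outlier_report`: list with `table` (sample, condition,
#'   timepoint, replicate, pc, score, z, flagged rows), `flagged` sample
#'   ids, `threshold`, `variance_explained`.
#' @export
replicate_zscores <- function(pca, sheet, n_pcs = 4, threshold = 2) {
  sheet <- validate_sample_sheet(sheet)
  scores <- pca$scores
  n_pcs <- min(n_pcs, ncol(scores))
  groups <- split(seq_len(nrow(sheet)),
                  paste(sheet$condition, sheet$timepoint_h))
  rows <- list()
  for (g in groups) {
    ids <- sheet$sample_id[g]
    ids <- ids[ids %in% rownames(scores)]
    if (length(ids) < 2L) {
      warning("group with < 2 replicates skipped: ",
              paste(sheet$condition[g[1L]], sheet$timepoint_h[g[1L]]))
      next
    }
    for (k in seq_len(n_pcs)) {
      x <- scores[ids, k]
      mu <- mean(x)
      sdev <- sqrt(mean((x - mu)^2))  # population sd, divisor N
      z <- if (sdev > 0) abs(x - mu) / sdev else rep(0, length(x))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids,
        condition = sheet$condition[g[1L]],
        timepoint_h = sheet$timepoint_h[g[1L]],
        replicate = sheet$replicate[g][match(ids, sheet$sample_id[g])],
        pc = k, score = x, z = z, flagged = z > threshold,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 flagged = sort(unique(tab$sample_id[tab$flagged])),
                 threshold = threshold,
                 variance_explained = pca$variance_explained),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d sample/PC rows, threshold z > %g, %d flagged\n",
              nrow(x$table), x$threshold, length(x$flagged)))
  if (length(x$flagged)) cat("flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise Pearson correlation between timepoint columns
#'
#' Correlation is taken over genes for each pair of columns; the associated
#' dissimilarity is `1 - r`.
#'
#' @param tm `timepoint_matrix` (scaled or not) or a plain matrix whose
#'   columns are the items to correlate.
#' @return `correlation_matrix`: list with `labels`, `r`, `distance`.
#' @export
pairwise_timepoint_correlation <- function(tm) {
  values <- if (inherits(tm, "timepoint_matrix")) tm$values else tm
  v <- apply(values, 2L, sd)
  if (any(v == 0)) {
    stop("zero-variance column: ", colnames(values)[which(v == 0)[1L]])
  }
  r <- cor(values)
  structure(list(labels = colnames(values), r = r, distance = 1 - r),
            class = "correlation_matrix")
}

#' Agglomerative clustering on 1 - r distance
#'
#' @param cm `correlation_matrix`.
#' @param linkage agglomeration method (default `"complete"`, passed to
#'   [stats::hclust()]).
#' @return list with the `hclust` object, `leaf_order` (labels in dendrogram
#'   order) and `newick` (the dendrogram as a Newick string).
#' @export
hierarchical_cluster <- function(cm, linkage = "complete") {
  stopifnot(inherits(cm, "correlation_matrix"))
  d <- cm$distance
  # deterministic tie-break: order items by label before clustering
  ord <- order(cm$labels)
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}
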