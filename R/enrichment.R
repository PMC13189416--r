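#' Read a BED peak file
#'
#' BED intervals are 0-based half-open on disk; the returned `GRanges` uses
#' the usual 1-based closed convention.
#'
#' @param path BED3+ file.
#' @return `GRanges` sorted by position within chromosome.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::sort(gr)
}

#' Read a TSS annotation table
#'
#' Tab-delimited with columns `chrom`, `tss_pos` (0-based base-pair
#' position of a transcript's first base), `strand`, `gene_id`,
#' `transcript_id`, `baseline_expr` (normalized expression in the
#' undifferentiated condition, used to pick representative transcripts).
#'
#' @param path TSV path.
#' @export
read_tss_table <- function(path) {
  tss <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "tss_pos", "gene_id", "transcript_id", "baseline_expr")
  miss <- setdiff(need, names(tss))
  if (length(miss)) stop("TSS table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tss$tss_pos < 0)) stop("negative tss_pos")
  tss
}

#' One representative transcript per gene
#'
#' For genes with multiple transcripts, keeps the transcript with the
#' highest baseline expression; ties break to the lexicographically
#' smallest transcript id.
#'
#' @param tss TSS annotation data.frame.
#' @return Annotation with exactly one row per gene.
#' @export
select_representative_transcript <- function(tss) {
  ord <- order(tss$gene_id, -tss$baseline_expr, tss$transcript_id)
  tss <- tss[ord, , drop = FALSE]
  out <- tss[!duplicated(tss$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# inclusive 0-based window [lo, hi] around tss -> 1-based IRanges,
# clipped at position 0; windows emptied by clipping get zero width
.window_ranges <- function(tss_pos, lo_off, hi_off) {
  lo <- pmax(tss_pos + lo_off, 0)
  hi <- pmax(tss_pos + hi_off, lo - 1)
  IRanges::IRanges(start = lo + 1L, end = hi + 1L)
}

#' Peak occupancy of proximal and distal TSS windows
#'
#' The proximal window spans +/- `proximal_bp` around the representative
#' TSS (inclusive); the distal window spans +/- `distal_bp` minus the
#' proximal zone. A gene is bound in a window when any peak overlaps it by
#' at least one base. Windows are strand-agnostic and clipped at position 0.
#'
#' @param peaks `GRanges` of peaks.
#' @param tss representative-transcript annotation (one row per gene).
#' @param proximal_bp,distal_bp half-widths in bp (defaults 1000, 50000).
#' @return data.frame `gene_id`, `bound_proximal`, `bound_distal`.
#' @export
assign_windows <- function(peaks, tss, proximal_bp = 1000, distal_bp = 50000) {
  if (anyDuplicated(tss$gene_id)) {
    stop("annotation has multiple rows per gene; run select_representative_transcript()")
  }
  pk_chroms <- as.character(unique(GenomicRanges::seqnames(peaks)))
  extra <- setdiff(pk_chroms, unique(tss$chrom))
  if (length(extra)) {
    warning("peak chromosome(s) absent from annotation ignored: ",
            paste(extra, collapse = ", "))
  }
  prox <- GenomicRanges::GRanges(
    tss$chrom, .window_ranges(tss$tss_pos, -proximal_bp, proximal_bp))
  dist_left <- GenomicRanges::GRanges(
    tss$chrom, .window_ranges(tss$tss_pos, -distal_bp, -proximal_bp - 1L))
  dist_right <- GenomicRanges::GRanges(
    tss$chrom, .window_ranges(tss$tss_pos, proximal_bp + 1L, distal_bp))
  hit <- function(win) {
    keep <- GenomicRanges::width(win) > 0
    res <- logical(length(win))
    # suppress the seqlevel-mismatch warning; extra chromosomes are
    # already reported above
    res[keep] <- suppressWarnings(
      GenomicRanges::countOverlaps(win[keep], peaks,
                                   ignore.strand = TRUE)) > 0
    res
  }
  data.frame(gene_id = tss$gene_id,
             bound_proximal = hit(prox),
             bound_distal = hit(dist_left) | hit(dist_right),
             stringsAsFactors = FALSE)
}

#' One-sided Fisher's exact test for binding enrichment
#'
#' Exact upper-tail hypergeometric probability of observing at least `T_p`
#' bound genes in a set of `T_n` genes drawn from a background of `A_n`
#' genes of which `A_p` are bound (the set is contained in the background).
#'
#' @param T_p bound genes in the set.
#' @param T_n set size.
#' @param A_p bound genes in the background.
#' @param A_n background size.
#' @return p-value in \[0, 1\].
#' @export
fisher_one_sided <- function(T_p, T_n, A_p, A_n) {
  if (T_p > T_n || A_p > A_n) stop("bound count exceeds set size")
  if (A_p - T_p < 0 || (A_n - T_n) - (A_p - T_p) < 0) {
    stop("set not contained in background")
  }
  hi <- min(A_p, T_n)
  if (T_p > hi) return(0)
  min(1, sum(dhyper(T_p:hi, m = A_p, n = A_n - A_p, k = T_n)))
}

#' Binding enrichment of a gene set over a background
#'
#' The enrichment ratio is the bound fraction in the set divided by the
#' bound fraction in the background, `(T_p / T_n) / (A_p / A_n)`; the
#' one-sided Fisher's exact test gives its significance. The ratio is `NA`
#' when no background gene is bound or the set is empty after intersection.
#'
#' @param bound data.frame from [assign_windows()], or a named logical
#'   vector of per-gene binding for one window.
#' @param gene_set character vector of set gene ids (must lie within the
#'   background).
#' @param background character vector of background gene ids (e.g. all
#'   genes with normalized expression >= 5).
#' @param window `"proximal"` or `"distal"` (used when `bound` is a
#'   data.frame).
#' @return One-row data.frame: `window`, `T_p`, `T_n`, `A_p`, `A_n`,
#'   `ratio`, `p_value`.
#' @export
binding_enrichment <- function(bound, gene_set, background,
                               window = c("proximal", "distal")) {
  window <- match.arg(window)
  if (is.data.frame(bound)) {
    col <- paste0("bound_", window)
    bound <- setNames(bound[[col]], bound$gene_id)
  }
  if (length(gene_set) == 0L) stop("empty gene_set")
  if (!all(gene_set %in% background)) stop("gene_set not within background")
  b_bg <- bound[background]
  b_bg[is.na(b_bg)] <- FALSE
  names(b_bg) <- background
  T_n <- length(gene_set); A_n <- length(background)
  T_p <- sum(b_bg[gene_set]); A_p <- sum(b_bg)
  ratio <- if (A_p > 0 && T_n > 0) (T_p / T_n) / (A_p / A_n) else NA_real_
  data.frame(window = window, T_p = T_p, T_n = T_n, A_p = A_p, A_n = A_n,
             ratio = ratio,
             p_value = fisher_one_sided(T_p, T_n, A_p, A_n),
             stringsAsFactors = FALSE)
}

#' Enrichment report over gene sets, windows and DEG directions
#'
#' For every input set, enrichment is computed in the proximal and distal
#' windows. A set supplied as a plain character vector yields one direction
#' (`"all"`); a set supplied as `list(up = ..., down = ...)` (a filtered
#' DEG table) yields `all` (union), `up` and `down` rows.
#'
#' @param sets named list of gene sets (character vectors or up/down
#'   lists).
#' @param peaks `GRanges` of peaks.
#' @param tss TSS annotation (representative transcripts are selected
#'   internally if needed).
#' @param background background gene ids.
#' @param proximal_bp,distal_bp window half-widths.
#' @param adjust add a Benjamini-Hochberg `padj` column (default `FALSE`;
#'   raw one-sided p-values are always reported).
#' @return data.frame with one row per (set, direction, window).
#' @export
enrichment_report <- function(sets, peaks, tss, background,
                              proximal_bp = 1000, distal_bp = 50000,
                              adjust = FALSE) {
  if (anyDuplicated(tss$gene_id)) {
    tss <- select_representative_transcript(tss)
  }
  bound <- assign_windows(peaks, tss, proximal_bp, distal_bp)
  rows <- list()
  for (set_name in names(sets)) {
    s <- sets[[set_name]]
    directions <- if (is.list(s)) {
      list(all = unique(unlist(s, use.names = FALSE)), up = s$up, down = s$down)
    } else list(all = s)
    for (dir_name in names(directions)) {
      genes <- intersect(directions[[dir_name]], background)
      if (length(genes) == 0L) next
      for (win in c("proximal", "distal")) {
        res <- binding_enrichment(bound, genes, background, window = win)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(set = set_name, direction = dir_name,
                     stringsAsFactors = FALSE), res)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
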